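---
title: "Genomic selection for multi-site conifer trials: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection for multi-site conifer trials: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprucegs)
```

# The problem

Conifer breeding programs evaluate thousands of full-sib progeny across
several field sites and want to select, as early as possible, trees that
combine growth, wood quality and — in the white spruce case that
motivates this package — constitutive chemical resistance to defoliating
insects (the needle acetophenones piceol and pungenol). Phenotyping the
metabolites is expensive, so only a subset of trees is measured while
the whole candidate population is genotyped on a SNP array. `sprucegs`
implements the full analysis chain for that setting: SNP quality
control and imputation, pedigree and genomic relationship matrices,
REML/BLUP mixed models with additive and dominance effects, a BayesC-pi
marker-effect sampler, replicated cross-validation, and multi-trait
selection scenarios — together with a synthetic trial generator that
reproduces the statistical structure these models assume.

# The mixed model

The individual-tree model for a trait $y$ is

$$ y = X\beta + Z_1 a + (Z_2 d) + e, $$

where $\beta$ holds the overall mean, site, test-within-site and tree
age (a covariate: tests were measured at ages 16–28); $a \sim
N(0, \sigma^2_a K)$ is the additive genetic effect with $K$ either the
pedigree relationship matrix $A$ (ABLUP, tabular method) or the VanRaden
genomic matrix $G = WW'/2\sum p_k(1-p_k)$ (GBLUP); the optional
dominance term uses either a full-sib family effect $d \sim N(0,
\sigma^2_f I)$ (pedigree models) or the Vitezica dominance matrix
$G_{Dom} = HH'/\sum(2p_kq_k)^2$ built from the covariates
$\{-2p^2, 2pq, -2q^2\}$; and $e$ is block-diagonal by site with one
residual variance per site, because multi-site trials are visibly
heteroskedastic.

Heritabilities are variance ratios against the phenotypic variance
$\sigma^2_a + (\sigma^2_d\ \text{or}\ \sigma^2_f) + \bar\sigma^2_e$ with
$\bar\sigma^2_e$ the mean residual across sites. In the family
parameterization the dominance fraction is $4\sigma^2_f$ over the
phenotypic variance (full sibs share one quarter of the dominance
variance) and the broad-sense numerator is $\sigma^2_a + 4\sigma^2_f$;
in the genomic parameterization the fractions are the plain ratios and
$d^2 = H^2 - h^2$. Standard errors come from the first-order delta
method over the average-information covariance of the variance
components.

## The REML engine

Variance components are estimated by average-information (AI) REML on
the dense phenotyped-tree covariance: each iteration costs one Cholesky
factorization and one symmetric inverse of the $n \times n$ matrix
$V(\theta)$, because every trace the score needs reduces to an
elementwise sum of $P$ against a fixed base matrix (the per-site
residual bases are diagonal, and the genetic bases are precomputed).
The AI matrix is positive semi-definite, so the AI direction is an
ascent direction; the update is step-halved until the restricted
log-likelihood does not decrease, giving a monotone iteration without a
separate EM mode. Variances are projected to a small positive bound
($10^{-8}$ times the phenotypic variance, keeping the estimator
scale-equivariant); a bound-stuck component with an outward gradient is
frozen out of the update. Convergence requires the log-likelihood
change below $10^{-6}$ and the relative parameter change below
$10^{-8}$; non-convergence raises an error carrying the iteration
trace. On a balanced single-site family design the estimator reproduces
the one-way ANOVA intraclass estimator, and the G-matrix animal model
reproduces ridge-regression marker BLUP to numerical precision when the
variance ratio is matched — both are enforced by tests.

Bivariate models stack two traits measured on the same trees and use
the CORGH parameterization: per-trait variances plus a correlation for
the additive (and optional dominance) term, and a homogeneous per-trait
residual with a shared within-tree residual correlation. Starting
values come from the univariate fits with correlations started at zero.
The total genetic and phenotypic correlations combine the estimated
(co)variances,

$$ \hat r_g = \frac{\hat r_a \hat\sigma_{a1}\hat\sigma_{a2} +
  \hat r_d \hat\sigma_{d1}\hat\sigma_{d2}}
  {\sqrt{(\hat\sigma^2_{a1}+\hat\sigma^2_{d1})
         (\hat\sigma^2_{a2}+\hat\sigma^2_{d2})}}, $$

with the analogous expression (adding the residual term) for
$\hat r_p$; significance uses likelihood-ratio tests against the fits
with the correlations fixed at zero.

Variance-component tests use the boundary-corrected mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; the reported p-value is
$\tfrac12 P(\chi^2_1 \ge \Lambda)$, which is exact for a single
variance on the boundary and holds its nominal size in a
1,000-replicate null simulation run by the test suite. AIC and BIC
count the estimated variance parameters, with residual degrees of
freedom ($n - \operatorname{rank} X$) as the BIC sample size — the
conventional REML choice, made explicit here because information
criteria on REML fits are only comparable across models with the same
fixed effects.

# BayesC-pi

The marker model replaces $Z_1 a$ by marker effects under a
spike-and-slab prior: each marker's additive effect (0/1/2 rare-allele
coding) is zero with probability $1-\pi$ or drawn from a common
Gaussian slab, and the dominance term (0/1 heterozygosity coding) gets
its own slab and its own $\pi$. Both $\pi$s carry a
$\mathrm{Beta}(p_0\pi_0, p_0(1-\pi_0))$ prior with mean $\pi_0 = 0.5$
and weight $p_0 = 10$; slab variances are scaled inverse chi-square
with 5 degrees of freedom and a scale chosen so the prior marker
variance explains half the phenotypic variance (split across terms in
additive-dominance fits); residual variances are per-site scaled
inverse chi-squares. The Gibbs sampler (compiled code) updates each
indicator and effect jointly from the marginalized likelihood ratio,
which avoids the poor mixing of separate indicator updates. Two chains
with consecutive seeds are pooled, and the Gelman–Rubin shrink factor
(between/within-chain variance) is reported for the monitored variance
parameters with the usual < 1.1 convergence yardstick. The default
schedule (5,000 iterations, 1,500 burn-in, thinning 5) is sized for
interactive use and testing; `preset = "paper"` selects the long
production schedule (50,000 / 15,000 / 20). With $\pi$ forced to 1 and
a fixed slab variance the sampler is Bayesian ridge regression and its
posterior-mean predictions match RR-BLUP, which the acceptance tests
verify.

# Cross-validation and accuracy

`make_folds()` deals each family's trees round-robin into 10 folds
(repeated 10 times, 100 fits per model), so every training set sees
every family — the relevant design for within-family selection.
Predictive ability (PA) is the Pearson correlation between predictions
for held-out trees and their fixed-effect-adjusted phenotypes
(residuals of the fixed-effects-only least squares fit, computed once
on the full data). Held-out trees enter prediction only through their
relationship rows or genotypes; a permutation test in the suite
verifies that shuffling held-out phenotypes leaves predictions
unchanged. By default the variance components are estimated once on
the full data and each fold solves the training-set BLUP at those
components; `reestimate = TRUE` refits REML inside every training set
at ~100x the cost, with practically identical summaries on the
synthetic trials.

Prediction accuracy (PACC) is reported three ways: PA standardized by
$\sqrt{h^2}$ (or $\sqrt{H^2}$ for additive-dominance fits), using the
genomic estimate so pedigree, genomic and Bayesian models are
standardized identically; and the correlations of fold predictions
with the full-data pedigree-model and genomic-model values treated as
pseudo-true values. The pseudo-truth variants are known to flatter the
models — the full-data values share information with every training
set — and are reported for comparability, not preferred.

# Selection scenarios

All strategies rank genomically predicted values (GEBV, or GEGV =
additive + dominance BLUP) for the complete genotyped candidate set,
including unphenotyped trees, which receive conditional-expectation
BLUPs from the same fit. Expected gains are reported per trait as
100 x mean predicted value of the selected set over the phenotypic
mean. Four strategies are provided: truncation (`select_top`, size =
round-half-up of intensity x candidates, ties broken by stable id
order); independent culling (cull on secondary-trait thresholds, then
rank on the primary trait); a z-score selection index with user
weights (standardized by the candidate-set standard deviation, since
no economic weights are available on the raw scales); and
correlation-breaker selection (top primary-trait candidates among
those non-negative on the secondary trait). Gains are computed and
reported on the analysis scale — for square-root-transformed
metabolites that is the transformed scale — because back-transformed
"percent of mean" mixes scales; the phenotypic means used as
denominators are stored in the candidate set, so a user who prefers
raw-scale percentages can substitute raw means.

# The synthetic trial generator

`sim_config()` defaults encode a large multi-site progeny trial: 120
female x 118 male parents crossed into 136 full-sib families of ten
phenotyped trees plus ~206 genotyped-only candidates; five sites with
tests nested in site and one test per family per site, with ~20% of
families on a single site (reproducing the family–test confounding of
real selection plantations, which is why genotype-by-environment terms
are not estimable and are not modelled); one age per test drawn from
16–28 years; and 4,148 SNPs in 20-SNP LD blocks (block-copula founder
haplotypes, latent loading 0.8) with 0.2% missingness and a 0.02%
error rate. Seven default traits mirror growth, acoustic velocity and
the three acetophenones, with genomic-scale heritability targets,
small dominance fractions, a positive-definite seven-trait genetic
correlation matrix (piceol–pungenol 0.60, pungenol–picein −0.65,
height–piceol −0.38), and per-site residual variances spread by a
0.7–1.3 profile — chosen so phenotypic coefficients of variation fall
in the range typical of such trials, since per-site residuals are
never published.

Breeding values are generated by a polygenic gene-drop: every SNP
carries a small normal effect, correlated across traits, and the
resulting genetic values are rescaled so the realized additive variance
among phenotyped progeny hits `h2_target` exactly. This choice matters:
drawing breeding values from the Cholesky factor of $A$ makes them
statistically independent of the markers, and genomic REML then
attenuates $\hat h^2$ by the (large) Mendelian-sampling share that the
markers cannot see — an interesting artefact, but not the data the
genomic models assume. With the gene-drop, GBLUP recovers the target
heritability and ABLUP overshoots it slightly, the same ordering
reported for real spruce data. The Cholesky route remains available
when no genotypes are passed. Dominance is simulated as a family
effect (variance $\sigma^2_d/4$, matching the $4\sigma^2_f$
convention) plus an individual deviation ($3\sigma^2_d/4$); metabolite
traits are emitted as squared latent values so the analysis-side
square-root transform is the correct normalization.

What the generator does not emulate: genotype-by-environment
interaction, spatial field trends, multi-generation selection,
recombination maps within blocks, and non-Gaussian residuals. Passing
recovery tests on these trials therefore shows the estimators are
correct for the assumed model, not that the model is complete for any
particular field dataset.

# Numerical choices and problem sizes

Relationship matrices are conditioned with a $10^{-6}$ diagonal
inflation only when their smallest eigenvalue is non-positive (the
flag is recorded); the LD-kNN imputer offsets Manhattan distances by 1
so perfect-LD neighbours keep finite $1/d^2$ weight, computes marker
r-squared on complete pairs only (avoiding imputation circularity),
and falls back to the modal genotype when a SNP has fewer observed
calls than neighbours; imputation ties go to the smaller genotype.
Default LD-kNN parameters are l = 30 SNPs and k = 5 neighbours, the
published defaults of the method this module follows.

The test suite exercises recovery at the sizes a reviewer can wait
for: 20 replicate trials of 2,000 trees for heritability recovery, one
2,000-tree bivariate fit for the genetic correlation, 1,000
pedigree-based null replicates (~180 trees each) for the
likelihood-ratio calibration, and reduced 2,500–5,000-iteration MCMC
schedules; the acceptance script uses 10 heritability replicates and a
598-tree marker-model subset. These sizes are the package's own
trade-off between Monte-Carlo error and turnaround, and all bands
asserted by the tests were chosen from the statistical properties of
the estimators at those sizes.

# Known limitations

Single-step (combined pedigree–genomic) evaluation, dominance pedigree
matrices, epistatic kinships, multi-trait (> 2) REML, spatial
adjustment and genotype-by-environment modelling are out of scope. The
AI-REML engine is dense and comfortable to ~4,000 stacked records;
larger problems need sparse or rotation tricks it deliberately avoids
for clarity. The BayesC-pi sampler reports Monte-Carlo summaries only;
no effective-sample-size diagnostics beyond the Gelman–Rubin factor
are computed.
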