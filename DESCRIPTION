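Package: sprucegs
Title: Genomic Selection for Conifer Breeding Trials with Additive and
    Dominance Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection analyses in forest-tree breeding
    programs of the kind run for white spruce resistance, growth and
    wood-quality traits. Builds pedigree (A), genomic additive (VanRaden G)
    and genomic dominance (Vitezica G_Dom) relationship matrices; fits
    univariate and bivariate individual-tree mixed models by average-information
    REML with site-heterogeneous residual variances; estimates narrow-sense,
    dominance and broad-sense heritabilities with delta-method standard
    errors, genetic correlations, likelihood-ratio tests and information
    criteria; runs a BayesC-pi spike-and-slab Gibbs sampler for additive and
    dominance marker effects with Gelman-Rubin convergence checks; performs
    family-stratified replicated cross-validation with predictive ability and
    three prediction-accuracy definitions; ranks candidates and reports
    expected multi-trait genetic gains under truncation, independent-culling,
    index and correlation-breaker selection. Includes SNP quality control
    with LD-kNN imputation and a synthetic breeding-trial generator that
    reproduces the statistical structure the models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    coda,
    withr
Config/testthat/edition: 3
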