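# Build a minimal fit object with known components, for the pure
# arithmetic of heritability ratios and information criteria.
fake_fit <- function(theta, tag, loglik = -100, n = 100, rank_X = 2) {
  structure(list(
    components = list(theta = theta,
                      sigma2_e_by_site = theta[grep("^sigma2_e_",
                                                    names(theta))],
                      sigma2_e_bar = mean(theta[grep("^sigma2_e_",
                                                     names(theta))]),
                      loglik = loglik,
                      ai_cov = diag(1e-4, length(theta))),
    model_tag = tag, n = n, rank_X = rank_X), class = "gs_fit")
}

test_that("heritability ratios follow the additive and AD definitions", {
  # additive model: va / (va + mean residual)
  f <- fake_fit(c(sigma2_a = 1, sigma2_e_S1 = 1),
                list(model = "GBLUP", effects = "a"))
  h <- heritability(f)
  expect_equal(h$h2, 0.5)
  expect_true(is.na(h$d2) && is.na(h$H2))
  # family-variance AD: d2 = 4 vf / (va + vf + ve), H2 = (va + 4vf)/(...)
  f2 <- fake_fit(c(sigma2_a = 1e-8, sigma2_f = 0.25, sigma2_e_S1 = 0.75),
                 list(model = "ABLUP", effects = "ad",
                      dominance_kind = "family"))
  h2 <- heritability(f2)
  expect_equal(h2$d2, 1.0, tolerance = 1e-6)
  expect_equal(h2$H2, 1.0, tolerance = 1e-6)
  # genomic AD: plain ratios, d2 = H2 - h2
  f3 <- fake_fit(c(sigma2_a = 0.4, sigma2_d = 0.05, sigma2_e_S1 = 0.55),
                 list(model = "GBLUP", effects = "ad",
                      dominance_kind = "matrix"))
  h3 <- heritability(f3)
  expect_equal(h3$h2, 0.40)
  expect_equal(h3$d2, 0.05)
  expect_equal(h3$H2, 0.45)
  expect_equal(h3$d2, h3$H2 - h3$h2)
  # multi-site residuals enter via their mean
  f4 <- fake_fit(c(sigma2_a = 1, sigma2_e_S1 = 0.5, sigma2_e_S2 = 1.5),
                 list(model = "GBLUP", effects = "a"))
  expect_equal(heritability(f4)$h2, 0.5)
})

test_that("information criteria penalize the variance-parameter count", {
  f <- fake_fit(c(sigma2_a = 1, sigma2_d = 1, sigma2_e_S1 = 1),
                list(model = "GBLUP", effects = "ad",
                     dominance_kind = "matrix"),
                loglik = -100, n = 102, rank_X = 2)
  ic <- information_criteria(f)
  expect_equal(ic$AIC, 206)
  expect_equal(ic$BIC, 200 + 3 * log(100))
  # one extra component costs exactly 2 AIC at equal loglik
  f_a <- fake_fit(c(sigma2_a = 1, sigma2_e_S1 = 1),
                  list(model = "GBLUP", effects = "a"),
                  loglik = -100, n = 102, rank_X = 2)
  expect_equal(ic$AIC - information_criteria(f_a)$AIC, 2)
})

test_that("single-site family REML matches the ANOVA intraclass oracle", {
  dat <- balanced_family_data(nf = 40, nr = 6, vf = 0.3, ve = 0.7)
  nf <- 40
  Kf <- diag(nf)
  rownames(Kf) <- colnames(Kf) <- paste0("f", seq_len(nf))
  ph <- dat
  ph$tree <- ph$family  # random effect indexed at the family level
  fit <- fit_univariate(ph, Kf, "y")
  # one-way ANOVA intraclass estimator
  av <- anova(lm(y ~ factor(family), dat))
  msb <- av[1, 3]
  msw <- av[2, 3]
  vf_hat <- (msb - msw) / 6
  icc <- vf_hat / (vf_hat + msw)
  expect_lt(abs(heritability(fit)$h2 - icc), 0.02)
  # REML log-likelihood trace is monotone non-decreasing
  expect_true(all(diff(fit$trace$loglik) >= -1e-8))
})

test_that("null traits yield near-zero additive variance", {
  sim <- small_trial()
  set.seed(8)
  ph <- sim$phenotypes
  ph$noise <- rnorm(nrow(ph))
  A <- pedigree_to_A(sim$pedigree)
  fit <- fit_univariate(ph, A, "noise")
  ratio <- fit$components$sigma2_a /
    (fit$components$sigma2_a + fit$components$sigma2_e_bar)
  expect_lt(ratio, 0.05)
})

test_that("heritability is invariant to rescaling the trait", {
  sim <- small_trial()
  G <- condition_psd(vanraden_G(small_trial_geno()))
  ph <- sim$phenotypes
  f1 <- fit_univariate(ph, G, "PICEIN")
  ph$PICEIN <- ph$PICEIN * 10
  f2 <- fit_univariate(ph, G, "PICEIN")
  expect_equal(heritability(f1)$h2, heritability(f2)$h2, tolerance = 1e-4)
  expect_equal(f2$components$sigma2_a / f1$components$sigma2_a, 100,
               tolerance = 1e-3)
})

test_that("predictions are invariant to reordering individuals", {
  sim <- small_trial()
  G <- condition_psd(vanraden_G(small_trial_geno()))
  ph <- sim$phenotypes
  f1 <- fit_univariate(ph, G, "VELO")
  perm <- sample(nrow(ph))
  f2 <- fit_univariate(ph[perm, ], G, "VELO")
  expect_equal(f1$ebv, f2$ebv[names(f1$ebv)], tolerance = 1e-6)
})

test_that("additive-dominance fits expose dominance BLUPs and EGVs", {
  sim <- small_trial()
  G <- condition_psd(vanraden_G(small_trial_geno()))
  D <- condition_psd(vitezica_D(small_trial_geno()))
  fit <- fit_univariate(sim$phenotypes, G, "HT", dominance = D)
  expect_equal(fit$model_tag$effects, "ad")
  expect_equal(fit$egv[names(fit$ebv)],
               fit$ebv + fit$dom_blup[names(fit$ebv)])
  # family parameterization: one BLUP per family
  fitf <- fit_univariate(sim$phenotypes, pedigree_to_A(sim$pedigree),
                         "HT", dominance = "family")
  expect_equal(length(fitf$dom_blup),
               length(unique(sim$phenotypes$family)))
  expect_false(is.null(fitf$components$sigma2_f))
})

test_that("variance LRT uses the boundary mixture and checks nesting", {
  sim <- small_trial()
  A <- pedigree_to_A(sim$pedigree)
  full <- fit_univariate(sim$phenotypes, A, "PICEIN")
  red <- fit_univariate(sim$phenotypes, NULL, "PICEIN")
  out <- lrt_variance(full, red)
  expect_gte(out$statistic, 0)
  expect_lt(out$p_value, 0.001)  # strong additive signal (h2 ~ 0.6)
  # identical fits: statistic 0, p = 0.5, not significant
  same <- lrt_variance(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 0.5)
  # mismatched sample sizes / non-nested models refuse to test
  expect_error(lrt_variance(red, full), "nested")
})

test_that("bivariate fit recovers degenerate and independent cases", {
  sim <- small_trial()
  G <- condition_psd(vanraden_G(small_trial_geno()))
  ph <- sim$phenotypes
  # trait duplicated: all correlations go to the +1 boundary
  ph$COPY <- ph$VELO
  bf <- fit_bivariate(ph, G, c("VELO", "COPY"), lrt = FALSE)
  expect_gte(bf$ra, 0.999 - 1e-8)
  expect_gte(bf$rp, 0.995)
  # independent noise traits: correlation near zero
  set.seed(21)
  ph$N1 <- rnorm(nrow(ph))
  ph$N2 <- rnorm(nrow(ph))
  bf0 <- fit_bivariate(ph, G, c("N1", "N2"), lrt = FALSE)
  expect_lt(abs(bf0$re), 0.15)
  expect_true(all(abs(c(bf0$ra, bf0$re, bf0$rg, bf0$rp)) <= 1))
})

test_that("bivariate genetic correlation matches the simulated truth", {
  sim <- small_trial()
  G <- condition_psd(vanraden_G(small_trial_geno()))
  bf <- fit_bivariate(sim$phenotypes, G, c("PICEOL", "PUNGENOL"),
                      transform = "sqrt")
  truth <- sim$truth$realized_ra["PICEOL", "PUNGENOL"]
  expect_lt(abs(bf$ra - truth), 3 * bf$se_ra + 0.05)
  expect_lt(bf$lrt_p_genetic, 0.05)
  # Eq-style combination stays inside [-1, 1] and near ra without dominance
  expect_equal(bf$rg, bf$ra, tolerance = 1e-8)
})

test_that("BIC prefers the additive model when dominance is absent", {
  wins <- 0L
  for (r in 1:20) {
    cfg <- sim_config(seed = 300 + r, n_females = 15, n_males = 15,
                      n_families = 25, progeny_per_family = 8,
                      n_unphenotyped = 0, n_sites = 2,
                      tests_per_site = 2, n_snps = 250,
                      trait_specs = list(trait_spec("Y", 10, 2, 0.4, 0)),
                      genetic_corr = diag(1))
    sim <- simulate_trial(cfg)
    G <- condition_psd(vanraden_G(attr(sim$genotypes, "truth")))
    D <- condition_psd(vitezica_D(attr(sim$genotypes, "truth")))
    fa <- fit_univariate(sim$phenotypes, G, "Y")
    fad <- fit_univariate(sim$phenotypes, G, "Y", dominance = D)
    if (information_criteria(fa)$BIC < information_criteria(fad)$BIC) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 16)  # >= 80% of 20 replicates
})
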