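test_that("pedigree simulation respects the mating design", {
  cfg <- sim_config(n_females = 2, n_males = 2, n_families = 4,
                    progeny_per_family = 10, n_unphenotyped = 0,
                    trait_specs = list(trait_spec("y", 10, 1, 0.3)),
                    genetic_corr = diag(1), seed = 5)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 44)  # 4 founders + 40 progeny
  expect_equal(sum(ped$cohort == "progeny"), 40)
  founders <- ped[ped$cohort == "founder", ]
  expect_true(all(is.na(founders$sire) & is.na(founders$dam)))
  # study-scale design: 136 distinct parent pairs
  ped2 <- simulate_pedigree(sim_config(seed = 2))
  pairs <- unique(paste(ped2$sire, ped2$dam)[ped2$cohort == "progeny"])
  expect_equal(length(pairs), 136)
  fam_sizes <- table(ped2$family[ped2$phenotyped])
  expect_true(all(fam_sizes == 10))
  # full sibs of a simulated family are 0.5 related
  A <- pedigree_to_A(ped)
  sibs <- ped$id[ped$family == ped$family[ped$cohort == "progeny"][1] &
                   !is.na(ped$family)]
  expect_equal(A$values[sibs[1], sibs[2]], 0.5)
})

test_that("infeasible or invalid configurations are rejected", {
  expect_error(sim_config(n_females = 2, n_males = 2, n_families = 5),
               "infeasible")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(missing_rate = 1.5), "rates")
  badR <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(
    sim_config(trait_specs = list(trait_spec("a", 1, 1, 0.3),
                                  trait_spec("b", 1, 1, 0.3)),
               genetic_corr = badR),
    "positive semi-definite")
  expect_error(trait_spec("x", 1, 1, h2_target = 0.8, d2_target = 0.4))
})

test_that("gene drop is Mendelian and masking honours the rates", {
  sim <- small_trial()
  truth <- attr(sim$genotypes, "truth")
  ped <- sim$pedigree
  # both-parent homozygous-reference SNPs give reference offspring
  prog <- ped[ped$cohort == "progeny", ][1:50, ]
  for (i in seq_len(nrow(prog))) {
    both0 <- truth[prog$sire[i], ] == 0 & truth[prog$dam[i], ] == 0
    expect_true(all(truth[prog$id[i], both0] == 0))
    both2 <- truth[prog$sire[i], ] == 2 & truth[prog$dam[i], ] == 2
    expect_true(all(truth[prog$id[i], both2] == 2))
  }
  # missingness close to the configured rate; truth has none
  expect_false(anyNA(truth))
  expect_lt(abs(mean(is.na(sim$genotypes)) - 0.01), 0.003)
  cfg0 <- sim$config
  cfg0$missing_rate <- 0
  g0 <- simulate_genotypes(ped, cfg0)
  expect_false(anyNA(g0))
})

test_that("founder allele frequencies match the configured MAF", {
  cfg <- sim_config(seed = 9, n_females = 150, n_males = 150,
                    n_families = 150, progeny_per_family = 1,
                    n_unphenotyped = 0, n_snps = 300)
  ped <- simulate_pedigree(cfg)
  M <- attr(simulate_genotypes(ped, cfg), "truth")
  p_target <- attr(simulate_genotypes(ped, cfg), "founder_p")
  founders <- ped$id[ped$cohort == "founder"]
  p_obs <- colMeans(M[founders, ]) / 2
  # binomial error on 600 alleles: |phat - p| within 4 SEs almost surely
  se <- sqrt(p_target * (1 - p_target) / (2 * length(founders)))
  expect_gt(mean(abs(p_obs - p_target) < 4 * se), 0.99)
  expect_gt(cor(p_obs, p_target), 0.95)
})

test_that("block copula generates within-block LD", {
  sim <- small_trial()
  truth <- attr(sim$genotypes, "truth")
  b <- sim$config$ld_block_size
  first <- seq(1, by = b, length.out = 10)  # block leaders
  r2_within <- vapply(first, function(s) {
    mean(cor(truth[, s], truth[, s + 1:3])^2)
  }, numeric(1))
  r2_across <- vapply(first[-10], function(s) {
    mean(cor(truth[, s], truth[, s + b + 1:3])^2)
  }, numeric(1))
  expect_gt(mean(r2_within), 0.1)
  expect_lt(mean(r2_across), 0.05)
  expect_gt(mean(r2_within), 4 * mean(r2_across))
})

test_that("realized heritability tracks the target", {
  cfg <- sim_config(seed = 31, n_families = 100, progeny_per_family = 10,
                    n_unphenotyped = 0, n_snps = 300,
                    trait_specs = list(trait_spec("y", 10, 2, 0.5)),
                    genetic_corr = diag(1))
  sim <- simulate_trial(cfg)
  expect_lt(abs(sim$truth$realized_h2["y"] - 0.5), 0.03)
  # null trait carries no genetic signal
  cfg0 <- sim_config(seed = 32, n_families = 60, progeny_per_family = 8,
                     n_unphenotyped = 0, n_snps = 200,
                     trait_specs = list(trait_spec("y", 10, 2, 0)),
                     genetic_corr = diag(1))
  sim0 <- simulate_trial(cfg0)
  expect_equal(unname(sim0$truth$realized_h2["y"]), 0)
  expect_true(all(sim0$truth$true_breeding_values == 0))
})

test_that("trait correlations and skew transforms behave as configured", {
  sim <- small_trial()
  ra <- sim$truth$realized_ra["PICEOL", "PUNGENOL"]
  expect_gt(ra, 0.4)  # configured 0.60, small-sample wobble allowed
  expect_lt(ra, 0.8)
  # square-emitted metabolite is right-skewed; sqrt restores symmetry
  x <- sim$phenotypes$PICEOL
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_gt(skew(x), 0.5)
  expect_lt(abs(skew(sqrt(x))), skew(x))
  # family-site layout: one or two sites per family, one test per site
  tab <- table(sim$phenotypes$family,
               paste(sim$phenotypes$site, sim$phenotypes$test))
  sites_per_fam <- rowSums(table(sim$phenotypes$family,
                                 sim$phenotypes$site) > 0)
  expect_true(all(sites_per_fam %in% 1:2))
  expect_true(all(rowSums(tab > 0) == sites_per_fam))
})

test_that("simulation is bit-reproducible from the seed", {
  cfg <- sim_config(seed = 77, n_families = 10, progeny_per_family = 4,
                    n_unphenotyped = 5, n_females = 8, n_males = 8,
                    n_snps = 50)
  s1 <- simulate_trial(cfg)
  s2 <- simulate_trial(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  cfg2 <- cfg
  cfg2$seed <- 78L
  expect_false(identical(simulate_trial(cfg2)$phenotypes, s1$phenotypes))
})
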