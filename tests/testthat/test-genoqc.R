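test_that("per-SNP statistics match direct counting", {
  set.seed(12)
  M <- hwe_panel(100, 50, seed = 12)
  mask <- matrix(runif(length(M)) < 0.10, nrow(M))
  Mm <- M
  Mm[mask] <- NA
  st <- compute_snp_stats(Mm)
  expect_equal(st$call_rate, unname(colMeans(!is.na(Mm))))
  expect_lt(abs(mean(st$call_rate) - 0.90), 0.02)
  p <- colMeans(Mm, na.rm = TRUE) / 2
  expect_equal(st$maf, unname(pmin(p, 1 - p)))
  # fully heterozygous SNP: p = 0.5, Hobs = 1, fe = 1 - 1/0.5 = -1
  Mh <- cbind(M, allhet = rep(1, 100))
  sth <- compute_snp_stats(Mh)
  expect_equal(sth$fe[sth$snp_id == "allhet"], -1)
  # monomorphic SNP: maf 0, fe undefined
  Mm2 <- cbind(M, mono = rep(0, 100))
  stm <- compute_snp_stats(Mm2)
  expect_equal(stm$maf[stm$snp_id == "mono"], 0)
  expect_true(is.na(stm$fe[stm$snp_id == "mono"]))
})

test_that("fe stays within [-1, 1] whenever defined", {
  for (s in 1:5) {
    M <- hwe_panel(60, 80, seed = s)
    fe <- compute_snp_stats(M)$fe
    fe <- fe[!is.na(fe)]
    expect_true(all(fe >= -1 - 1e-12 & fe <= 1 + 1e-12))
  }
})

test_that("Mendelian checks flag impossible trios", {
  ped <- data.frame(id = c("s", "d", paste0("k", 1:6)),
                    sire = c(NA, NA, rep("s", 6)),
                    dam = c(NA, NA, rep("d", 6)),
                    stringsAsFactors = FALSE)
  M <- rbind(s = c(0, 1), d = c(0, 1),
             matrix(c(0, 0, 0, 0, 0, 2,      # snp1: one impossible kid
                      1, 1, 0, 2, 1, 0), 6, 2,
                    dimnames = list(paste0("k", 1:6), NULL)))
  colnames(M) <- c("snp1", "snp2")
  st <- compute_snp_stats(M, pedigree = ped)
  expect_gt(st$mendel_impossible[st$snp_id == "snp1"], 0)
  expect_equal(st$mendel_impossible[st$snp_id == "snp2"], 0)
})

test_that("replicate discordance is counted over compared calls", {
  M <- rbind(a = c(0, 1, 2, 1), a2 = c(0, 1, 0, NA),
             b = c(2, 2, 2, 2))
  colnames(M) <- paste0("s", 1:4)
  st <- compute_snp_stats(M, replicates = cbind("a", "a2"))
  expect_equal(st$replicate_error_rate, c(0, 0, 1, NA_real_))
})

test_that("filters remove exactly the offending SNPs", {
  set.seed(3)
  n <- 60
  clean <- hwe_panel(n, 95, p = runif(95, 0.2, 0.5), seed = 3)
  bad_missing <- rbinom(n, 2, 0.3)
  bad_missing[seq_len(0.2 * n)] <- NA
  bad_maf <- c(0, 0, 1, rep(0, n - 3))             # maf ~ 0.008
  bad_fe <- rep(1, n)                              # all heterozygous
  bad_err <- rbinom(n, 2, 0.4)
  bad_err[2] <- (bad_err[1] + 1) %% 3              # replicate discordance
  M <- cbind(clean, miss = bad_missing, lowmaf = bad_maf,
             allhet = bad_fe, err = bad_err)
  rownames(M) <- paste0("i", 1:n)
  reps <- cbind(paste0("i", 1), paste0("i", 2))
  # make i2 a replicate of i1: identical except the planted discordance
  M[2, seq_len(95)] <- M[1, seq_len(95)]
  M["i2", "miss"] <- M["i1", "miss"]
  M["i2", "lowmaf"] <- M["i1", "lowmaf"]
  st <- compute_snp_stats(M, replicates = reps)
  out <- filter_snps(st, qc_thresholds())
  expect_setequal(out$retained, colnames(clean))
  expect_equal(sum(out$attrition), 4)
  # vacuous thresholds keep every segregating SNP
  out2 <- filter_snps(st, qc_thresholds(max_missing = 1, min_maf = 0,
                                        max_abs_fe = 1,
                                        max_error_rate = 1,
                                        mendel_alpha = 0,
                                        max_mendel_impossible = 1))
  expect_true(all(c(colnames(clean), "miss", "err") %in% out2$retained))
  # the retained set is order-invariant: recompute from permuted stats
  st_perm <- st[sample(nrow(st)), ]
  expect_setequal(filter_snps(st_perm, qc_thresholds())$retained,
                  out$retained)
})

test_that("monomorphic panels are fully filtered", {
  M <- matrix(0, 20, 5, dimnames = list(paste0("i", 1:20), paste0("s", 1:5)))
  out <- filter_snps(compute_snp_stats(M), qc_thresholds())
  expect_equal(length(out$retained), 0)
})

test_that("LD-kNN imputation is exact on perfect-LD duplicates and
           idempotent on complete data", {
  M <- small_trial_geno()[, 1:60]
  expect_identical(impute_ldknni(M, l = 10, k = 5), {
    M2 <- M
    storage.mode(M2) <- "double"
    M2
  })
  # duplicate column, one masked cell: the twin determines the value
  Md <- cbind(M, twin = M[, 13])
  Md[7, "twin"] <- NA
  imp <- impute_ldknni(Md, l = 10, k = 5)
  expect_equal(imp[7, "twin"], M[7, 13])
  expect_equal(imp[-7, "twin"], Md[-7, "twin"])  # observed cells untouched
})

test_that("imputation accuracy beats the modal baseline on block-LD data", {
  M <- small_trial_geno()[, 1:200]
  res <- imputation_accuracy(M, n_mask = 500, seed = 11, l = 30, k = 5)
  cells <- sprucegs:::with_seed(11, sample(which(!is.na(M)), 500))
  modal <- vapply(seq_len(ncol(M)),
                  function(s) sprucegs:::modal_genotype(M[, s]),
                  numeric(1))
  baseline <- mean(modal[arrayInd(cells, dim(M))[, 2]] == M[cells])
  expect_gt(res$accuracy, baseline)
  expect_gt(res$accuracy, 0.5)
  expect_lt(res$accuracy, 1.0)
  # reproducible under the same seed
  res2 <- imputation_accuracy(M, n_mask = 500, seed = 11, l = 30, k = 5)
  expect_identical(res$accuracy, res2$accuracy)
})

test_that("degenerate masking requests error out", {
  M <- small_trial_geno()[, 1:20]
  expect_error(imputation_accuracy(M, n_mask = 0), "positive")
  expect_error(imputation_accuracy(M, n_mask = length(M) + 1), "exceeds")
})

test_that("SNPs with too few observed calls fall back to the mode", {
  M <- hwe_panel(30, 10, seed = 4)
  M[1:28, 3] <- NA
  expect_warning(imp <- impute_ldknni(M, l = 5, k = 5), "modal")
  expect_false(anyNA(imp))
})
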