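# Candidate values with a known bivariate-normal structure.
make_candidates <- function(n = 1000, r = 0.6, seed = 1,
                            means = c(A = 2.5, B = 2.0)) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  vals <- cbind(A = z1, B = z2)
  rownames(vals) <- sprintf("c%04d", seq_len(n))
  fam <- setNames(sprintf("f%03d", rep(seq_len(n / 10), each = 10)),
                  rownames(vals))
  candidate_set(vals, means, fam)
}

test_that("truncation size uses round-half-up and stable tie order", {
  v <- setNames(rep(1, 1516), sprintf("t%04d", 1:1516))
  sel <- select_top(v, 0.05)
  expect_length(sel, 76)  # 0.05 * 1516 = 75.8 -> 76
  expect_equal(sel, names(v)[1:76])  # ties resolved by id order
  expect_length(select_top(setNames(rnorm(100), 1:100), 0.05), 5)
  expect_error(select_top(numeric(0), 0.05), "empty")
  expect_error(select_top(v, 0), "intensity")
  # deterministic given values
  v2 <- setNames(rnorm(200), sprintf("x%03d", 1:200))
  expect_identical(select_top(v2, 0.1), select_top(v2, 0.1))
})

test_that("gains are percentages of the phenotypic mean with family counts", {
  cand <- make_candidates(r = 0.6)
  sel <- select_top(setNames(cand$values[, "A"], cand$ids), 0.05)
  rep1 <- expected_gains(sel, cand)
  expect_length(rep1$selected, 50)
  expect_gt(rep1$gains["A"], 0)
  expect_gt(rep1$gains["B"], 0)  # positively correlated gain
  expect_lt(rep1$gains["B"], rep1$gains["A"] *
              cand$phenotypic_means["A"] / cand$phenotypic_means["B"])
  expect_lte(rep1$n_families, length(rep1$selected))
  # selecting everyone gains nothing (values are centred)
  all_rep <- expected_gains(cand$ids, cand)
  expect_lt(max(abs(all_rep$gains)), 2)
  # negatively correlated pair: correlated loss
  cand_neg <- make_candidates(r = -0.4, seed = 2)
  sel_neg <- select_top(setNames(cand_neg$values[, "A"], cand_neg$ids),
                        0.05)
  expect_lt(expected_gains(sel_neg, cand_neg)$gains["B"], 0)
  # zero mean is refused by name
  bad <- candidate_set(cand$values, c(A = 0, B = 1))
  expect_error(expected_gains(cand$ids[1:5], bad), "zero phenotypic mean")
})

test_that("gain matrix is diagonally dominant by column", {
  cand <- make_candidates(r = 0.6, seed = 3)
  gains <- sapply(c("A", "B"), function(tr) {
    sel <- select_top(setNames(cand$values[, tr], cand$ids), 0.05)
    expected_gains(sel, cand)$gains
  })
  # columns = selected-on trait; diagonal maximizes its own column
  expect_gte(gains["A", "A"], gains["A", "B"])
  expect_gte(gains["B", "B"], gains["B", "A"])
})

test_that("independent culling is bounded by unconstrained selection", {
  cand <- make_candidates(r = -0.4, seed = 5)
  un <- expected_gains(select_top(setNames(cand$values[, "A"], cand$ids),
                                  0.05), cand)
  cul <- independent_culling(cand, "A", c(B = 0), 0.05)
  expect_lte(cul$gains["A"], un$gains["A"])
  expect_gte(min(cand$values[cul$selected, "B"]), 0)
  expect_length(cul$selected, length(un$selected))
  # vacuous constraint reproduces plain truncation
  vac <- independent_culling(cand, "A", c(B = -Inf), 0.05)
  expect_setequal(vac$selected, un$selected)
  # impossible constraint: empty, flagged, no crash
  none <- independent_culling(cand, "A", c(B = Inf), 0.05)
  expect_length(none$selected, 0)
  expect_true(none$flag_short)
  expect_error(independent_culling(cand, "A", c(Z = 0)), "unknown")
})

test_that("index selection trades off correlated traits", {
  cand <- make_candidates(r = 0.6, seed = 7)
  single_A <- expected_gains(select_top(setNames(cand$values[, "A"],
                                                 cand$ids), 0.05), cand)
  single_B <- expected_gains(select_top(setNames(cand$values[, "B"],
                                                 cand$ids), 0.05), cand)
  idx <- selection_index(cand, c(A = 0.5, B = 0.5), 0.05)
  expect_gt(idx$gains["A"], 0)
  expect_gt(idx$gains["B"], 0)
  expect_lte(idx$gains["A"], single_A$gains["A"])
  expect_lte(idx$gains["B"], single_B$gains["B"])
  # single-trait weight reduces to truncation
  one <- selection_index(cand, c(A = 1), 0.05)
  expect_setequal(one$selected, single_A$selected)
  # perfectly correlated traits: index equals either single-trait choice
  dup <- candidate_set(cbind(A = cand$values[, "A"],
                             B = 2 * cand$values[, "A"]),
                       c(A = 1, B = 1))
  both <- selection_index(dup, c(A = 0.5, B = 0.5), 0.05)
  expect_setequal(both$selected,
                  select_top(setNames(dup$values[, "A"], dup$ids), 0.05))
  # degenerate index is refused
  flat_vals <- cbind(A = rep(1, 10), B = rnorm(10))
  rownames(flat_vals) <- paste0("q", 1:10)
  flat <- candidate_set(flat_vals, c(A = 1, B = 1))
  expect_error(selection_index(flat, c(A = 1)), "zero-variance")
})

test_that("correlation breakers combine both traits favourably", {
  cand <- make_candidates(r = -0.4, seed = 9)
  brk <- correlation_breakers(cand, "A", "B", 0.05)
  expect_equal(brk$strategy, "breaker")
  expect_gt(brk$gains["A"], 0)
  expect_gte(brk$gains["B"], 0)  # culling at zero forces non-negative mean
  un <- expected_gains(select_top(setNames(cand$values[, "A"], cand$ids),
                                  0.05), cand)
  expect_lte(brk$gains["A"], un$gains["A"])
  # all-positive secondary trait: identical to plain truncation
  pos <- candidate_set(cbind(A = cand$values[, "A"],
                             B = abs(cand$values[, "B"]) + 0.1),
                       c(A = 1, B = 1))
  expect_setequal(correlation_breakers(pos, "A", "B", 0.05)$selected,
                  select_top(setNames(pos$values[, "A"], pos$ids), 0.05))
})

test_that("unphenotyped candidates inherit BLUPs from the fit", {
  sim <- small_trial()
  M <- small_trial_geno()
  # append a clone: identical genotype row, never phenotyped
  M2 <- rbind(M, clone = M["P00001", ])
  # residual variances keep V nonsingular, so the duplicated row needs no
  # diagonal conditioning and the clone identity is exact
  G <- vanraden_G(M2)
  fit <- fit_univariate(sim$phenotypes, G, "PUNGENOL", transform = "sqrt")
  pred <- predict_unphenotyped(fit)
  expect_setequal(pred$id, G$ids)
  clone_vs_orig <- abs(pred$gebv[pred$id == "clone"] -
                         pred$gebv[pred$id == "P00001"])
  expect_lt(clone_vs_orig, 1e-8)
  # truly unphenotyped trees still track their true breeding values
  unph <- setdiff(sim$pedigree$id[sim$pedigree$cohort == "progeny"],
                  sim$phenotypes$tree)
  vals <- setNames(pred$gebv, pred$id)[unph]
  expect_gt(cor(vals, sim$truth$true_breeding_values[unph, "PUNGENOL"]),
            0.4)
  expect_error(predict_unphenotyped(fit, ids = c("nope", unph[1])),
               "absent")
  expect_equal(nrow(predict_unphenotyped(fit, ids = character(0))), 0)
})
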