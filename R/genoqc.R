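# SNP quality control and LD-kNN genotype imputation.

#' Per-SNP quality statistics
#'
#' Computes, per SNP: call rate, minor allele frequency on non-missing
#' calls, the fixation index `Fe = 1 - Hobs/Hexp` (with `Hexp = 2pq`;
#' undefined for monomorphic SNPs), a replicate discordance rate when
#' replicate sample pairs are supplied, and a Mendelian-segregation check
#' within full-sib families: a count of impossible parent-parent-child
#' configurations plus a chi-square test of observed versus expected
#' segregation ratios pooled over informative families (Bonferroni over
#' families).
#'
#' @param genotypes matrix of 0/1/2/NA, individuals in rows (rownames are
#'   ids), SNPs in columns.
#' @param pedigree optional pedigree data frame (`id`, `sire`, `dam`);
#'   needed for the Mendelian checks and only parents that are themselves
#'   genotyped contribute.
#' @param replicates optional two-column matrix/data frame of id pairs
#'   genotyped twice.
#' @return data frame with one row per SNP: `snp_id`, `call_rate`, `maf`,
#'   `fe`, `replicate_error_rate`, `mendel_impossible` (rate of impossible
#'   trios among informative trios), `mendel_p` (minimum Bonferroni-adjusted
#'   family segregation p-value; `NA` when no family is informative).
#' @export
compute_snp_stats <- function(genotypes, pedigree = NULL,
                              replicates = NULL) {
  M <- as.matrix(genotypes)
  storage.mode(M) <- "double"
  snps <- colnames(M)
  if (is.null(snps)) snps <- as.character(seq_len(ncol(M)))
  n <- nrow(M)
  obs <- !is.na(M)
  call_rate <- colMeans(obs)
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hobs <- colMeans(M == 1, na.rm = TRUE)
  hexp <- 2 * p * (1 - p)
  fe <- ifelse(hexp > 0, 1 - hobs / hexp, NA_real_)
  rep_err <- rep(NA_real_, ncol(M))
  if (!is.null(replicates)) {
    rp <- as.matrix(replicates)
    i1 <- match(rp[, 1], rownames(M))
    i2 <- match(rp[, 2], rownames(M))
    ok <- !is.na(i1) & !is.na(i2)
    if (any(ok)) {
      A1 <- M[i1[ok], , drop = FALSE]
      A2 <- M[i2[ok], , drop = FALSE]
      comp <- !is.na(A1) & !is.na(A2)
      disc <- comp & (A1 != A2)
      ncomp <- colSums(comp)
      rep_err <- ifelse(ncomp > 0, colSums(disc) / ncomp, NA_real_)
    }
  }
  mendel_imp <- rep(NA_real_, ncol(M))
  mendel_p <- rep(NA_real_, ncol(M))
  if (!is.null(pedigree)) {
    md <- mendel_checks(M, pedigree)
    mendel_imp <- md$impossible
    mendel_p <- md$p
  }
  data.frame(snp_id = snps, call_rate = call_rate, maf = maf, fe = fe,
             replicate_error_rate = rep_err,
             mendel_impossible = mendel_imp, mendel_p = mendel_p,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Expected offspring genotype distribution given parent genotypes.
mendel_expected <- function(gs, gd) {
  seg <- function(g) switch(as.character(g),
                            "0" = c(1, 0), "1" = c(0.5, 0.5),
                            "2" = c(0, 1))  # P(transmit ref), P(transmit alt)
  ps <- seg(gs); pd <- seg(gd)
  c(ps[1] * pd[1],                      # offspring 0
    ps[1] * pd[2] + ps[2] * pd[1],      # offspring 1
    ps[2] * pd[2])                      # offspring 2
}

mendel_checks <- function(M, pedigree) {
  ped <- validate_pedigree(pedigree)
  gi <- match(ped$id, rownames(M))
  si <- match(ped$sire, rownames(M))
  di <- match(ped$dam, rownames(M))
  trio <- which(!is.na(gi) & !is.na(si) & !is.na(di))
  m <- ncol(M)
  impossible <- rep(NA_real_, m)
  pval <- rep(NA_real_, m)
  if (!length(trio)) return(list(impossible = impossible, p = pval))
  fam_key <- paste(ped$sire[trio], ped$dam[trio])
  fams <- split(trio, fam_key)
  exp_tab <- lapply(0:2, function(gs) lapply(0:2, mendel_expected, gd = gs))
  for (s in seq_len(m)) {
    bad <- 0L; n_trio <- 0L
    chi_p <- c()
    for (rows in fams) {
      gS <- M[si[rows[1]], s]; gD <- M[di[rows[1]], s]
      if (is.na(gS) || is.na(gD)) next
      kid <- M[gi[rows], s]
      kid <- kid[!is.na(kid)]
      if (!length(kid)) next
      e <- exp_tab[[gS + 1]][[gD + 1]]
      n_trio <- n_trio + length(kid)
      bad <- bad + sum(e[kid + 1] == 0)
      inf <- e > 0 & e < 1
      if (sum(e > 0) > 1 && length(kid) >= 5) {
        o <- tabulate(kid + 1, 3)
        keep <- e > 0
        stat <- sum((o[keep] - length(kid) * e[keep])^2 /
                      (length(kid) * e[keep]))
        chi_p <- c(chi_p, pchisq(stat, df = sum(keep) - 1,
                                 lower.tail = FALSE))
      }
    }
    impossible[s] <- if (n_trio > 0) bad / n_trio else NA_real_
    pval[s] <- if (length(chi_p)) {
      min(pmin(chi_p * length(chi_p), 1))
    } else NA_real_
  }
  list(impossible = impossible, p = pval)
}

#' QC thresholds
#'
#' Defaults follow common SNP-array practice for full-sib trials: at most
#' 15% missing calls, MAF at least 0.01, absolute fixation index below
#' 0.50, replicate error rate below 2%, and a Mendelian-segregation alpha
#' of 0.001 with a hard fail when at least 1% of informative trios are
#' impossible.
#'
#' @param max_missing,min_maf,max_abs_fe,max_error_rate,mendel_alpha,max_mendel_impossible
#'   filter thresholds, all in `[0, 1]`.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(max_missing = 0.15, min_maf = 0.01,
                          max_abs_fe = 0.50, max_error_rate = 0.02,
                          mendel_alpha = 0.001,
                          max_mendel_impossible = 0.01) {
  th <- list(max_missing = max_missing, min_maf = min_maf,
             max_abs_fe = max_abs_fe, max_error_rate = max_error_rate,
             mendel_alpha = mendel_alpha,
             max_mendel_impossible = max_mendel_impossible)
  if (any(unlist(th) < 0 | unlist(th) > 1)) {
    stop("all thresholds must lie in [0, 1]")
  }
  th
}

#' Filter SNPs on QC statistics
#'
#' A SNP is retained iff it passes every filter; attrition is reported per
#' filter in application order (missingness, MAF, fixation index,
#' replicate error rate, Mendelian), so attrition counts depend on the
#' order while the retained set does not.  Statistics that are `NA`
#' (e.g. no replicates) do not fail their filter, except `fe`: a SNP with
#' undefined `fe` is monomorphic and already fails the MAF filter.
#' Setting a threshold to its vacuous limit (`max_abs_fe` or
#' `max_error_rate` of 1) disables that filter entirely.
#'
#' @param stats output of [compute_snp_stats()].
#' @param thresholds a [qc_thresholds()] list.
#' @return list with `retained` (character vector of SNP ids) and
#'   `attrition` (named integer vector of SNPs removed by each filter, in
#'   order).
#' @export
filter_snps <- function(stats, thresholds = qc_thresholds()) {
  th <- thresholds
  pass <- list(
    missing = stats$call_rate >= 1 - th$max_missing,
    maf = !is.na(stats$maf) & stats$maf >= th$min_maf & stats$maf > 0,
    fe = th$max_abs_fe >= 1 | is.na(stats$fe) |
      abs(stats$fe) < th$max_abs_fe,
    error_rate = th$max_error_rate >= 1 |
      is.na(stats$replicate_error_rate) |
      stats$replicate_error_rate < th$max_error_rate,
    mendel = (is.na(stats$mendel_impossible) |
                stats$mendel_impossible < th$max_mendel_impossible) &
      (is.na(stats$mendel_p) | stats$mendel_p >= th$mendel_alpha)
  )
  alive <- rep(TRUE, nrow(stats))
  attrition <- integer(length(pass))
  names(attrition) <- names(pass)
  for (i in seq_along(pass)) {
    removed <- alive & !pass[[i]]
    attrition[i] <- sum(removed)
    alive <- alive & pass[[i]]
  }
  list(retained = stats$snp_id[alive], attrition = attrition)
}

#' LD-kNN genotype imputation
#'
#' For each missing call at SNP `s` in individual `i`: the `l` SNPs in
#' highest r-squared with `s` (complete-pairs correlation) define a local
#' distance; every individual with an observed call at `s` is scored by
#' the mean absolute genotype difference to `i` over those `l` SNPs
#' (pairs observed in both), distances are offset by 1 so that identical
#' neighbours keep finite weight; the `k` nearest neighbours vote for a
#' genotype in {0, 1, 2} with weights `1/d^2` and the heaviest class is
#' imputed (ties go to the smaller genotype).  Observed cells are never
#' altered.  SNPs with fewer than `k` observed calls fall back to the
#' modal genotype with a warning.
#'
#' @param genotypes matrix of 0/1/2/NA.
#' @param l number of LD SNPs used for the distance (default 30).
#' @param k number of neighbours (default 5).
#' @return completed genotype matrix.
#' @export
impute_ldknni <- function(genotypes, l = 30, k = 5) {
  M <- as.matrix(genotypes)
  storage.mode(M) <- "double"
  if (!anyNA(M)) return(M)
  miss_snps <- which(colSums(is.na(M)) > 0)
  Mc <- M
  out <- M
  for (s in miss_snps) {
    obs_s <- which(!is.na(M[, s]))
    miss_i <- which(is.na(M[, s]))
    if (length(obs_s) < k) {
      warning("SNP ", colnames(M)[s] %||% s, " has fewer than k observed ",
              "calls; falling back to the modal genotype")
      out[miss_i, s] <- modal_genotype(M[, s])
      next
    }
    r <- suppressWarnings(cor(M[, s], M, use = "pairwise.complete.obs"))
    r2 <- drop(r)^2
    r2[s] <- -Inf
    r2[is.na(r2)] <- -Inf
    ld <- order(r2, decreasing = TRUE)[seq_len(min(l, ncol(M) - 1))]
    ld <- ld[is.finite(r2[ld])]
    if (!length(ld)) {
      out[miss_i, s] <- modal_genotype(M[, s])
      next
    }
    L <- M[, ld, drop = FALSE]
    for (i in miss_i) {
      diffs <- abs(sweep(L[obs_s, , drop = FALSE], 2, L[i, ], "-"))
      ncmp <- rowSums(!is.na(diffs))
      d <- rowSums(diffs, na.rm = TRUE) / pmax(ncmp, 1)
      d[ncmp == 0] <- Inf
      d <- d + 1  # offset: zero raw distance keeps finite 1/d^2 weight
      nb <- order(d)[seq_len(min(k, length(obs_s)))]
      w <- 1 / d[nb]^2
      g_nb <- M[obs_s[nb], s]
      score <- vapply(0:2, function(g) sum(w[g_nb == g]), numeric(1))
      out[i, s] <- (0:2)[which.max(score)]
    }
  }
  out
}

modal_genotype <- function(x) {
  tab <- tabulate(x[!is.na(x)] + 1, 3)
  (0:2)[which.max(tab)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Imputation accuracy by random masking
#'
#' Masks `n_mask` observed calls uniformly at random, re-imputes the
#' matrix with [impute_ldknni()] and returns the proportion of imputed
#' calls that equal the original values.
#'
#' @inheritParams impute_ldknni
#' @param n_mask number of observed cells to mask (must be positive and at
#'   most the number of observed cells).
#' @param seed integer seed for the masking.
#' @return list with `accuracy`, `n_mask`, and the per-cell comparison.
#' @export
imputation_accuracy <- function(genotypes, n_mask = 10000, seed = 1,
                                l = 30, k = 5) {
  M <- as.matrix(genotypes)
  storage.mode(M) <- "double"
  obs_cells <- which(!is.na(M))
  if (n_mask <= 0) stop("n_mask must be positive")
  if (n_mask > length(obs_cells)) {
    stop("n_mask exceeds the number of observed cells")
  }
  masked <- with_seed(seed, sample(obs_cells, n_mask))
  Mm <- M
  Mm[masked] <- NA
  imp <- impute_ldknni(Mm, l = l, k = k)
  correct <- imp[masked] == M[masked]
  list(accuracy = mean(correct), n_mask = n_mask,
       truth = M[masked], imputed = imp[masked])
}
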