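# Family-stratified replicated cross-validation: predictive ability (PA)
# and the three prediction-accuracy (PACC) definitions.

#' Family-stratified fold plan
#'
#' Within each repetition, each family's members are shuffled and dealt
#' round-robin to folds (with a random starting fold per family), so each
#' fold holds about 1/k of every family and fold sizes differ by at most
#' the number of families.
#'
#' @param pheno phenotype data frame with `tree` and `family`.
#' @param k folds (default 10).
#' @param reps repetitions (default 10).
#' @param seed integer seed.
#' @return object of class `fold_plan`: data frame `assignments`
#'   (`tree`, `rep`, `fold`) plus `k`, `reps`, `seed`.
#' @export
make_folds <- function(pheno, k = 10, reps = 10, seed = 1) {
  if (k < 2) stop("k must be at least 2")
  trees <- as.character(pheno$tree)
  fams <- as.character(pheno$family)
  if (k > length(trees)) stop("k exceeds the number of phenotyped trees")
  asg <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      fold <- integer(length(trees))
      for (f in unique(fams)) {
        rows <- which(fams == f)
        rows <- rows[sample.int(length(rows))]
        start <- sample.int(k, 1)
        fold[rows] <- ((start - 1 + seq_along(rows) - 1) %% k) + 1
      }
      data.frame(tree = trees, rep = r, fold = fold,
                 stringsAsFactors = FALSE)
    }))
  })
  structure(list(assignments = asg, k = k, reps = reps, seed = seed),
            class = "fold_plan")
}

#' Fixed-effect-adjusted phenotypes
#'
#' Residuals of the fixed-effects-only least-squares fit (overall mean,
#' site, test-within-site, age), i.e. the phenotype with the trial design
#' removed; these are the validation targets for predictive ability.
#'
#' @inheritParams fit_univariate
#' @return named numeric vector of adjusted phenotypes (one per
#'   phenotyped tree).
#' @export
adjusted_phenotypes <- function(pheno, trait, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  ph <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  y <- ph[[trait]]
  if (transform == "sqrt") y <- sqrt(y)
  X <- build_fixed_design(ph)
  setNames(lm.fit(X, y)$residuals, ph$tree)
}

#' Prediction accuracy from predictive ability
#'
#' `PACC = PA / sqrt(h2)` (use the broad-sense estimate for
#' additive-dominance models); the heritability should come from the
#' additive (resp. additive-dominance) GBLUP model so that pedigree-based,
#' genomic and Bayesian models are standardized on the same footing.
#'
#' @param pa predictive ability (Pearson correlation).
#' @param h2 heritability estimate in (0, 1].
#' @return numeric prediction accuracy.
#' @export
pacc_ratio <- function(pa, h2) {
  if (any(h2 <= 0)) stop("heritability must be positive")
  pa / sqrt(h2)
}

# BLUP prediction of held-out genetic values at fixed variance components.
blup_predict_heldout <- function(y_tr, X_tr, Qa_tr, Ka_val_tr, site_tr,
                                 comps, Qd_tr = NULL, Kd_val_tr = NULL) {
  n <- length(y_tr)
  V <- comps$sigma2_a * Qa_tr
  vd <- comps$sigma2_d %||% comps$sigma2_f
  if (!is.null(Qd_tr) && !is.null(vd)) V <- V + vd * Qd_tr
  ve <- comps$sigma2_e_by_site
  dg <- ve[match(as.character(site_tr), names(ve))]
  dg[is.na(dg)] <- comps$sigma2_e_bar
  diag(V) <- diag(V) + dg
  ch <- chol(V)
  ViX <- backsolve(ch, forwardsolve(t(ch), X_tr))
  Viy <- backsolve(ch, forwardsolve(t(ch), y_tr))
  beta <- solve(crossprod(X_tr, ViX), crossprod(X_tr, Viy))
  Pyr <- Viy - ViX %*% beta
  pred <- comps$sigma2_a * Ka_val_tr %*% Pyr
  if (!is.null(Kd_val_tr) && !is.null(vd)) {
    pred <- pred + vd * Kd_val_tr %*% Pyr
  }
  drop(pred)
}

#' Run replicated cross-validation
#'
#' For each repetition x fold: the model is trained on the other folds and
#' the held-out trees are predicted; held-out phenotypes never enter their
#' own predictions (test individuals contribute only their relationship
#' rows or marker genotypes).  For relationship-matrix models the variance
#' components are estimated once on the full data and each fold solves the
#' training-set BLUP at those components (set `reestimate = TRUE` for a
#' full REML fit per fold).  Per fold the function reports the predictive
#' ability `PA = cor(prediction, adjusted phenotype)` and three accuracy
#' definitions: `PA/sqrt(h2)` (or `sqrt(H2)` for additive-dominance
#' models), and the correlations with full-data pedigree-model and
#' genomic-model (G)E(B/G)Vs used as pseudo-true values (these pseudo-truth
#' variants are known to overestimate accuracy).
#'
#' @inheritParams fit_univariate
#' @param plan a [make_folds()] plan.
#' @param method `"blup"` (relationship-matrix models) or `"bayescpi"`
#'   (marker-effect sampler; requires `genotypes`).
#' @param genotypes complete genotype matrix for `method = "bayescpi"`.
#' @param h2_ref heritability used in `PA/sqrt(h2)`; defaults to the
#'   narrow-sense (or broad-sense for `ad` fits) estimate from the
#'   full-data fit of this model, but should be the GBLUP estimate when
#'   comparing model classes.
#' @param ref_ablup,ref_gblup named vectors of full-data (G)EBVs or
#'   (G)EGVs used as pseudo-true values (optional).
#' @param reestimate refit variance components within every training set.
#' @param bayes_config a [bayescpi_config()] for `method = "bayescpi"`.
#' @return object of class `gs_cv`: `folds` data frame (one row per
#'   rep x fold with `pa`, `pacc_h2`, `pacc_vs_ablup`, `pacc_vs_gblup`),
#'   `summary` (means and standard errors over all fits), `n_fits`,
#'   `h2_ref`, `failed`.
#' @export
run_cv <- function(pheno, trait, plan, K = NULL, dominance = NULL,
                   transform = c("none", "sqrt"),
                   method = c("blup", "bayescpi"), genotypes = NULL,
                   h2_ref = NULL, ref_ablup = NULL, ref_gblup = NULL,
                   reestimate = FALSE, bayes_config = NULL) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  ph <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  ystar <- adjusted_phenotypes(ph, trait, transform)
  y_all <- ph[[trait]]
  if (transform == "sqrt") y_all <- sqrt(y_all)
  if (method == "blup") {
    if (is.null(K)) stop("method = 'blup' needs a relationship matrix K")
    kin <- as_kinship(K)
    full <- fit_univariate(ph, kin, trait, dominance = dominance,
                           transform = transform)
    if (is.null(h2_ref)) {
      h <- heritability(full)
      h2_ref <- if (full$model_tag$effects == "ad") h$H2 else h$h2
    }
    idx <- match(ph$tree, kin$ids)
    Qa <- kin$values[idx, idx, drop = FALSE]
    dom <- resolve_dominance(dominance, ph, kin$ids)
  } else {
    if (is.null(genotypes)) stop("method = 'bayescpi' needs genotypes")
    if (is.null(bayes_config)) bayes_config <- bayescpi_config()
    if (is.null(h2_ref)) stop("h2_ref is required for method = 'bayescpi'")
    gm <- genotypes[as.character(ph$tree), , drop = FALSE]
    effects_kind <- if (is.null(dominance)) "a" else "ad"
  }
  asg <- plan$assignments
  asg <- asg[asg$tree %in% as.character(ph$tree), , drop = FALSE]
  rows <- list()
  failed <- 0L
  for (r in seq_len(plan$reps)) {
    asg_r <- asg[asg$rep == r, ]
    fold_of <- setNames(asg_r$fold, asg_r$tree)[as.character(ph$tree)]
    for (f in seq_len(plan$k)) {
      val <- which(fold_of == f)
      tr <- which(fold_of != f)
      if (length(val) < 3) next
      pred <- tryCatch({
        if (method == "blup") {
          comps <- if (reestimate) {
            fit_univariate(ph[tr, , drop = FALSE], kin, trait,
                           dominance = dominance,
                           transform = transform)$components
          } else full$components
          dom_tr <- if (!is.null(dominance)) {
            resolve_dominance(dominance, ph[tr, , drop = FALSE], kin$ids)
          } else NULL
          Kd_val_tr <- NULL
          Qd_tr <- NULL
          if (!is.null(dom_tr)) {
            if (dom_tr$kind == "matrix") {
              Qd_tr <- dom_tr$Q
              idx_d <- match(ph$tree, dom_tr$D$ids)
              Kd_val_tr <- dom_tr$D$values[idx_d[val], idx_d[tr],
                                           drop = FALSE]
            } else {
              fam <- as.character(ph$family)
              Qd_tr <- outer(fam[tr], fam[tr], "==") * 1
              Kd_val_tr <- outer(fam[val], fam[tr], "==") * 1
            }
          }
          blup_predict_heldout(
            y_all[tr], build_fixed_design(ph[tr, , drop = FALSE]),
            Qa[tr, tr, drop = FALSE], Qa[val, tr, drop = FALSE],
            ph$site[tr], comps, Qd_tr, Kd_val_tr)
        } else {
          eff <- fit_bayescpi(ph[tr, , drop = FALSE],
                              gm[tr, , drop = FALSE], trait = trait,
                              effects = effects_kind,
                              transform = transform,
                              config = bayes_config)
          pv <- predict_from_markers(eff, gm[val, , drop = FALSE])
          if (effects_kind == "ad") pv$gegv else pv$gebv
        }
      }, error = function(e) NULL)
      if (is.null(pred)) { failed <- failed + 1L; next }
      ys <- ystar[as.character(ph$tree[val])]
      rows[[length(rows) + 1]] <- data.frame(
        rep = r, fold = f, n_val = length(val),
        pa = cor(pred, ys),
        pacc_h2 = cor(pred, ys) / sqrt(h2_ref),
        pacc_vs_ablup = if (!is.null(ref_ablup)) {
          cor(pred, ref_ablup[as.character(ph$tree[val])])
        } else NA_real_,
        pacc_vs_gblup = if (!is.null(ref_gblup)) {
          cor(pred, ref_gblup[as.character(ph$tree[val])])
        } else NA_real_)
    }
  }
  folds <- do.call(rbind, rows)
  summ <- vapply(c("pa", "pacc_h2", "pacc_vs_ablup", "pacc_vs_gblup"),
                 function(cn) {
                   x <- folds[[cn]]
                   x <- x[!is.na(x)]
                   if (!length(x)) return(c(mean = NA_real_, se = NA_real_))
                   c(mean = mean(x), se = sd(x) / sqrt(length(x)))
                 }, numeric(2))
  structure(list(folds = folds, summary = t(summ), n_fits = nrow(folds),
                 h2_ref = h2_ref, failed = failed, trait = trait,
                 method = method),
            class = "gs_cv")
}

#' @export
print.gs_cv <- function(x, ...) {
  cat(sprintf("<gs_cv %s trait=%s: %d fits (%d failed)>\n", x$method,
              x$trait, x$n_fits, x$failed))
  print(round(x$summary, 4))
  invisible(x)
}
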