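# Ranking of genotyped candidates on predicted breeding / genetic values
# and expected multi-trait gains under four selection strategies.

#' Candidate set for selection
#'
#' @param values numeric matrix of predicted values (GEBV or GEGV),
#'   candidates in rows (rownames are ids), traits in columns.
#' @param phenotypic_means named per-trait population means on the
#'   analysis scale (gains are reported as a percentage of these).
#' @param family_of named character vector mapping candidate id to family.
#' @return object of class `gs_candidates`.
#' @export
candidate_set <- function(values, phenotypic_means, family_of = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("candidate values need rownames (ids)")
  if (anyNA(values)) stop("every candidate needs a value for every trait")
  traits <- colnames(values)
  if (!all(traits %in% names(phenotypic_means))) {
    stop("phenotypic_means missing for: ",
         paste(setdiff(traits, names(phenotypic_means)), collapse = ", "))
  }
  structure(list(ids = rownames(values), values = values,
                 phenotypic_means = phenotypic_means[traits],
                 family_of = family_of),
            class = "gs_candidates")
}

round_half_up <- function(x) floor(x + 0.5)

#' Truncation selection of the top fraction
#'
#' Selects `round-half-up(intensity * n)` candidates by descending value;
#' ties are broken by stable id order, so the result is deterministic.
#'
#' @param values named numeric vector of candidate values.
#' @param intensity selected fraction in (0, 1).
#' @return character vector of selected ids.
#' @export
select_top <- function(values, intensity = 0.05) {
  if (!length(values)) stop("empty candidate set")
  if (intensity <= 0 || intensity >= 1) stop("intensity must be in (0, 1)")
  n_sel <- round_half_up(intensity * length(values))
  ord <- order(-values, seq_along(values))
  names(values)[ord[seq_len(max(n_sel, 1))]]
}

#' Expected gains of a selected set
#'
#' For every trait, gain% = 100 x mean(predicted value of the selected
#' trees) / phenotypic mean; negative values are correlated losses.  Also
#' reports the number of distinct full-sib families among the selected
#' trees.
#'
#' @param selected character vector of selected candidate ids.
#' @param candidates a [candidate_set()].
#' @param strategy label stored in the report.
#' @param flag_short whether the target size could not be filled.
#' @return object of class `gs_selection`: `strategy`, `selected`,
#'   `gains` (named per-trait percentages), `n_families`, `flag_short`.
#' @export
expected_gains <- function(selected, candidates, strategy = "single",
                           flag_short = FALSE) {
  stopifnot(inherits(candidates, "gs_candidates"))
  if (any(candidates$phenotypic_means == 0)) {
    bad <- names(candidates$phenotypic_means)[
      candidates$phenotypic_means == 0]
    stop("zero phenotypic mean for trait: ", paste(bad, collapse = ", "))
  }
  missing <- setdiff(selected, candidates$ids)
  if (length(missing)) {
    stop("selected ids absent from the candidate set: ",
         paste(head(missing), collapse = ", "))
  }
  vals <- candidates$values[selected, , drop = FALSE]
  gains <- 100 * colMeans(vals) / candidates$phenotypic_means
  n_fam <- if (!is.null(candidates$family_of)) {
    length(unique(stats::na.omit(candidates$family_of[selected])))
  } else NA_integer_
  structure(list(strategy = strategy, selected = selected, gains = gains,
                 n_families = n_fam, flag_short = flag_short),
            class = "gs_selection")
}

#' @export
print.gs_selection <- function(x, ...) {
  cat(sprintf("<gs_selection %s: %d trees, %s families%s>\n", x$strategy,
              length(x$selected),
              ifelse(is.na(x$n_families), "?", x$n_families),
              if (x$flag_short) ", target size not reached" else ""))
  print(round(x$gains, 2))
  invisible(x)
}

#' Independent culling selection
#'
#' Candidates failing any secondary-trait threshold are culled, then the
#' survivors are ranked on the primary trait; the target size is the
#' intensity times the full candidate count.  If fewer survivors exist
#' than the target, all are selected and the report is flagged.
#'
#' @param candidates a [candidate_set()].
#' @param primary trait to rank on.
#' @param constraints named numeric vector: minimum value per secondary
#'   trait (e.g. `c(PUNGENOL = 0)` culls negative breeding values).
#' @param intensity selected fraction of the full candidate count.
#' @return `gs_selection` report.
#' @export
independent_culling <- function(candidates, primary, constraints,
                                intensity = 0.05) {
  stopifnot(inherits(candidates, "gs_candidates"))
  traits <- colnames(candidates$values)
  unknown <- setdiff(c(primary, names(constraints)), traits)
  if (length(unknown)) {
    stop("unknown traits: ", paste(unknown, collapse = ", "))
  }
  ok <- rep(TRUE, length(candidates$ids))
  for (tr in names(constraints)) {
    ok <- ok & candidates$values[, tr] >= constraints[[tr]]
  }
  n_target <- round_half_up(intensity * length(candidates$ids))
  pool <- candidates$values[ok, primary]
  names(pool) <- candidates$ids[ok]
  if (!length(pool)) {
    return(expected_gains(character(0), candidates,
                          strategy = "culling", flag_short = TRUE))
  }
  short <- length(pool) < n_target
  ord <- order(-pool, seq_along(pool))
  sel <- names(pool)[ord[seq_len(min(n_target, length(pool)))]]
  expected_gains(sel, candidates, strategy = "culling", flag_short = short)
}

#' Selection-index selection
#'
#' The index is the weighted sum of per-trait z-scores (value minus
#' candidate mean over candidate standard deviation); candidates are
#' ranked on the index and truncated as in [select_top()].
#'
#' @param candidates a [candidate_set()].
#' @param weights named numeric weights (nonzero for at least one trait).
#' @param intensity selected fraction.
#' @return `gs_selection` report.
#' @export
selection_index <- function(candidates, weights, intensity = 0.05) {
  stopifnot(inherits(candidates, "gs_candidates"))
  weights <- weights[weights != 0]
  if (!length(weights)) stop("at least one nonzero weight is required")
  unknown <- setdiff(names(weights), colnames(candidates$values))
  if (length(unknown)) stop("unknown traits: ", paste(unknown, collapse = ", "))
  idx <- rep(0, length(candidates$ids))
  for (tr in names(weights)) {
    v <- candidates$values[, tr]
    s <- sd(v)
    if (s == 0) stop("zero-variance trait in index: ", tr)
    idx <- idx + weights[[tr]] * (v - mean(v)) / s
  }
  names(idx) <- candidates$ids
  sel <- select_top(idx, intensity)
  expected_gains(sel, candidates, strategy = "index")
}

#' Correlation-breaker selection
#'
#' Among candidates with a non-negative value for the secondary trait,
#' selects the top fraction (of the full candidate count) on the primary
#' trait — i.e. trees that combine a favourable value on both traits of an
#' unfavourably correlated pair.
#'
#' @param candidates a [candidate_set()].
#' @param trait_a primary trait (ranked).
#' @param trait_b secondary trait (must be >= 0).
#' @param intensity selected fraction of the full candidate count.
#' @return `gs_selection` report.
#' @export
correlation_breakers <- function(candidates, trait_a, trait_b,
                                 intensity = 0.05) {
  stopifnot(inherits(candidates, "gs_candidates"))
  unknown <- setdiff(c(trait_a, trait_b), colnames(candidates$values))
  if (length(unknown)) stop("unknown traits: ", paste(unknown, collapse = ", "))
  rep_ <- independent_culling(candidates, primary = trait_a,
                              constraints = setNames(0, trait_b),
                              intensity = intensity)
  rep_$strategy <- "breaker"
  rep_
}

#' Predicted values for unphenotyped candidates
#'
#' Extracts or computes GEBV (and GEGV for additive-dominance fits) for a
#' set of candidate ids.  For relationship-matrix fits the values are the
#' conditional-expectation BLUPs already computed for every individual in
#' the relationship matrix; for BayesC-pi marker effects the values are
#' marker sums over the supplied genotypes.
#'
#' @param object a `gs_fit` (from [fit_univariate()]) or `gs_bayescpi`
#'   marker-effect object.
#' @param ids candidate ids (default: everything the fit can predict).
#' @param genotypes genotype matrix (required for marker effects).
#' @return data frame with `id`, `gebv` and (for `ad` fits) `gegv`.
#' @export
predict_unphenotyped <- function(object, ids = NULL, genotypes = NULL) {
  if (inherits(object, "gs_fit")) {
    vals <- object$ebv
    if (is.null(ids)) ids <- names(vals)
    missing <- setdiff(ids, names(vals))
    if (length(missing)) {
      stop("candidates absent from the relationship matrix: ",
           paste(head(missing), collapse = ", "))
    }
    out <- data.frame(id = ids, gebv = unname(vals[ids]),
                      stringsAsFactors = FALSE)
    if (!is.null(object$egv)) {
      miss2 <- setdiff(ids, names(object$egv))
      out$gegv <- ifelse(ids %in% names(object$egv),
                         unname(object$egv[match(ids, names(object$egv))]),
                         NA_real_)
      if (length(miss2) == 0) out$gegv <- unname(object$egv[ids])
    }
    out
  } else if (inherits(object, "gs_bayescpi")) {
    if (is.null(genotypes)) stop("marker effects need candidate genotypes")
    if (!is.null(ids)) {
      genotypes <- genotypes[ids, , drop = FALSE]
    }
    predict_from_markers(object, genotypes)
  } else {
    stop("unsupported object for prediction")
  }
}
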