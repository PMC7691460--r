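# Individual-tree mixed models: univariate and bivariate additive and
# additive-dominance REML fits with site-heterogeneous residual variances,
# heritability ratios with delta-method standard errors, likelihood-ratio
# tests on variance components, and information criteria.

#' Fixed-effect design for trial phenotypes
#'
#' Overall mean, site, test-within-site (site x test dummies with aliased
#' columns dropped) and centred tree age as a covariate.  Factors with a
#' single level and constant covariates are dropped so the design is
#' always full column rank.
#'
#' @param pheno data frame with columns `site`, `test`, `age`.
#' @return numeric design matrix.
#' @export
build_fixed_design <- function(pheno) {
  n <- nrow(pheno)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  site <- factor(pheno$site)
  if (nlevels(site) > 1) {
    X <- cbind(X, model.matrix(~site)[, -1, drop = FALSE])
  }
  tw <- droplevels(interaction(pheno$site, pheno$test, drop = TRUE,
                               sep = ":"))
  if (nlevels(tw) > nlevels(site)) {
    Xt <- model.matrix(~tw)[, -1, drop = FALSE]
    colnames(Xt) <- sub("^tw", "test", colnames(Xt))
    X <- cbind(X, Xt)
  }
  if (!is.null(pheno$age) && length(unique(pheno$age)) > 1) {
    X <- cbind(X, age = pheno$age - mean(pheno$age))
  }
  drop_aliased(X)
}

drop_aliased <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

resolve_dominance <- function(dominance, pheno_sub, ids_K) {
  if (is.null(dominance)) return(NULL)
  if (identical(dominance, "family")) {
    fam <- factor(pheno_sub$family)
    if (nlevels(fam) < 2) stop("family dominance term needs >= 2 families")
    Zf <- model.matrix(~ fam - 1)
    list(kind = "family", Q = tcrossprod(Zf), Zf = Zf,
         fam_levels = levels(fam))
  } else {
    D <- as_kinship(dominance, "G_Dom")
    idx <- match(pheno_sub$tree, D$ids)
    if (anyNA(idx)) {
      stop("phenotyped trees missing from the dominance matrix: ",
           paste(head(pheno_sub$tree[is.na(idx)]), collapse = ", "))
    }
    list(kind = "matrix", Q = D$values[idx, idx, drop = FALSE], D = D,
         idx = idx)
  }
}

#' Fit a univariate additive or additive-dominance mixed model by REML
#'
#' Fits `y = X beta + Z1 a + [Z2 d] + e` with `a ~ N(0, sigma_a^2 K)`,
#' an optional dominance term (a second relationship matrix such as the
#' Vitezica dominance matrix, or `"family"` for the full-sib family
#' identity parameterization), and residuals block-diagonal by site with
#' one variance per site.  Estimation is by average-information REML with
#' monotone step halving; BLUPs of the additive (and dominance) effects
#' are computed for every individual in the relationship matrix at the
#' converged components, so genotyped-but-unphenotyped candidates receive
#' predictions from the same fit.
#'
#' @param pheno phenotype data frame (`tree`, `family`, `site`, `test`,
#'   `age`, trait columns).
#' @param K relationship matrix (`gs_kinship` from [pedigree_to_A()] or
#'   [vanraden_G()], or a plain symmetric matrix with rownames); `NULL`
#'   drops the additive term (used as the reduced model in
#'   likelihood-ratio tests of the additive variance).
#' @param trait name of the trait column.
#' @param dominance `NULL`, a `gs_kinship`/matrix for genomic dominance,
#'   or `"family"` for the family-variance parameterization.
#' @param transform `"none"` or `"sqrt"` (applied to the trait before
#'   fitting; used for right-skewed metabolite traits).
#' @param maxit,tol_ll,tol_par passed to the REML engine.
#' @return object of class `gs_fit` with elements `components` (variance
#'   components incl. per-site residuals and their mean, log-likelihood and
#'   the AI covariance of the estimates), `beta_hat`, `ebv`, `dom_blup`,
#'   `egv`, `model_tag`, `n`, `rank_X`, `trace`.
#' @export
fit_univariate <- function(pheno, K, trait, dominance = NULL,
                           transform = c("none", "sqrt"),
                           maxit = 100, tol_ll = 1e-6, tol_par = 1e-8) {
  transform <- match.arg(transform)
  kin <- if (!is.null(K)) as_kinship(K) else NULL
  ph <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  y <- ph[[trait]]
  if (transform == "sqrt") {
    if (any(y < 0)) stop("sqrt transform requires non-negative trait values")
    y <- sqrt(y)
  }
  if (!all(is.finite(y))) stop("non-finite trait values after transform")
  if (!is.null(kin)) {
    idx <- match(ph$tree, kin$ids)
    if (anyNA(idx)) {
      stop("phenotyped trees missing from the relationship matrix: ",
           paste(head(ph$tree[is.na(idx)]), collapse = ", "))
    }
  }
  X <- build_fixed_design(ph)
  site <- factor(ph$site)
  sites <- levels(site)
  dom <- resolve_dominance(dominance, ph, if (!is.null(kin)) kin$ids)
  bases <- list()
  nm <- character(0)
  if (!is.null(kin)) {
    Qa <- kin$values[idx, idx, drop = FALSE]
    bases <- list(Qa)
    nm <- "sigma2_a"
  }
  if (!is.null(dom)) {
    bases <- c(bases, list(dom$Q))
    nm <- c(nm, if (dom$kind == "family") "sigma2_f" else "sigma2_d")
  }
  for (s in sites) bases <- c(bases, list(list(diag = as.numeric(site == s))))
  nm <- c(nm, paste0("sigma2_e_", sites))
  v0 <- var(lm.fit(X, y)$residuals)
  theta0 <- c(if (!is.null(kin)) v0 / 3, if (!is.null(dom)) v0 / 6,
              rep(v0 / 2, length(sites)))
  par <- reml_linear_par(bases, nm, lower = rep(1e-8 * v0, length(nm)))
  fit <- reml_fit_engine(y, X, par, theta0, maxit = maxit,
                         tol_ll = tol_ll, tol_par = tol_par)
  if (!fit$converged) {
    stop("REML did not converge in ", maxit, " iterations; trace:\n",
         paste(utils::capture.output(print(utils::tail(fit$trace, 5))),
               collapse = "\n"))
  }
  th <- fit$theta
  ve_site <- th[grep("^sigma2_e_", names(th))]
  names(ve_site) <- sites
  comp <- list(sigma2_a = if (!is.null(kin)) unname(th["sigma2_a"]) else NULL,
               sigma2_d = if (!is.null(dom) && dom$kind == "matrix")
                 unname(th["sigma2_d"]) else NULL,
               sigma2_f = if (!is.null(dom) && dom$kind == "family")
                 unname(th["sigma2_f"]) else NULL,
               sigma2_e_by_site = ve_site,
               sigma2_e_bar = mean(ve_site),
               loglik = fit$loglik, ai_cov = fit$ai_cov,
               theta = th)
  # BLUPs: cov(a_all, y) = sigma_a^2 K[all, pheno]
  ebv <- NULL
  if (!is.null(kin)) {
    ebv <- drop(comp$sigma2_a * kin$values[, idx, drop = FALSE] %*% fit$Py)
    names(ebv) <- kin$ids
  }
  dom_blup <- NULL
  egv <- NULL
  if (!is.null(dom)) {
    if (dom$kind == "matrix") {
      dhat <- drop(th["sigma2_d"] *
                     dom$D$values[, dom$idx, drop = FALSE] %*% fit$Py)
      names(dhat) <- dom$D$ids
      dom_blup <- dhat
      common <- intersect(kin$ids, dom$D$ids)
      egv <- ebv[common] + dhat[common]
    } else {
      fhat <- drop(th["sigma2_f"] * crossprod(dom$Zf, fit$Py))
      names(fhat) <- dom$fam_levels
      dom_blup <- fhat
      fam_of <- setNames(as.character(ph$family), ph$tree)
      if (!is.null(ebv)) {
        egv <- ebv[names(fam_of)] + fhat[fam_of]
        names(egv) <- names(fam_of)
      }
    }
  }
  model <- if (is.null(kin)) "resid"
           else if (kin$kind == "A") "ABLUP"
           else if (kin$kind == "G") "GBLUP" else kin$kind
  structure(list(components = comp,
                 beta_hat = setNames(fit$beta, colnames(X)),
                 ebv = ebv, dom_blup = dom_blup, egv = egv,
                 model_tag = list(model = model,
                                  effects = if (is.null(dom)) "a" else "ad",
                                  dominance_kind = if (is.null(dom)) NULL
                                                   else dom$kind),
                 trait = trait, transform = transform,
                 n = fit$n, rank_X = fit$rank_X, converged = fit$converged,
                 trace = fit$trace),
            class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("<gs_fit %s-%s trait=%s n=%d loglik=%.3f>\n",
              x$model_tag$model, x$model_tag$effects, x$trait, x$n,
              x$components$loglik))
  comps <- x$components
  cat(sprintf("  sigma2_a = %.4g", comps$sigma2_a))
  if (!is.null(comps$sigma2_d)) cat(sprintf("  sigma2_d = %.4g", comps$sigma2_d))
  if (!is.null(comps$sigma2_f)) cat(sprintf("  sigma2_f = %.4g", comps$sigma2_f))
  cat(sprintf("  mean sigma2_e = %.4g\n", comps$sigma2_e_bar))
  invisible(x)
}

num_gradient <- function(f, x, eps = NULL) {
  if (is.null(eps)) eps <- pmax(abs(x), 1e-8) * 1e-6
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    xp <- x; xm <- x
    xp[k] <- x[k] + eps[k]
    xm[k] <- max(x[k] - eps[k], 0)
    g[k] <- (f(xp) - f(xm)) / (xp[k] - xm[k])
  }
  g
}

#' Heritability ratios with delta-method standard errors
#'
#' Narrow-sense heritability uses the additive variance over the
#' phenotypic variance (additive [+ dominance] + mean residual across
#' sites).  For the family-variance (ABLUP) dominance parameterization the
#' dominance fraction is `4 sigma_f^2` over the phenotypic variance (the
#' full-sib family variance captures one quarter of the dominance
#' variance), and the broad-sense numerator is `sigma_a^2 + 4 sigma_f^2`.
#' For genomic dominance the fractions are the plain variance ratios and
#' `d2 = H2 - h2`.  Standard errors propagate the AI covariance of the
#' variance components through the ratios (first-order delta method).
#'
#' @param fit a `gs_fit` from [fit_univariate()].
#' @return list with `h2`, `d2`, `H2` and `se_h2`, `se_d2`, `se_H2`
#'   (`d2`/`H2` are `NA` for additive-only fits).
#' @export
heritability <- function(fit) {
  comp <- fit$components
  th <- comp$theta
  ns <- length(comp$sigma2_e_by_site)
  e_idx <- grep("^sigma2_e_", names(th))
  ratio_fns <- heritability_fns(fit$model_tag, names(th), e_idx)
  tot0 <- ratio_fns$ptot(th)
  if (tot0 <= 0) stop("zero total variance: heritability undefined")
  C <- comp$ai_cov
  out <- list()
  for (what in c("h2", "d2", "H2")) {
    fn <- ratio_fns[[what]]
    if (is.null(fn)) {
      out[[what]] <- NA_real_
      out[[paste0("se_", what)]] <- NA_real_
      next
    }
    val <- fn(th)
    g <- num_gradient(fn, th)
    se <- if (all(is.finite(C))) sqrt(max(drop(t(g) %*% C %*% g), 0))
          else NA_real_
    out[[what]] <- val
    out[[paste0("se_", what)]] <- se
  }
  out
}

heritability_fns <- function(tag, nm, e_idx) {
  ebar <- function(th) mean(th[e_idx])
  if (tag$effects == "a") {
    ptot <- function(th) th["sigma2_a"] + ebar(th)
    list(ptot = ptot,
         h2 = function(th) unname(th["sigma2_a"] / ptot(th)),
         d2 = NULL, H2 = NULL)
  } else if (identical(tag$dominance_kind, "family")) {
    ptot <- function(th) th["sigma2_a"] + th["sigma2_f"] + ebar(th)
    list(ptot = ptot,
         h2 = function(th) unname(th["sigma2_a"] / ptot(th)),
         d2 = function(th) unname(4 * th["sigma2_f"] / ptot(th)),
         H2 = function(th) unname((th["sigma2_a"] + 4 * th["sigma2_f"]) /
                                    ptot(th)))
  } else {
    ptot <- function(th) th["sigma2_a"] + th["sigma2_d"] + ebar(th)
    list(ptot = ptot,
         h2 = function(th) unname(th["sigma2_a"] / ptot(th)),
         d2 = function(th) unname(th["sigma2_d"] / ptot(th)),
         H2 = function(th) unname((th["sigma2_a"] + th["sigma2_d"]) /
                                    ptot(th)))
  }
}

#' Likelihood-ratio test for a variance component
#'
#' The reduced model must be the full model with one variance dropped
#' (identical parameter sets are tolerated and give a zero statistic).
#' Because the null value lies on the boundary of the parameter space, the
#' statistic is referred to the equal mixture of a point mass at zero and
#' a chi-square with one degree of freedom; the reported p-value is
#' `0.5 * P(chi2_1 >= stat)` (so two identical fits give p = 0.5, not
#' significant).
#'
#' @param full,reduced `gs_fit` objects on the same data.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
lrt_variance <- function(full, reduced) {
  nf <- names(full$components$theta)
  nr <- names(reduced$components$theta)
  if (full$n != reduced$n || !all(nr %in% nf) ||
      length(setdiff(nf, nr)) > 1) {
    stop("models are not nested with one variance dropped")
  }
  stat <- max(0, 2 * (full$components$loglik - reduced$components$loglik))
  list(statistic = stat,
       p_value = 0.5 * pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1)
}

#' Information criteria for a REML fit
#'
#' `AIC = -2 loglik + 2 k`, `BIC = -2 loglik + k log(n - rank X)` with `k`
#' the number of estimated variance parameters and residual degrees of
#' freedom in the BIC sample size.
#'
#' @param fit `gs_fit`.
#' @return list with `AIC`, `BIC`, `k`.
#' @export
information_criteria <- function(fit) {
  k <- length(fit$components$theta)
  ll <- fit$components$loglik
  list(AIC = -2 * ll + 2 * k,
       BIC = -2 * ll + k * log(fit$n - fit$rank_X),
       k = k)
}

block2 <- function(Q, pos) {
  n <- nrow(Q)
  B <- matrix(0, 2 * n, 2 * n)
  if (pos == 11) B[1:n, 1:n] <- Q
  else if (pos == 22) B[n + 1:n, n + 1:n] <- Q
  else { B[1:n, n + 1:n] <- Q; B[n + 1:n, 1:n] <- Q }
  B
}

#' Fit a bivariate mixed model and estimate genetic correlations
#'
#' Stacks the two traits measured on the same trees and fits the CORGH
#' parameterization: per-trait additive (and optional dominance) variances
#' with a correlation, per-trait residual variances with a residual
#' correlation shared by co-measured observations.  Starting values come
#' from univariate fits with correlations started at zero.  Returns the
#' additive correlation `ra` (and `rd` if dominance is fitted), the
#' residual correlation `re`, the total genetic correlation `rg`
#' (additive + dominance covariance over the geometric-mean total genetic
#' variances) and the phenotypic correlation `rp`, with likelihood-ratio
#' p-values against the models with the genetic (respectively all)
#' correlations fixed at zero.
#'
#' @inheritParams fit_univariate
#' @param traits character vector of two trait names.
#' @param transform per-trait transforms, recycled to length 2.
#' @param lrt also fit the reduced models (correlations fixed at zero)
#'   for the likelihood-ratio p-values; skipping them roughly halves the
#'   run time when only the estimates are needed.
#' @return object of class `gs_bifit`.
#' @export
fit_bivariate <- function(pheno, K, traits, dominance = NULL,
                          transform = "none", maxit = 100, lrt = TRUE) {
  stopifnot(length(traits) == 2)
  transform <- rep_len(transform, 2)
  kin <- as_kinship(K)
  keep <- !is.na(pheno[[traits[1]]]) & !is.na(pheno[[traits[2]]])
  ph <- pheno[keep, , drop = FALSE]
  n <- nrow(ph)
  ylist <- lapply(1:2, function(t) {
    y <- ph[[traits[t]]]
    if (transform[t] == "sqrt") y <- sqrt(y)
    y
  })
  y <- c(ylist[[1]], ylist[[2]])
  idx <- match(ph$tree, kin$ids)
  if (anyNA(idx)) stop("phenotyped trees missing from relationship matrix")
  X1 <- build_fixed_design(ph)
  p <- ncol(X1)
  X <- rbind(cbind(X1, matrix(0, n, p)), cbind(matrix(0, n, p), X1))
  Qa <- kin$values[idx, idx, drop = FALSE]
  dom <- resolve_dominance(dominance, ph, kin$ids)
  has_d <- !is.null(dom)
  uni <- lapply(1:2, function(t) {
    fit_univariate(ph, kin, traits[t], dominance = dominance,
                   transform = transform[t], tol_par = 1e-6)
  })
  bases <- list(block2(Qa, 11), block2(Qa, 22), block2(Qa, 12))
  nm <- c("va1", "va2", "ra")
  if (has_d) {
    bases <- c(bases, list(block2(dom$Q, 11), block2(dom$Q, 22),
                           block2(dom$Q, 12)))
    nm <- c(nm, "vd1", "vd2", "rd")
  }
  I2 <- diag(n)
  bases <- c(bases, list(list(diag = rep(c(1, 0), each = n)),
                         list(diag = rep(c(0, 1), each = n)),
                         block2(I2, 12)))
  nm <- c(nm, "ve1", "ve2", "re")
  vy <- vapply(ylist, var, numeric(1))
  lower_v <- 1e-8 * mean(vy)
  make_par <- function(free_corr) {
    is_corr <- nm %in% c("ra", "rd", "re")
    fixed_zero <- is_corr & !(nm %in% free_corr)
    coef <- function(theta) {
      cf <- numeric(length(nm))
      for (i in seq_along(nm)) {
        cf[i] <- switch(nm[i],
          va1 = theta["va1"], va2 = theta["va2"],
          ra = if ("ra" %in% free_corr)
                 theta["ra"] * sqrt(theta["va1"] * theta["va2"]) else 0,
          vd1 = theta["vd1"], vd2 = theta["vd2"],
          rd = if ("rd" %in% free_corr)
                 theta["rd"] * sqrt(theta["vd1"] * theta["vd2"]) else 0,
          ve1 = theta["ve1"], ve2 = theta["ve2"],
          re = if ("re" %in% free_corr)
                 theta["re"] * sqrt(theta["ve1"] * theta["ve2"]) else 0)
      }
      cf
    }
    pnames <- nm[!fixed_zero]
    jac <- function(theta) {
      J <- matrix(0, length(nm), length(pnames),
                  dimnames = list(nm, pnames))
      for (v in intersect(pnames, c("va1", "va2", "vd1", "vd2",
                                    "ve1", "ve2"))) J[v, v] <- 1
      dcorr <- function(r, v1, v2) {
        if (!(r %in% pnames)) return()
        J[r, r] <<- sqrt(theta[v1] * theta[v2])
        J[r, v1] <<- J[r, v1] +
          0.5 * theta[r] * sqrt(theta[v2] / max(theta[v1], 1e-12))
        J[r, v2] <<- J[r, v2] +
          0.5 * theta[r] * sqrt(theta[v1] / max(theta[v2], 1e-12))
      }
      dcorr("ra", "va1", "va2")
      if (has_d) dcorr("rd", "vd1", "vd2")
      dcorr("re", "ve1", "ve2")
      J
    }
    list(bases = lapply(bases, normalize_base),
         coef = function(theta) coef(setNames(theta, pnames)),
         jac = function(theta) jac(setNames(theta, pnames)),
         lower = ifelse(pnames %in% c("ra", "rd", "re"), -0.999, lower_v),
         is_corr = pnames %in% c("ra", "rd", "re"),
         names = pnames)
  }
  start_for <- function(pnames) {
    va <- vapply(uni, function(f) f$components$sigma2_a, numeric(1))
    vd <- if (has_d) {
      vapply(uni, function(f) {
        c0 <- f$components
        if (!is.null(c0$sigma2_d)) c0$sigma2_d else c0$sigma2_f
      }, numeric(1))
    } else c(NA, NA)
    ve <- vapply(uni, function(f) f$components$sigma2_e_bar, numeric(1))
    full <- c(va1 = va[1], va2 = va[2], ra = 0,
              vd1 = vd[1], vd2 = vd[2], rd = 0,
              ve1 = ve[1], ve2 = ve[2], re = 0)
    pmax(full[pnames], ifelse(pnames %in% c("ra", "rd", "re"),
                              -0.999, lower_v))
  }
  fit_one <- function(free_corr) {
    par <- make_par(free_corr)
    reml_fit_engine(y, X, par, start_for(par$names), maxit = maxit,
                    tol_ll = 1e-6, tol_par = 1e-6)
  }
  all_corr <- c("ra", if (has_d) "rd", "re")
  full <- fit_one(all_corr)
  red_gen <- if (lrt) fit_one("re") else NULL
  red_all <- if (lrt) fit_one(character(0)) else NULL
  th <- full$theta
  gv1 <- th["va1"] + if (has_d) th["vd1"] else 0
  gv2 <- th["va2"] + if (has_d) th["vd2"] else 0
  cov_g <- th["ra"] * sqrt(th["va1"] * th["va2"]) +
    if (has_d) th["rd"] * sqrt(th["vd1"] * th["vd2"]) else 0
  rg <- unname(cov_g / sqrt(gv1 * gv2))
  cov_p <- cov_g + th["re"] * sqrt(th["ve1"] * th["ve2"])
  rp <- unname(cov_p / sqrt((gv1 + th["ve1"]) * (gv2 + th["ve2"])))
  df_gen <- 1 + has_d
  stat_gen <- if (lrt) max(0, 2 * (full$loglik - red_gen$loglik)) else NA
  stat_phe <- if (lrt) max(0, 2 * (full$loglik - red_all$loglik)) else NA
  se_ra <- sqrt(max(full$ai_cov["ra", "ra"], 0))
  structure(list(
    ra = unname(th["ra"]), rd = if (has_d) unname(th["rd"]) else NA_real_,
    re = unname(th["re"]), rg = rg, rp = rp, se_ra = se_ra,
    variances = th[!grepl("^r", names(th))],
    loglik = full$loglik,
    lrt_p_genetic = if (lrt) pchisq(stat_gen, df_gen, lower.tail = FALSE)
                    else NA_real_,
    lrt_p_phenotypic = if (lrt) pchisq(stat_phe, df_gen + 1,
                                       lower.tail = FALSE) else NA_real_,
    converged = full$converged, traits = traits, n = n,
    model_tag = list(model = if (kin$kind == "A") "ABLUP" else "GBLUP",
                     effects = if (has_d) "ad" else "a")),
    class = "gs_bifit")
}

#' @export
print.gs_bifit <- function(x, ...) {
  cat(sprintf("<gs_bifit %s-%s %s~%s n=%d>\n", x$model_tag$model,
              x$model_tag$effects, x$traits[1], x$traits[2], x$n))
  cat(sprintf("  ra = %.3f (se %.3f)  re = %.3f  rg = %.3f  rp = %.3f\n",
              x$ra, x$se_ra, x$re, x$rg, x$rp))
  invisible(x)
}
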