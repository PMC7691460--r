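# Dense average-information REML engine.
#
# The variance model is V(theta) = sum_i c_i(theta) * B_i where each base
# B_i is either a dense symmetric n x n matrix or a diagonal matrix stored
# as a vector.  Variance parameters enter linearly (c_i = theta_k);
# correlation parameters enter through products such as r * sqrt(v1 * v2),
# which is how the bivariate CORGH structure is expressed.  All traces
# needed for the score reduce to elementwise sums against P, so each
# iteration costs one Cholesky factorization and one symmetric inverse.

#' Build a linear variance parameterization
#'
#' Helper for the common case where every parameter is itself the
#' coefficient of one base matrix (univariate additive / additive-dominance
#' models with per-site residual variances).
#'
#' @param bases list of bases; each element is either a symmetric numeric
#'   matrix or a list `list(diag = d)` holding the diagonal as a vector.
#' @param names parameter names.
#' @param lower lower bounds (defaults to 0 for every parameter).
#' @return parameterization object for [reml_fit_engine()].
#' @keywords internal
#' @noRd
reml_linear_par <- function(bases, names, lower = NULL) {
  m <- length(bases)
  if (is.null(lower)) lower <- rep(0, m)
  list(
    bases = lapply(bases, normalize_base),
    coef = function(theta) theta,
    jac = function(theta) diag(m),
    lower = lower,
    is_corr = rep(FALSE, m),
    names = names
  )
}

normalize_base <- function(b) {
  if (is.list(b)) {
    stopifnot(!is.null(b$diag))
    list(type = "diag", d = as.numeric(b$diag))
  } else if (is.matrix(b)) {
    list(type = "dense", M = b)
  } else {
    list(type = "diag", d = as.numeric(b))
  }
}

base_times_vec <- function(b, v) {
  if (b$type == "dense") drop(b$M %*% v) else b$d * v
}

trace_P_base <- function(P, diagP, b) {
  if (b$type == "dense") sum(P * b$M) else sum(diagP * b$d)
}

assemble_V <- function(bases, cf, n) {
  V <- matrix(0, n, n)
  dg <- numeric(n)
  for (i in seq_along(bases)) {
    b <- bases[[i]]
    if (cf[i] == 0) next
    if (b$type == "dense") V <- V + cf[i] * b$M else dg <- dg + cf[i] * b$d
  }
  if (any(dg != 0)) diag(V) <- diag(V) + dg
  V
}

# Cheap restricted log-likelihood at theta (one Cholesky, no inverse).
reml_loglik_at <- function(theta, y, X, par) {
  cf <- par$coef(theta)
  n <- length(y)
  V <- assemble_V(par$bases, cf, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  ViX <- backsolve(ch, forwardsolve(t(ch), X))
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, ViX)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(-Inf)
  XtViy <- crossprod(X, Viy)
  beta <- backsolve(chX, forwardsolve(t(chX), XtViy))
  yPy <- sum(y * Viy) - sum(XtViy * beta)
  -0.5 * (logdetV + 2 * sum(log(diag(chX))) + yPy)
}

# Full state: loglik plus P, Py and projections needed for score/AI.
reml_state_at <- function(theta, y, X, par) {
  cf <- par$coef(theta)
  n <- length(y)
  V <- assemble_V(par$bases, cf, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  XtViX_inv <- chol2inv(chX)
  P <- Vi - ViX %*% tcrossprod(XtViX_inv, ViX)
  Py <- drop(P %*% y)
  beta <- drop(XtViX_inv %*% crossprod(X, Vi %*% y))
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                  sum(y * Py))
  list(theta = theta, cf = cf, ll = ll, P = P, Py = Py, Vi = Vi,
       ViX = ViX, XtViX_inv = XtViX_inv, beta = beta)
}

project_theta <- function(theta, par) {
  for (k in seq_along(theta)) {
    if (par$is_corr[k]) {
      theta[k] <- min(max(theta[k], -0.999), 0.999)
    } else {
      theta[k] <- max(theta[k], par$lower[k])
    }
  }
  theta
}

#' Average-information REML driver
#'
#' Maximizes the restricted log-likelihood of `y = X beta + e`,
#' `e ~ N(0, V(theta))`, by AI updates with step halving (the AI matrix is
#' positive semi-definite, so the proposed direction is an ascent direction
#' and halving guarantees a monotone log-likelihood path).  Variance
#' parameters are projected onto their lower bound; bound-stuck parameters
#' with an outward score are frozen out of the update.
#'
#' @param y numeric response (already transformed).
#' @param X fixed-effect design matrix, full column rank.
#' @param par parameterization (see [reml_linear_par()]).
#' @param theta0 starting values.
#' @param maxit,tol_ll,tol_par iteration cap and convergence tolerances:
#'   convergence requires the log-likelihood change below `tol_ll` and the
#'   relative parameter change below `tol_par`.
#' @return list with `theta`, `loglik`, `ai_cov`, `beta`, `converged`,
#'   per-iteration `trace`, and the internal state needed for BLUPs.
#' @keywords internal
#' @noRd
reml_fit_engine <- function(y, X, par, theta0, maxit = 100,
                            tol_ll = 1e-6, tol_par = 1e-8) {
  theta <- project_theta(theta0, par)
  st <- reml_state_at(theta, y, X, par)
  if (is.null(st)) stop("REML: starting values give a singular variance matrix")
  trace <- data.frame(iter = 0, loglik = st$ll,
                      t(setNames(theta, par$names)), check.names = FALSE)
  converged <- FALSE
  AI <- NULL
  nt <- length(theta)
  for (iter in seq_len(maxit)) {
    J <- par$jac(theta)
    diagP <- diag(st$P)
    m <- length(par$bases)
    tB <- numeric(m)
    W <- vector("list", m)
    for (i in seq_len(m)) {
      tB[i] <- trace_P_base(st$P, diagP, par$bases[[i]])
      W[[i]] <- base_times_vec(par$bases[[i]], st$Py)
    }
    qB <- vapply(W, function(w) sum(st$Py * w), numeric(1))
    score <- -0.5 * (drop(crossprod(J, tB)) - drop(crossprod(J, qB)))
    # u_k = dV/dtheta_k %*% Py, then AI_kj = 0.5 u_k' P u_j
    U <- matrix(0, length(y), nt)
    for (k in seq_len(nt)) {
      uk <- numeric(length(y))
      for (i in seq_len(m)) if (J[i, k] != 0) uk <- uk + J[i, k] * W[[i]]
      U[, k] <- uk
    }
    PU <- st$Vi %*% U - st$ViX %*% (st$XtViX_inv %*% crossprod(st$ViX, U))
    AI <- 0.5 * crossprod(U, PU)
    at_bound <- !par$is_corr & (theta <= par$lower + 1e-14)
    free <- !(at_bound & score < 0)
    if (!any(free)) { converged <- TRUE; break }
    ridge <- 1e-8 * max(diag(AI)[free], 1e-12)
    delta <- numeric(nt)
    sol <- tryCatch(
      solve(AI[free, free, drop = FALSE] + diag(ridge, sum(free)),
            score[free]),
      error = function(e) NULL)
    if (is.null(sol)) sol <- score[free] / (diag(AI)[free] + ridge)
    delta[free] <- sol
    step <- 1
    accepted <- NULL
    for (h in 1:30) {
      cand <- project_theta(theta + step * delta, par)
      ll <- reml_loglik_at(cand, y, X, par)
      if (is.finite(ll) && ll >= st$ll - 1e-10) {
        accepted <- cand
        break
      }
      step <- step / 2
    }
    if (is.null(accepted)) { converged <- TRUE; break }  # no uphill move left
    new_st <- reml_state_at(accepted, y, X, par)
    if (is.null(new_st)) { converged <- TRUE; break }
    dll <- new_st$ll - st$ll
    relpar <- max(abs(accepted - theta) / pmax(abs(theta), 1e-10))
    theta <- accepted
    st <- new_st
    trace <- rbind(trace, data.frame(iter = iter, loglik = st$ll,
                                     t(setNames(theta, par$names)),
                                     check.names = FALSE))
    if (abs(dll) < tol_ll && (relpar < tol_par || max(abs(score[free])) < 1e-6)) {
      converged <- TRUE
      break
    }
  }
  ai_cov <- tryCatch(solve(AI + diag(1e-12, nt)), error = function(e) {
    matrix(NA_real_, nt, nt)
  })
  dimnames(ai_cov) <- list(par$names, par$names)
  list(theta = setNames(theta, par$names), loglik = st$ll, ai_cov = ai_cov,
       beta = st$beta, Py = st$Py, Vi = st$Vi, P = st$P,
       XtViX_inv = st$XtViX_inv, converged = converged, trace = trace,
       n = length(y), rank_X = ncol(X))
}
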