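# Shared small synthetic trial, built once per test run.
small_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_trial(sim_config(
        seed = 101, n_families = 40, progeny_per_family = 6,
        n_unphenotyped = 20, n_females = 30, n_males = 30,
        n_snps = 400, ld_block_size = 20,
        missing_rate = 0.01, genotyping_error_rate = 0))
    }
    cache
  }
})

# Complete genotypes (pre-masking truth) of the shared trial.
small_trial_geno <- function() attr(small_trial()$genotypes, "truth")

# Balanced single-site family data with known intraclass structure.
balanced_family_data <- function(nf = 40, nr = 6, vf = 0.3, ve = 0.7,
                                 seed = 42) {
  set.seed(seed)
  fam <- rep(seq_len(nf), each = nr)
  u <- rnorm(nf, 0, sqrt(vf))
  y <- 10 + u[fam] + rnorm(nf * nr, 0, sqrt(ve))
  data.frame(tree = paste0("t", seq_along(y)),
             family = paste0("f", fam), site = "S1", test = "T1",
             age = 20, y = y, stringsAsFactors = FALSE)
}

# HWE genotype panel with no pedigree structure.
hwe_panel <- function(n, m, p = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.5)
  M <- sapply(p, function(pk) rbinom(n, 2, pk))
  dimnames(M) <- list(paste0("i", seq_len(n)), paste0("s", seq_len(m)))
  M
}

# Joint ridge-regression marker BLUP (independent oracle for GBLUP).
rrblup_oracle <- function(y, M, var_marker, var_e) {
  W <- scale(M, center = TRUE, scale = FALSE)
  n <- nrow(M)
  X <- matrix(1, n, 1)
  C11 <- crossprod(X) / var_e
  C12 <- crossprod(X, W) / var_e
  C22 <- crossprod(W) / var_e + diag(1 / var_marker, ncol(W))
  Cm <- rbind(cbind(C11, C12), cbind(t(C12), C22))
  rhs <- c(crossprod(X, y) / var_e, crossprod(W, y) / var_e)
  sol <- solve(Cm, rhs)
  drop(W %*% sol[-1])
}
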