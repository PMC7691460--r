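# Relationship matrices: pedigree A (tabular method), genomic additive G
# (VanRaden), genomic dominance G_Dom (Vitezica), and PSD conditioning.

#' Pedigree numerator relationship matrix
#'
#' Computes the additive relationship matrix A by the tabular method:
#' individuals are processed parents-first, `A[i,i] = 1 + 0.5 * A[s,d]`
#' (so the diagonal is `1 + F`), and `A[i,j] = 0.5 * (A[j,s] + A[j,d])`
#' with unknown parents contributing zero.
#'
#' @param pedigree data frame with columns `id`, `sire`, `dam` (`NA` for
#'   unknown parents).  Parents need not precede their offspring; rows are
#'   topologically sorted internally.  A cycle (an individual that is its
#'   own ancestor) is an error.
#' @return object of class `gs_kinship`: list with `ids`, the symmetric
#'   `values` matrix, and `kind = "A"`.
#' @examples
#' ped <- data.frame(id = c("s", "d", "x", "y"),
#'                   sire = c(NA, NA, "s", "s"),
#'                   dam  = c(NA, NA, "d", "d"))
#' A <- pedigree_to_A(ped)
#' A$values["x", "y"]  # full sibs: 0.5
#' @export
pedigree_to_A <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  ord <- pedigree_topological_order(ped)
  ped <- ped[ord, ]
  n <- nrow(ped)
  ids <- as.character(ped$id)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      A[j, i] <- 0.5 * (as_ + ad_)
      A[i, j] <- A[j, i]
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  new_kinship(ids, A, "A")
}

#' VanRaden genomic relationship matrix
#'
#' `G = W W' / (2 * sum p_k (1 - p_k))` where `W` is the 0/1/2 genotype
#' matrix column-centred by twice the observed allele frequency.
#' Monomorphic columns are excluded from numerator and denominator.
#'
#' @param genotypes complete (no missing) numeric matrix, individuals in
#'   rows, SNPs in columns, minor-allele counts 0/1/2.
#' @return `gs_kinship` of kind `"G"`.
#' @export
vanraden_G <- function(genotypes) {
  M <- check_complete_genotypes(genotypes)
  p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all SNPs monomorphic: VanRaden denominator is zero")
  M <- M[, keep, drop = FALSE]
  p <- p[keep]
  W <- sweep(M, 2, 2 * p, "-")
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  new_kinship(rownames(M), G, "G")
}

#' Vitezica genomic dominance relationship matrix
#'
#' Each SNP contributes the dominance covariate `{-2p^2, 2pq, -2q^2}` for
#' genotypes `{0, 1, 2}` (`q = 1 - p`); `G_Dom = H H' / sum (2 p_k q_k)^2`.
#' The sign convention (which homozygote receives `-2p^2`) cancels in the
#' cross-product and does not affect the matrix.
#'
#' @inheritParams vanraden_G
#' @return `gs_kinship` of kind `"G_Dom"`.
#' @export
vitezica_D <- function(genotypes) {
  M <- check_complete_genotypes(genotypes)
  p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all SNPs monomorphic: dominance denominator is zero")
  M <- M[, keep, drop = FALSE]
  p <- p[keep]
  q <- 1 - p
  # H[i,k] = -2p^2, 2pq, -2q^2 for genotype 0, 1, 2
  n <- nrow(M)
  H <- matrix(0, n, ncol(M), dimnames = dimnames(M))
  for (g in 0:2) {
    val <- switch(as.character(g),
                  "0" = -2 * p^2, "1" = 2 * p * q, "2" = -2 * q^2)
    idx <- M == g
    H[idx] <- rep(val, each = n)[idx]
  }
  D <- tcrossprod(H) / sum((2 * p * q)^2)
  new_kinship(rownames(M), D, "G_Dom")
}

#' Condition a relationship matrix to be positive definite
#'
#' Adds `epsilon` to the diagonal when the smallest eigenvalue is not
#' strictly positive, and records whether conditioning was applied.
#'
#' @param K `gs_kinship` or symmetric matrix.
#' @param epsilon diagonal inflation (default `1e-6`); `epsilon = 0` on a
#'   non-PD input is an error.
#' @return `gs_kinship` with attribute `conditioned` (logical).
#' @export
condition_psd <- function(K, epsilon = 1e-6) {
  kin <- as_kinship(K)
  ev <- eigen(kin$values, symmetric = TRUE, only.values = TRUE)$values
  applied <- FALSE
  if (min(ev) <= 0) {
    if (epsilon <= 0) {
      stop("matrix is not positive definite and epsilon = 0 cannot fix it")
    }
    kin$values <- kin$values + diag(epsilon, nrow(kin$values))
    applied <- TRUE
  }
  kin$conditioned <- applied
  kin
}

new_kinship <- function(ids, values, kind) {
  structure(list(ids = as.character(ids), values = values, kind = kind),
            class = "gs_kinship")
}

as_kinship <- function(K, kind = "K") {
  if (inherits(K, "gs_kinship")) return(K)
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  ids <- rownames(K)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(K)))
  dimnames(K) <- list(ids, ids)
  new_kinship(ids, K, kind)
}

#' @export
print.gs_kinship <- function(x, ...) {
  cat(sprintf("<gs_kinship %s: %d individuals, mean diag %.3f>\n",
              x$kind, length(x$ids), mean(diag(x$values))))
  invisible(x)
}

check_complete_genotypes <- function(genotypes) {
  M <- as.matrix(genotypes)
  storage.mode(M) <- "double"
  if (anyNA(M)) stop("genotype matrix has missing values; impute first")
  if (!all(M %in% c(0, 1, 2))) stop("genotypes must be coded 0/1/2")
  if (is.null(rownames(M))) rownames(M) <- as.character(seq_len(nrow(M)))
  M
}

validate_pedigree <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped))) {
    stop("pedigree needs columns id, sire, dam")
  }
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  if (anyDuplicated(ped$id)) stop("duplicated individual ids in pedigree")
  for (col in c("sire", "dam")) {
    known <- !is.na(ped[[col]])
    if (!all(ped[[col]][known] %in% ped$id)) {
      stop("pedigree lists ", col, "s absent from the id column")
    }
  }
  if (any(ped$id == ped$sire | ped$id == ped$dam, na.rm = TRUE)) {
    stop("pedigree cycle: individual listed as its own parent")
  }
  ped
}

pedigree_topological_order <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    stop("pedigree cycle: individual listed as its own ancestor")
  }
  ord
}
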