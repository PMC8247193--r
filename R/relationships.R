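# Relationship matrices for single-step GBLUP: pedigree numerator matrix A
# (tabular method with inbreeding), its sparse inverse (Henderson/Quaas
# rules), the genotyped submatrix A22, the VanRaden genomic matrix G with SNP
# weights, two-moment tuning + blending against A22, and the combined H^-1.

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Recursive tabular method with inbreeding: for animal i with parents s, d
#' (in topological order), `a(i, j) = (a(s, j) + a(d, j)) / 2` and
#' `a(i, i) = 1 + a(s, d) / 2`; terms for unknown parents drop.
#'
#' @param pedigree pedigree data.frame in topological order (`animal`,
#'   `sire`, `dam`; NA = unknown).
#' @return dense symmetric matrix with dimnames = animal ids and attribute
#'   `F` (inbreeding coefficients, `diag(A) - 1`).
#' @export
numerator_relationship <- function(pedigree) {
  n <- nrow(pedigree)
  A <- matrix(0, n, n, dimnames = list(pedigree$animal, pedigree$animal))
  idx <- seq_len(n); names(idx) <- pedigree$animal
  si <- unname(idx[pedigree$sire]); di <- unname(idx[pedigree$dam])
  if (any(si >= idx, na.rm = TRUE) || any(di >= idx, na.rm = TRUE)) {
    stop_sswool("pedigree is not topologically sorted",
                class = "sswool_validation_error")
  }
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(si[i])) row <- row + 0.5 * A[si[i], j]
      if (!is.na(di[i])) row <- row + 0.5 * A[di[i], j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(si[i]) && !is.na(di[i])) 0.5 * A[si[i], di[i]] else 0
  }
  attr(A, "F") <- diag(A) - 1
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding (Quaas): each animal
#' contributes blocks scaled by the inverse Mendelian-sampling variance
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (0.75 - 0.25 F_p with one known parent, 1
#' with none), with terms for unknown parents dropped.
#'
#' @param pedigree pedigree data.frame in topological order.
#' @param inbreeding optional numeric vector of inbreeding coefficients per
#'   animal (computed via [numerator_relationship()] when missing).
#' @return sparse symmetric matrix ([Matrix::dsCMatrix-class]) with dimnames.
#' @export
a_inverse <- function(pedigree, inbreeding = NULL) {
  n <- nrow(pedigree)
  if (is.null(inbreeding)) {
    inbreeding <- if (n > 0L) attr(numerator_relationship(pedigree), "F") else numeric()
  }
  idx <- seq_len(n); names(idx) <- pedigree$animal
  si <- unname(idx[pedigree$sire]); di <- unname(idx[pedigree$dam])
  Fs <- ifelse(is.na(si), 0, inbreeding[ifelse(is.na(si), 1L, si)])
  Fd <- ifelse(is.na(di), 0, inbreeding[ifelse(is.na(di), 1L, di)])
  n_known <- (!is.na(si)) + (!is.na(di))
  d <- ifelse(n_known == 2L, 0.5 - 0.25 * (Fs + Fd),
              ifelse(n_known == 1L, 0.75 - 0.25 * (Fs + Fd), 1))
  b <- 1 / d
  all_i <- seq_len(n)
  ks <- which(!is.na(si)); kd <- which(!is.na(di)); kb <- which(n_known == 2L)
  ii <- c(all_i,
          ks, si[ks], si[ks],
          kd, di[kd], di[kd],
          si[kb], di[kb])
  jj <- c(all_i,
          si[ks], ks, si[ks],
          di[kd], kd, di[kd],
          di[kb], si[kb])
  xx <- c(b,
          -b[ks] / 2, -b[ks] / 2, b[ks] / 4,
          -b[kd] / 2, -b[kd] / 2, b[kd] / 4,
          b[kb] / 4, b[kb] / 4)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(pedigree$animal, pedigree$animal))
}

#' Principal submatrix of A for the genotyped animals
#'
#' @param A numerator relationship matrix with dimnames.
#' @param genotyped_ids animal ids, in the order of the genomic matrix.
#' @return dense matrix `A[genotyped_ids, genotyped_ids]`.
#' @export
subset_a22 <- function(A, genotyped_ids) {
  missing_ids <- setdiff(genotyped_ids, rownames(A))
  if (length(missing_ids)) {
    stop_sswool("genotyped id(s) absent from pedigree: %s",
                paste(utils::head(missing_ids, 5L), collapse = ", "),
                class = "sswool_lookup_error")
  }
  A[genotyped_ids, genotyped_ids, drop = FALSE]
}

#' VanRaden genomic relationship matrix with SNP weights
#'
#' `G = Z D Z' * lambda` with Z the dosage matrix centred columnwise by
#' `2 p_i`, D a diagonal SNP-weight matrix, and
#' `lambda = 1 / sum(2 p_i (1 - p_i))`. Missing dosages are mean-imputed to
#' `2 p_i` (zero contribution after centring); markers fixed at p = 0 or 1
#' are excluded from Z and lambda.
#'
#' @param genotypes dosage matrix (genotyped individuals x markers).
#' @param freqs per-marker counted-allele frequencies (see
#'   [allele_frequencies()]).
#' @param weights per-marker weights (diagonal of D); default all 1.
#' @return list `G` (dense symmetric matrix with dimnames), `Z` (centred
#'   marker matrix over the markers used), `lambda`, `used` (logical marker
#'   mask), `p` (frequencies of used markers), `weights` (weights of used
#'   markers).
#' @export
genomic_relationship <- function(genotypes, freqs, weights = NULL) {
  m <- ncol(genotypes)
  stopifnot(length(freqs) == m)
  weights <- weights %||% rep(1, m)
  stopifnot(length(weights) == m, all(weights >= 0))
  used <- !is.na(freqs) & freqs > 0 & freqs < 1
  p <- freqs[used]
  lambda <- 1 / sum(2 * p * (1 - p))
  if (!is.finite(lambda)) {
    stop_sswool("sum 2p(1-p) is zero: no polymorphic markers",
                class = "sswool_degenerate_error")
  }
  Z <- genotypes[, used, drop = FALSE]
  if (anyNA(Z)) {
    for (j in seq_len(ncol(Z))) {
      nas <- is.na(Z[, j])
      if (any(nas)) Z[nas, j] <- 2 * p[j]
    }
  }
  Z <- sweep(Z, 2L, 2 * p)
  w <- weights[used]
  G <- tcrossprod(sweep(Z, 2L, w, "*"), Z) * lambda
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  list(G = G, Z = Z, lambda = lambda, used = used, p = p, weights = w)
}

#' Tune G to A22 and blend for invertibility
#'
#' Two-moment adjustment: solve `alpha`, `beta` so the mean diagonal and mean
#' off-diagonal of `alpha + beta G` match those of `A22`, then blend
#' `G_w = blend_weight (alpha + beta G) + (1 - blend_weight) A22`.
#'
#' @param G genomic relationship matrix (dense).
#' @param A22 pedigree relationship submatrix of the same animals/order.
#' @param blend_weight weight on the tuned G (default 0.95).
#' @return list `G_w`, `alpha`, `beta`.
#' @export
tune_and_blend <- function(G, A22, blend_weight = 0.95) {
  stopifnot(all(dim(G) == dim(A22)))
  n <- nrow(G)
  md_G <- mean(diag(G)); md_A <- mean(diag(A22))
  if (n > 1L) {
    off <- upper.tri(G) | lower.tri(G)
    mo_G <- mean(G[off]); mo_A <- mean(A22[off])
    beta <- (md_A - mo_A) / (md_G - mo_G)
    alpha <- md_A - beta * md_G
  } else {
    beta <- md_A / md_G; alpha <- 0
  }
  if (!is.finite(beta) || beta <= 0) {
    stop_sswool("tuning failed: beta = %s", format(beta),
                class = "sswool_tuning_error")
  }
  G_w <- blend_weight * (alpha + beta * G) + (1 - blend_weight) * A22
  G_w <- (G_w + t(G_w)) / 2
  ok <- tryCatch({ chol(G_w); TRUE }, error = function(e) FALSE)
  if (!ok) {
    stop_sswool("blended G_w is not positive definite (blend_weight = %g)",
                blend_weight, class = "sswool_linear_algebra_error")
  }
  list(G_w = G_w, alpha = alpha, beta = beta)
}

# Symmetric solve with a logged jitter fallback (+1e-8 on the diagonal).
solve_sym <- function(M, label) {
  tryCatch(chol2inv(chol(M)), error = function(e) {
    message(sprintf("factorisation of %s failed; retrying with 1e-8 jitter", label))
    tryCatch(chol2inv(chol(M + diag(1e-8, nrow(M)))), error = function(e2) {
      stop_sswool("%s is not invertible", label,
                  class = "sswool_linear_algebra_error")
    })
  })
}

#' Combined single-step relationship inverse H^-1
#'
#' `H^-1 = A^-1 + [[0, 0], [0, G_w^-1 - A22^-1]]`, with the correction placed
#' on the genotyped animals' rows/columns.
#'
#' @param A_inv sparse inverse of A (see [a_inverse()]), dimnames = all
#'   animals.
#' @param A22 pedigree submatrix of the genotyped animals.
#' @param G_w tuned/blended genomic matrix (same order as `A22`).
#' @param genotyped_ids ids matching the rows of `G_w`/`A22`.
#' @return sparse symmetric matrix over all animals.
#' @export
h_inverse <- function(A_inv, A22, G_w, genotyped_ids) {
  H <- methods::as(A_inv, "CsparseMatrix")
  if (length(genotyped_ids) == 0L) return(Matrix::forceSymmetric(H))
  pos <- match(genotyped_ids, rownames(A_inv))
  if (anyNA(pos)) {
    stop_sswool("genotyped id(s) absent from A^-1",
                class = "sswool_lookup_error")
  }
  corr <- solve_sym(G_w, "G_w") - solve_sym(A22, "A22")
  n_g <- length(pos)
  Corr <- Matrix::sparseMatrix(i = rep(pos, times = n_g),
                               j = rep(pos, each = n_g),
                               x = as.numeric(corr), dims = dim(H),
                               dimnames = dimnames(H))
  Matrix::forceSymmetric(H + Corr)
}
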