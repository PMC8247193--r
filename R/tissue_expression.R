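# Tissue-specificity scoring from a multi-tissue expression atlas: TPM
# normalisation, scaled log2 expression, per-gene/per-tissue least-squares
# models with a +1/-1 tissue code, t-statistic ranking, and top-decile
# tissue-specific gene sets.

#' TPM normalisation of a count matrix
#'
#' `rate = counts / length_kb`, then each sample is scaled so its rates sum
#' to 1e6.
#'
#' @param counts genes x samples count matrix.
#' @param lengths per-gene lengths in bp (> 0).
#' @return TPM matrix (columns sum to 1e6); all-zero samples are set to `NA`
#'   with a warning.
#' @export
tpm_normalize <- function(counts, lengths) {
  stopifnot(nrow(counts) == length(lengths), all(lengths > 0))
  rate <- counts / (lengths / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero sample(s); TPM undefined", sum(zero)))
    tot[zero] <- NA_real_
  }
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Scaled log2 expression
#'
#' `y = log2(TPM + 0.25)`, then per-gene standardisation to mean 0, SD 1
#' across samples. Zero-variance genes are excluded (returned in the
#' `excluded` attribute).
#'
#' @param tpm non-negative TPM matrix (genes x samples).
#' @return scaled matrix over the retained genes, with attribute `excluded`
#'   (ids of zero-variance genes).
#' @export
scale_expression <- function(tpm) {
  stopifnot(all(tpm >= 0, na.rm = TRUE))
  y <- log2(tpm + 0.25)
  sds <- apply(y, 1L, stats::sd)
  keep <- !is.na(sds) & sds > 0
  scaled <- t(scale(t(y[keep, , drop = FALSE])))
  attr(scaled, "excluded") <- rownames(tpm)[!keep]
  scaled
}

# Design matrix for one tissue (or organ-system) contrast: intercept, the
# +1/-1 tissue code, and dummy-coded age/sex covariates; collinear covariate
# columns are dropped with a warning. Returns the rows (samples) used.
tissue_design <- function(metadata, target) {
  is_system <- target %in% metadata$organ_system
  if (is_system) {
    rows <- seq_len(nrow(metadata))
    code <- ifelse(metadata$organ_system == target, 1, -1)
  } else {
    if (!target %in% metadata$tissue) {
      stop_sswool("unknown tissue or organ system: %s", target,
                  class = "sswool_lookup_error")
    }
    sys <- metadata$organ_system[match(target, metadata$tissue)]
    # exclude other samples of the same organ system
    rows <- which(metadata$tissue == target | metadata$organ_system != sys)
    code <- ifelse(metadata$tissue[rows] == target, 1, -1)
  }
  if (sum(code == 1) < 2L || sum(code == -1) < 2L) {
    stop_sswool("need >= 2 samples in each of the +1 and -1 groups",
                class = "sswool_validation_error")
  }
  md <- metadata[rows, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, tissue_code = code)
  for (cv in c("age_stage", "sex")) {
    f <- droplevels(as.factor(md[[cv]]))
    if (nlevels(f) > 1L) {
      X <- cbind(X, stats::model.matrix(~f)[, -1L, drop = FALSE])
    }
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep_cols <- qx$pivot[seq_len(qx$rank)]
    if (!(2L %in% keep_cols)) {
      stop_sswool("tissue code is confounded with covariates for %s", target,
                  class = "sswool_rank_error")
    }
    warning("dropping collinear covariate column(s) in tissue design")
    X <- X[, sort(keep_cols), drop = FALSE]
  }
  list(X = X, rows = rows)
}

#' Least-squares tissue-specificity model for one gene
#'
#' Regresses the scaled log2 expression on an intercept, a +1/-1 tissue
#' code (target samples +1; when the target is a tissue, other samples of
#' its organ system are excluded) and age/sex covariates; `t = beta / se`
#' with residual degrees of freedom `n - p` (se floored at 1e-12).
#'
#' @param y scaled expression vector over all samples of `metadata`.
#' @param metadata sample metadata (`sample_id`, `tissue`, `organ_system`,
#'   `age_stage`, `sex`).
#' @param target tissue or organ-system name.
#' @return named vector `c(beta, se, t)`.
#' @export
fit_tissue_model <- function(y, metadata, target) {
  des <- tissue_design(metadata, target)
  res <- tissue_t_stats(matrix(y[des$rows], nrow = 1L), des$X)
  c(beta = unname(res$beta[1L]), se = unname(res$se[1L]),
    t = unname(res$t[1L]))
}

# Vectorised least squares of many genes on one fixed design; returns the
# tissue-code coefficient, its SE and t per gene.
tissue_t_stats <- function(Y, X) {
  n <- ncol(Y); p <- ncol(X)
  XtXi <- solve(crossprod(X))
  B <- Y %*% X %*% XtXi            # genes x p coefficients
  fitted <- B %*% t(X)
  rss <- rowSums((Y - fitted)^2)
  df <- n - p
  sigma2 <- rss / df
  se <- pmax(sqrt(sigma2 * XtXi["tissue_code", "tissue_code"]), 1e-12)
  beta <- B[, "tissue_code"]
  list(beta = beta, se = se, t = beta / se, df = df)
}

#' Tissue-specificity t-statistics for all genes in one target
#'
#' @param scaled scaled expression matrix (genes x samples, see
#'   [scale_expression()]).
#' @param metadata sample metadata aligned to the columns.
#' @param target tissue or organ-system name.
#' @return data.frame (`gene_id`, `beta`, `se`, `t`, `rank`), ranked by t
#'   descending (dense over tested genes).
#' @export
tissue_specificity <- function(scaled, metadata, target) {
  stopifnot(ncol(scaled) == nrow(metadata))
  des <- tissue_design(metadata, target)
  st <- tissue_t_stats(scaled[, des$rows, drop = FALSE], des$X)
  out <- data.frame(gene_id = rownames(scaled), beta = st$beta, se = st$se,
                    t = st$t, stringsAsFactors = FALSE)
  out$rank <- rank(-out$t, ties.method = "first")
  rownames(out) <- NULL
  out
}

#' Top-decile tissue-specific gene set
#'
#' The top `floor(fraction * n)` genes by t-statistic descending; ties broken
#' by gene id ascending.
#'
#' @param results per-gene results for one target (see
#'   [tissue_specificity()]).
#' @param fraction fraction of genes (default 0.10).
#' @return sorted character vector of gene ids.
#' @export
tissue_specific_genes <- function(results, fraction = 0.10) {
  if (is.null(results) || nrow(results) == 0L) {
    warning("no tissue-specificity results")
    return(character())
  }
  n_take <- floor(fraction * nrow(results))
  ord <- order(-results$t, results$gene_id)
  sort(results$gene_id[ord][seq_len(n_take)])
}

#' Sample-sample correlation matrix of scaled expression
#'
#' @param scaled scaled expression matrix (genes x samples).
#' @return symmetric Pearson correlation matrix of the sample columns.
#' @export
sample_correlation_matrix <- function(scaled) {
  stopifnot(nrow(scaled) >= 2L)
  stats::cor(scaled)
}
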