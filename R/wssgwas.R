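# Weighted single-step GWAS: Henderson mixed-model equations with H^-1,
# SNP-effect backsolving from GEBV, iterative SNP reweighting, sliding-window
# variance decomposition, and QTL-region calling.

#' Solve Henderson's mixed-model equations for the animal model
#'
#' `[X'X, X'W; W'X, W'W + k K^-1] [beta; a] = [X'y; W'y]` with
#' `k = sigma2_e / sigma2_a`. Animals without phenotypes still receive
#' breeding values through the relationship structure.
#'
#' @param phenotypes phenotype data.frame (`animal`, fixed factors, trait).
#' @param trait trait column name.
#' @param K_inv sparse inverse relationship matrix over all animals (A^-1 or
#'   H^-1), dimnames = animal ids.
#' @param sigma2_a,sigma2_e variance components (> 0).
#' @param fixed fixed-effect factor columns.
#' @return list `beta` (named fixed-effect estimates), `a_hat` (named
#'   breeding values for all animals), `residual_norm` (relative residual of
#'   the solved system).
#' @export
solve_mme <- function(phenotypes, trait, K_inv, sigma2_a, sigma2_e,
                      fixed = c("flock", "year", "season")) {
  stopifnot(sigma2_a > 0, sigma2_e > 0)
  dat <- phenotypes[!is.na(phenotypes[[trait]]), , drop = FALSE]
  ids <- rownames(K_inv)
  pos <- match(dat$animal, ids)
  if (anyNA(pos)) {
    stop_sswool("phenotyped animal(s) missing from the relationship inverse",
                class = "sswool_lookup_error")
  }
  X <- build_fixed_design(dat, fixed)
  y <- dat[[trait]]
  n_obs <- nrow(dat); n_all <- length(ids)
  W <- Matrix::sparseMatrix(i = seq_len(n_obs), j = pos, x = 1,
                            dims = c(n_obs, n_all))
  Xs <- methods::as(X, "CsparseMatrix")
  k <- sigma2_e / sigma2_a
  C <- rbind(cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, W)),
             cbind(Matrix::crossprod(W, Xs),
                   Matrix::crossprod(W) + k * K_inv))
  C <- Matrix::forceSymmetric(C)
  rhs <- c(as.numeric(Matrix::crossprod(Xs, y)),
           as.numeric(Matrix::crossprod(W, y)))
  sol <- tryCatch(as.numeric(Matrix::solve(Matrix::Cholesky(C, LDL = FALSE),
                                           rhs, system = "A")),
                  error = function(e) {
                    stop_sswool("mixed-model equations singular (confounded fixed-effect levels?): %s",
                                conditionMessage(e), class = "sswool_linear_algebra_error")
                  })
  resid <- sqrt(sum((as.numeric(C %*% sol) - rhs)^2)) / sqrt(sum(rhs^2))
  p <- ncol(X)
  beta <- sol[seq_len(p)]; names(beta) <- colnames(X)
  a_hat <- sol[p + seq_len(n_all)]; names(a_hat) <- ids
  list(beta = beta, a_hat = a_hat, residual_norm = resid,
       variance_ratio = k)
}

#' Backsolve SNP effects from genomic breeding values
#'
#' `u_hat = lambda D Z' G^-1 a_g`. When `G = Z D Z' lambda` exactly and is
#' full rank, the reconstructed genomic values `Z u_hat` equal `a_g`.
#'
#' @param Z centred marker matrix (genotyped animals x used markers).
#' @param weights per-marker weights (diagonal of D, aligned to `Z` columns).
#' @param lambda VanRaden scale `1 / sum(2 p (1 - p))`.
#' @param G invertible genomic relationship matrix of the same animals.
#' @param a_g GEBV of the genotyped animals (aligned to `Z` rows).
#' @return per-marker effects.
#' @export
backsolve_snp_effects <- function(Z, weights, lambda, G, a_g) {
  stopifnot(nrow(Z) == nrow(G), length(a_g) == nrow(G),
            length(weights) == ncol(Z))
  lambda * weights * drop(crossprod(Z, solve(G, a_g)))
}

#' SNP weights from effects and allele frequencies
#'
#' `d_i = u_i^2 * 2 p_i (1 - p_i)`.
#'
#' @param u per-marker effects.
#' @param p per-marker counted-allele frequencies.
#' @return non-negative weights.
#' @export
update_weights <- function(u, p) {
  stopifnot(length(u) == length(p))
  u^2 * 2 * p * (1 - p)
}

#' Normalise SNP weights to keep total genetic variance constant
#'
#' Rescales so the trace equals the first-iteration trace, i.e.
#' `sum(d) = m`.
#'
#' @param d weights.
#' @param m number of markers (trace of the identity first-iteration D).
#' @return rescaled weights summing to `m`.
#' @export
normalize_weights <- function(d, m = length(d)) {
  s <- sum(d)
  if (s <= 0) {
    stop_sswool("all SNP weights are zero; cannot normalise",
                class = "sswool_degenerate_error")
  }
  d * (m / s)
}

#' Run the weighted single-step GWAS loop
#'
#' Executes the iterative scheme: start from `D = I`; build
#' `G = Z D Z' lambda`, tune and blend against `A22`, assemble `H^-1`, solve
#' the mixed-model equations for GEBV, backsolve SNP effects, reweight
#' (`d_i = u_i^2 2 p_i (1 - p_i)`), normalise the weights to constant trace,
#' and rebuild G. `n_reweight` counts executions of the reweighting steps
#' (default 1); `n_reweight = 0` is unweighted ssGBLUP.
#'
#' @param phenotypes phenotype data.frame.
#' @param trait trait column name.
#' @param pedigree topologically sorted pedigree covering all animals.
#' @param genotypes dosage matrix of the genotyped animals (post-QC).
#' @param sigma2_a,sigma2_e variance components for the trait.
#' @param n_reweight number of reweighting iterations (default 1).
#' @param fixed fixed-effect factor columns.
#' @param blend_weight weight on tuned G when blending with A22.
#' @return list with `u` (final per-marker effects, zero for excluded
#'   monomorphic markers), `weights` (final normalised weights),
#'   `weight_history` / `effect_history` (per iteration), `p` (allele
#'   frequencies), `lambda`, `Zc` (centred marker matrix over all markers,
#'   genotyped animals), `mme` (final [solve_mme()] solution), `a_g` (final
#'   GEBV of genotyped animals), `tuning` (alpha/beta per iteration).
#' @export
run_wssgwas <- function(phenotypes, trait, pedigree, genotypes,
                        sigma2_a, sigma2_e, n_reweight = 1L,
                        fixed = c("flock", "year", "season"),
                        blend_weight = 0.95) {
  genotyped_ids <- rownames(genotypes)
  A <- numerator_relationship(pedigree)
  Ainv <- a_inverse(pedigree, attr(A, "F"))
  A22 <- subset_a22(A, genotyped_ids)
  p <- allele_frequencies(genotypes)
  m <- ncol(genotypes)
  w <- rep(1, m)
  u_full <- numeric(m)
  weight_history <- list(w); effect_history <- list(); tuning <- list()
  mme <- NULL; a_g <- NULL; gr <- NULL; lambda <- NA_real_
  n_iter <- n_reweight + 1L
  for (t in seq_len(n_iter)) {
    gr <- genomic_relationship(genotypes, p, w)
    lambda <- gr$lambda
    tb <- tune_and_blend(gr$G, A22, blend_weight)
    Hinv <- h_inverse(Ainv, A22, tb$G_w, genotyped_ids)
    mme <- solve_mme(phenotypes, trait, Hinv, sigma2_a, sigma2_e, fixed)
    a_g <- mme$a_hat[genotyped_ids]
    u_used <- backsolve_snp_effects(gr$Z, gr$weights, gr$lambda, tb$G_w, a_g)
    u_full <- numeric(m); names(u_full) <- colnames(genotypes)
    u_full[gr$used] <- u_used
    effect_history[[t]] <- u_full
    tuning[[t]] <- c(alpha = tb$alpha, beta = tb$beta)
    if (t < n_iter) {
      d <- update_weights(u_full, ifelse(is.na(p), 0, p))
      w <- normalize_weights(d, m)
      weight_history[[t + 1L]] <- w
    }
  }
  Zc <- matrix(0, nrow(genotypes), m,
               dimnames = dimnames(genotypes))
  Zc[, gr$used] <- gr$Z
  list(u = u_full, weights = w, p = p, lambda = lambda,
       weight_history = weight_history, effect_history = effect_history,
       tuning = tuning, Zc = Zc, mme = mme, a_g = a_g, used = gr$used)
}

#' Percentage of genetic variance explained by sliding SNP windows
#'
#' For every window of `window_size` consecutive SNPs within a chromosome
#' (sliding step of one SNP), computes the genomic value
#' `a_i = sum_j z_j u_j` over the genotyped individuals (z centred as in G)
#' and reports `var(a_i) / sigma2_a * 100` with the empirical `1/(n-1)`
#' variance. A chromosome with fewer SNPs than `window_size` yields a single
#' truncated window, flagged.
#'
#' @param u per-marker effects aligned to `map` rows.
#' @param Zc centred marker matrix (genotyped animals x markers).
#' @param map marker map aligned to `Zc` columns.
#' @param sigma2_a total additive genetic variance.
#' @param window_size SNPs per window (default 20).
#' @return data.frame (`chrom`, `first_snp`, `last_snp`, `start_bp`,
#'   `end_bp`, `pct_variance`, `truncated`, `rank`); rank is over
#'   non-truncated windows, by descending percentage with (chromosome,
#'   start) tie-break.
#' @export
window_variances <- function(u, Zc, map, sigma2_a, window_size = 20L) {
  stopifnot(length(u) == ncol(Zc), nrow(map) == ncol(Zc), sigma2_a > 0)
  n <- nrow(Zc)
  res <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    idx <- idx[order(map$pos[idx])]
    m_ch <- length(idx)
    V <- sweep(Zc[, idx, drop = FALSE], 2L, u[idx], "*")
    Cs <- V
    if (m_ch > 1L) for (j in 2:m_ch) Cs[, j] <- Cs[, j - 1L] + V[, j]
    if (m_ch < window_size) {
      a <- Cs[, m_ch]
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, first_snp = map$snp[idx[1L]], last_snp = map$snp[idx[m_ch]],
        start_bp = map$pos[idx[1L]], end_bp = map$pos[idx[m_ch]],
        pct_variance = stats::var(a) / sigma2_a * 100, truncated = TRUE)
      next
    }
    n_win <- m_ch - window_size + 1L
    pct <- numeric(n_win)
    for (s in seq_len(n_win)) {
      hi <- s + window_size - 1L
      a <- if (s == 1L) Cs[, hi] else Cs[, hi] - Cs[, s - 1L]
      pct[s] <- stats::var(a) / sigma2_a * 100
    }
    res[[length(res) + 1L]] <- data.frame(
      chrom = ch,
      first_snp = map$snp[idx[seq_len(n_win)]],
      last_snp = map$snp[idx[seq_len(n_win) + window_size - 1L]],
      start_bp = map$pos[idx[seq_len(n_win)]],
      end_bp = map$pos[idx[seq_len(n_win) + window_size - 1L]],
      pct_variance = pct, truncated = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$rank <- NA_integer_
  ok <- !out$truncated
  ord <- order(-out$pct_variance[ok],
               suppressWarnings(as.numeric(out$chrom[ok])),
               out$chrom[ok], out$start_bp[ok])
  out$rank[which(ok)[ord]] <- seq_len(sum(ok))
  out
}

#' Select the top QTL regions from ranked windows
#'
#' Walks the windows in rank order (percentage descending; ties by
#' chromosome then start position; truncated chromosome-tail windows
#' excluded). A window that overlaps or is bookended to an already-selected
#' region extends that region; otherwise it opens a new region. Selection
#' stops before a `k+1`-th region would be opened, so `k` counts distinct
#' merged QTL regions — sliding windows covering the same locus collapse
#' into one reported region.
#'
#' @param results window table from [window_variances()].
#' @param k number of QTL regions (default 10).
#' @return data.frame (`chrom`, `start_bp`, `end_bp`, `n_windows`,
#'   `best_pct_variance` (the region's best single window),
#'   `sum_pct_variance` (sum over member windows; overlapping sliding
#'   windows make this an overcount of distinct variance), `best_rank`),
#'   ordered by `best_rank`.
#' @export
top_windows <- function(results, k = 10L) {
  cand <- results[!results$truncated & !is.na(results$rank), , drop = FALSE]
  cand <- cand[order(cand$rank), , drop = FALSE]
  regions <- list()
  for (i in seq_len(nrow(cand))) {
    w <- cand[i, ]
    joined <- FALSE
    for (ri in seq_along(regions)) {
      r <- regions[[ri]]
      if (w$chrom == r$chrom && w$start_bp <= r$end_bp + 1L &&
          w$end_bp >= r$start_bp - 1L) {
        r$start_bp <- min(r$start_bp, w$start_bp)
        r$end_bp <- max(r$end_bp, w$end_bp)
        r$n_windows <- r$n_windows + 1L
        r$best_pct_variance <- max(r$best_pct_variance, w$pct_variance)
        r$sum_pct_variance <- r$sum_pct_variance + w$pct_variance
        regions[[ri]] <- r
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      if (length(regions) == k) break
      regions[[length(regions) + 1L]] <-
        data.frame(chrom = w$chrom, start_bp = w$start_bp, end_bp = w$end_bp,
                   n_windows = 1L, best_pct_variance = w$pct_variance,
                   sum_pct_variance = w$pct_variance, best_rank = w$rank)
    }
  }
  if (length(regions) < k) {
    warning(sprintf("only %d region(s) available (k = %d)", length(regions), k))
  }
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out[order(out$best_rank), , drop = FALSE]
}

#' Genes overlapping the top fraction of ranked windows
#'
#' Takes the `ceiling(fraction * n_windows)` best windows and returns the
#' ids of genes whose span overlaps any of their bp spans.
#'
#' @param results window table from [window_variances()].
#' @param annotation gene annotation (see [read_gene_annotation()]).
#' @param fraction fraction of windows (default 0.01).
#' @return sorted character vector of gene ids (empty, with a warning, when
#'   the annotation is empty).
#' @export
top_percent_snps <- function(results, annotation, fraction = 0.01) {
  if (is.null(annotation) || nrow(annotation) == 0L) {
    warning("empty gene annotation")
    return(character())
  }
  cand <- results[!results$truncated & !is.na(results$rank), , drop = FALSE]
  n_top <- ceiling(fraction * nrow(cand))
  sel <- cand[cand$rank <= n_top, , drop = FALSE]
  hits <- character()
  for (i in seq_len(nrow(sel))) {
    ov <- annotation$chrom == sel$chrom[i] &
      annotation$start <= sel$end_bp[i] & annotation$end >= sel$start_bp[i]
    hits <- c(hits, annotation$gene_id[ov])
  }
  sort(unique(hits))
}
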