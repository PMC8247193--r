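# Sum-based GWAS-signal enrichment of gene sets with a cyclical-permutation
# null: markers are assigned to a gene set through symmetric 20-kb extensions
# of the gene spans, the statistic is the sum of squared marker effects over
# the set, and the null rotates the genome-ordered effect vector, which
# preserves the set size and the local (LD) ordering of effects.

#' Mark the SNPs lying within extended gene spans
#'
#' A SNP is in the mask iff its position falls in
#' `[start - extension, end + extension]` (clamped at 1) of any gene in the
#' set; strand is ignored.
#'
#' @param map marker map (`snp`, `chrom`, `pos`).
#' @param genes gene annotation rows for the set (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param extension_bp symmetric extension (default 20000).
#' @return logical vector aligned to `map` rows.
#' @export
map_markers_to_genes <- function(map, genes, extension_bp = 20000L) {
  if (nrow(genes) > 0L && !any(genes$chrom %in% map$chrom)) {
    stop_sswool("no shared chromosome names between map and annotation (map: %s...; genes: %s...)",
                paste(utils::head(unique(map$chrom), 3), collapse = ","),
                paste(utils::head(unique(genes$chrom), 3), collapse = ","),
                class = "sswool_validation_error")
  }
  mask <- rep(FALSE, nrow(map))
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    rows <- which(map$chrom == ch)
    if (!length(rows)) next
    lo <- pmax(1L, g$start - extension_bp)
    hi <- g$end + extension_bp
    pos <- map$pos[rows]
    for (i in seq_along(lo)) {
      mask[rows[pos >= lo[i] & pos <= hi[i]]] <- TRUE
    }
  }
  mask
}

#' Sum of squared marker effects over a marker set
#'
#' @param effects per-SNP effects aligned to the mask.
#' @param mask logical marker-set mask (see [map_markers_to_genes()]).
#' @return `sum(effects[mask]^2)`; errors if the mask is empty.
#' @export
t_sum <- function(effects, mask) {
  stopifnot(length(effects) == length(mask))
  if (!any(mask)) {
    stop_sswool("empty marker set (m_g = 0)", class = "sswool_degenerate_error")
  }
  sum(effects[mask]^2)
}

#' Cyclical-permutation enrichment test
#'
#' Rotates the genome-ordered effect vector by a uniformly random offset
#' `k in {1, ..., n-1}` (the genome treated as one circle), recomputes the
#' sum statistic against the fixed mask, and reports the one-tailed
#' empirical p-value `(1 + #\{T_perm >= T_obs\}) / (1 + n_perm)`. Offsets are
#' sampled with replacement.
#'
#' @param effects per-SNP effects in genome order.
#' @param mask marker-set mask in the same order.
#' @param n_perm number of rotations (default 10000).
#' @param seed integer seed.
#' @return list `t_sum_observed`, `p_empirical`, `m_g`, `n_perm`.
#' @export
cyclic_permutation_test <- function(effects, mask, n_perm = 10000L, seed = 1L) {
  stopifnot(n_perm >= 100L)
  n <- length(effects)
  t_obs <- t_sum(effects, mask)
  b2 <- effects^2
  set.seed(derive_seed(seed, "cyclic"))
  offsets <- sample.int(n - 1L, n_perm, replace = TRUE)
  midx <- which(mask)
  t_perm <- vapply(offsets, function(k) {
    # rotating effects by +k == evaluating the mask at positions shifted by -k
    sum(b2[(midx - k - 1L) %% n + 1L])
  }, numeric(1))
  p <- (1 + sum(t_perm >= t_obs)) / (1 + n_perm)
  list(t_sum_observed = t_obs, p_empirical = p, m_g = length(midx),
       n_perm = n_perm)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values numeric p-values in (0, 1].
#' @return q-values of the same length.
#' @export
fdr_bh <- function(p_values) {
  if (!length(p_values)) return(numeric())
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment of many gene sets against many traits
#'
#' Computes the sum statistic and cyclical-permutation p-value for every
#' (trait, gene set) pair and applies BH-FDR within each trait. Gene sets
#' whose marker mask is empty are skipped with `NA` results.
#'
#' @param trait_effects named list: trait -> per-SNP effects in `map` order.
#' @param gene_sets named list: set name (e.g. tissue) -> character vector of
#'   gene ids.
#' @param annotation gene annotation table.
#' @param map marker map (genome order).
#' @param extension_bp symmetric gene extension (default 20000).
#' @param n_perm permutations per test (default 10000).
#' @param seed integer seed (sub-seeds are derived per trait x set, so the
#'   full table is deterministic).
#' @return data.frame (`trait`, `gene_set`, `m_g`, `t_sum`, `p`, `fdr`).
#' @export
enrich_all <- function(trait_effects, gene_sets, annotation, map,
                       extension_bp = 20000L, n_perm = 10000L, seed = 1L) {
  masks <- lapply(gene_sets, function(ids) {
    map_markers_to_genes(map,
                         annotation[annotation$gene_id %in% ids, , drop = FALSE],
                         extension_bp)
  })
  rows <- list()
  for (tr in names(trait_effects)) {
    b <- trait_effects[[tr]]
    stopifnot(length(b) == nrow(map))
    p_vec <- rep(NA_real_, length(gene_sets))
    t_vec <- rep(NA_real_, length(gene_sets))
    m_vec <- vapply(masks, sum, integer(1))
    for (si in seq_along(gene_sets)) {
      if (m_vec[si] == 0L) next
      res <- cyclic_permutation_test(
        b, masks[[si]], n_perm = n_perm,
        seed = derive_seed(seed, paste(tr, names(gene_sets)[si])))
      p_vec[si] <- res$p_empirical
      t_vec[si] <- res$t_sum_observed
    }
    fdr <- rep(NA_real_, length(p_vec))
    fdr[!is.na(p_vec)] <- fdr_bh(p_vec[!is.na(p_vec)])
    rows[[tr]] <- data.frame(trait = tr, gene_set = names(gene_sets),
                             m_g = m_vec, t_sum = t_vec, p = p_vec, fdr = fdr,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
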