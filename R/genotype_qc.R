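# Marker and individual quality control, allele frequencies, exact
# Hardy-Weinberg testing, composite LD, and phenotype outlier filtering.

#' Counted-allele frequencies per marker
#'
#' @param genotypes dosage matrix (individuals x markers, 0/1/2/NA).
#' @return numeric vector `p = mean(dosage)/2` over non-missing calls, with
#'   attribute `all_missing` flagging markers with no calls (their `p` is
#'   `NA`).
#' @export
allele_frequencies <- function(genotypes) {
  n_called <- colSums(!is.na(genotypes))
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  p[n_called == 0L] <- NA_real_
  attr(p, "all_missing") <- n_called == 0L
  p
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: given the observed allele counts, sums
#' the probabilities of all heterozygote counts (same parity) whose
#' conditional probability does not exceed that of the observed
#' configuration.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return the exact p-value (1 for monomorphic markers).
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop_sswool("no genotypes", class = "sswool_validation_error")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log conditional probability of each possible heterozygote count
  lp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_com <- n - h - hom_rare
    h * log(2) + lgamma(n + 1) -
      (lgamma(hom_rare + 1) + lgamma(h + 1) + lgamma(hom_com + 1)) +
      lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_Aa)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Quality-control filter for markers and individuals
#'
#' Removal order: unmapped markers, sex-chromosome markers, individuals with
#' low call rate, markers with low call rate, low MAF, then HWE failures
#' (allele frequencies recomputed after individual removal). Thresholds
#' default to the standard array settings: call rate 90%, MAF 1%, HWE
#' p < 1e-6.
#'
#' @param genotypes dosage matrix.
#' @param map marker map (`snp`, `chrom`, `pos`); `chrom` values `"X"`,
#'   `"Y"`, `"XY"`, `"MT"` (case-insensitive) or `sex_chromosomes` count as
#'   sex chromosomes, `NA`/`"0"` chrom or pos as unmapped.
#' @param snp_call_min,maf_min,hwe_p_min,ind_call_min thresholds.
#' @param sex_chromosomes chromosome tokens treated as sex chromosomes.
#' @return list `genotypes`, `map`, `report` (removed-marker counts by
#'   reason, removed-individual count, thresholds).
#' @export
qc_filter <- function(genotypes, map, snp_call_min = 0.90, maf_min = 0.01,
                      hwe_p_min = 1e-6, ind_call_min = 0.90,
                      sex_chromosomes = c("X", "Y", "XY", "MT", "27")) {
  stopifnot(ncol(genotypes) == nrow(map))
  removed <- c(unmapped = 0L, sex_chromosome = 0L, low_call_rate = 0L,
               low_maf = 0L, hwe_fail = 0L)
  keep <- rep(TRUE, ncol(genotypes))

  unmapped <- is.na(map$chrom) | map$chrom == "0" | is.na(map$pos) | map$pos < 1
  removed["unmapped"] <- sum(unmapped & keep)
  keep <- keep & !unmapped

  sexchr <- toupper(map$chrom) %in% toupper(sex_chromosomes)
  removed["sex_chromosome"] <- sum(sexchr & keep)
  keep <- keep & !sexchr

  # individual call rate, computed on surviving markers
  ind_cr <- rowMeans(!is.na(genotypes[, keep, drop = FALSE]))
  keep_ind <- ind_cr >= ind_call_min
  g <- genotypes[keep_ind, , drop = FALSE]

  snp_cr <- colMeans(!is.na(g))
  low_cr <- snp_cr < snp_call_min
  removed["low_call_rate"] <- sum(low_cr & keep)
  keep <- keep & !low_cr

  p <- allele_frequencies(g)
  maf <- pmin(p, 1 - p)
  low_maf <- is.na(maf) | maf < maf_min
  removed["low_maf"] <- sum(low_maf & keep)
  keep <- keep & !low_maf

  hwe_p <- rep(1, ncol(g))
  for (j in which(keep)) {
    gj <- g[, j]
    hwe_p[j] <- hwe_exact_test(sum(gj == 2L, na.rm = TRUE),
                               sum(gj == 1L, na.rm = TRUE),
                               sum(gj == 0L, na.rm = TRUE))
  }
  hwe_fail <- hwe_p < hwe_p_min
  removed["hwe_fail"] <- sum(hwe_fail & keep)
  keep <- keep & !hwe_fail

  if (!any(keep)) warning("qc_filter removed every marker")
  list(genotypes = g[, keep, drop = FALSE],
       map = { mm <- map[keep, , drop = FALSE]; rownames(mm) <- NULL; mm },
       report = list(removed_markers = as.list(removed),
                     removed_individuals = sum(!keep_ind),
                     n_markers_in = ncol(genotypes),
                     n_markers_out = sum(keep),
                     thresholds = list(snp_call_min = snp_call_min,
                                       maf_min = maf_min,
                                       hwe_p_min = hwe_p_min,
                                       ind_call_min = ind_call_min)))
}

#' Set phenotype outliers to missing
#'
#' Single pass per trait: values more than `k_sd` standard deviations from
#' the trait mean (strict inequality) are set to `NA`. A zero-SD trait is
#' left unchanged.
#'
#' @param phenotypes phenotype data.frame.
#' @param traits character vector of trait column names (default: all
#'   numeric columns except ids/factors).
#' @param k_sd threshold in SD units (default 3).
#' @return the phenotype data.frame with outliers set to `NA`.
#' @export
phenotype_outlier_filter <- function(phenotypes, traits = NULL, k_sd = 3) {
  if (is.null(traits)) {
    traits <- names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))]
  }
  for (tr in traits) {
    x <- phenotypes[[tr]]
    mu <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) next
    phenotypes[[tr]][!is.na(x) & abs(x - mu) > k_sd * s] <- NA
  }
  phenotypes
}

#' Composite LD r-squared between two markers
#'
#' Squared Pearson correlation of the dosage vectors (genotypic/composite
#' LD; genotypes are unphased), missing calls excluded pairwise.
#'
#' @param genotypes dosage matrix.
#' @param marker_i,marker_j column indices or names.
#' @return r-squared in `[0, 1]`, or `NA` (with a warning) when either
#'   marker is monomorphic on the jointly called individuals.
#' @export
ld_r2 <- function(genotypes, marker_i, marker_j) {
  x <- genotypes[, marker_i]; y <- genotypes[, marker_j]
  ok <- !is.na(x) & !is.na(y)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("monomorphic marker: LD undefined")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])^2
}

#' LD decay: mean r-squared by physical distance bin
#'
#' Within-chromosome marker pairs only, up to `max_dist_bp`.
#'
#' @param genotypes dosage matrix.
#' @param map marker map aligned to `genotypes` columns.
#' @param bin_width_bp width of distance bins.
#' @param max_dist_bp maximum pair distance considered.
#' @return data.frame (`bin_start`, `bin_end`, `mean_r2`, `n_pairs`); empty
#'   bins are reported with `n_pairs = 0` and `mean_r2 = NA`.
#' @export
ld_decay <- function(genotypes, map, bin_width_bp, max_dist_bp) {
  n_bins <- ceiling(max_dist_bp / bin_width_bp)
  sums <- numeric(n_bins); counts <- integer(n_bins)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    idx <- idx[order(map$pos[idx])]
    pos <- map$pos[idx]
    for (a in seq_along(idx)) {
      b <- a + 1L
      while (b <= length(idx) && pos[b] - pos[a] <= max_dist_bp) {
        r2 <- suppressWarnings(ld_r2(genotypes, idx[a], idx[b]))
        if (!is.na(r2)) {
          bin <- min(n_bins, floor((pos[b] - pos[a]) / bin_width_bp) + 1L)
          sums[bin] <- sums[bin] + r2
          counts[bin] <- counts[bin] + 1L
        }
        b <- b + 1L
      }
    }
  }
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_width_bp,
             bin_end = seq_len(n_bins) * bin_width_bp,
             mean_r2 = ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_),
             n_pairs = counts)
}
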