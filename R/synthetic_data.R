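# Synthetic data generator: multi-generation pedigree, gene dropping with
# Haldane recombination (1 cM/Mb), polygenic + QTL trait architecture, and a
# multi-tissue TPM expression atlas with planted tissue-specific genes.
# Defaults emulate a partially genotyped fine-wool sheep population scaled to
# desk size: six traits with the published heritabilities, 50/8/2 fixed-effect
# levels, ~17% of phenotyped females genotyped, 26 autosomes.

#' Simulation configuration
#'
#' @param n_founders even number of founder animals (half of each sex).
#' @param n_generations number of non-overlapping descendant generations.
#' @param offspring_per_mating litter size per mating pair.
#' @param n_chromosomes,markers_per_chromosome,chromosome_length_bp genome
#'   layout; recombination uses a Haldane map at 1 cM/Mb.
#' @param founder_maf_range founder allele frequencies are drawn uniformly
#'   from this range.
#' @param n_qtl number of markers given explicit QTL effects.
#' @param qtl_variance_fraction fraction of the additive variance carried by
#'   the explicit QTL; the remainder is an infinitesimal polygenic term bred
#'   down the pedigree.
#' @param target_h2 named vector of per-trait heritabilities (phenotypic
#'   variance is 1 per trait, so `sigma2_a = h2`).
#' @param genetic_correlation_targets named vector of genetic correlations,
#'   names `"T1:T2"`.
#' @param residual_correlation_targets named vector of residual correlations,
#'   same naming; default none (zero).
#' @param fixed_effect_levels integer vector `(n_flock, n_year, n_season)`.
#' @param genotyped_fraction fraction of phenotyped animals flagged genotyped.
#' @param phenotype_sex `"F"` (females only, as in the study design) or
#'   `"both"`.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 400L,
                       n_generations = 3L,
                       offspring_per_mating = 2L,
                       n_chromosomes = 26L,
                       markers_per_chromosome = 200L,
                       chromosome_length_bp = 1e8,
                       founder_maf_range = c(0.05, 0.5),
                       n_qtl = 50L,
                       qtl_variance_fraction = 0.3,
                       target_h2 = c(MFD = 0.36, CVFD = 0.05, CN = 0.07,
                                     MSL = 0.27, GFW = 0.28, LW = 0.33),
                       genetic_correlation_targets = default_genetic_correlations(),
                       residual_correlation_targets = NULL,
                       fixed_effect_levels = c(n_flock = 50L, n_year = 8L,
                                               n_season = 2L),
                       genotyped_fraction = 0.17,
                       phenotype_sex = c("F", "both"),
                       seed = 1L) {
  phenotype_sex <- match.arg(phenotype_sex)
  if (n_founders < 2L) {
    stop_sswool("need at least 2 founders", class = "sswool_config_error")
  }
  if (qtl_variance_fraction < 0 || qtl_variance_fraction > 1) {
    stop_sswool("qtl_variance_fraction must lie in [0, 1]",
                class = "sswool_config_error")
  }
  if (n_qtl > n_chromosomes * markers_per_chromosome) {
    stop_sswool("n_qtl exceeds total marker count", class = "sswool_config_error")
  }
  if (any(target_h2 < 0) || any(target_h2 >= 1)) {
    stop_sswool("target heritabilities must lie in [0, 1)",
                class = "sswool_config_error")
  }
  structure(list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    offspring_per_mating = as.integer(offspring_per_mating),
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    chromosome_length_bp = chromosome_length_bp,
    founder_maf_range = founder_maf_range,
    n_qtl = as.integer(n_qtl),
    qtl_variance_fraction = qtl_variance_fraction,
    target_h2 = target_h2,
    genetic_correlation_targets = genetic_correlation_targets,
    residual_correlation_targets = residual_correlation_targets,
    fixed_effect_levels = fixed_effect_levels,
    genotyped_fraction = genotyped_fraction,
    phenotype_sex = phenotype_sex,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Published genetic correlations among the six wool/weight traits
#'
#' Used as the default simulation targets for the six-trait configuration.
#' @return named vector, names `"T1:T2"`.
#' @export
default_genetic_correlations <- function() {
  c("MFD:CVFD" = -0.21, "MFD:CN" = 0.11, "MFD:MSL" = 0.29, "MFD:GFW" = 0.06,
    "MFD:LW" = 0.14, "CVFD:CN" = 0.06, "CVFD:MSL" = 0.02, "CVFD:GFW" = 0.05,
    "CVFD:LW" = 0.05, "CN:MSL" = -0.18, "CN:GFW" = -0.25, "CN:LW" = -0.44,
    "MSL:GFW" = 0.24, "MSL:LW" = 0.29, "GFW:LW" = 0.77)
}

#' Simulate a multi-generation pedigree with non-overlapping generations
#'
#' Founders are split evenly by sex; each later generation is produced by
#' random monogamous matings of the previous generation (no selfing by
#' construction). Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return pedigree data.frame (`animal`, `sire`, `dam`) with extra columns
#'   `sex` ("M"/"F") and `generation`, in topological order.
#' @export
simulate_pedigree <- function(config) {
  set.seed(derive_seed(config$seed, "pedigree"))
  nf <- config$n_founders
  if (nf < 2L || nf %% 2L != 0L) {
    stop_sswool("n_founders must be even and >= 2 for a mating structure",
                class = "sswool_config_error")
  }
  ped <- data.frame(animal = sprintf("G0_%04d", seq_len(nf)),
                    sire = NA_character_, dam = NA_character_,
                    sex = rep(c("M", "F"), nf / 2L),
                    generation = 0L, stringsAsFactors = FALSE)
  prev <- ped
  for (g in seq_len(config$n_generations)) {
    males <- sample(prev$animal[prev$sex == "M"])
    females <- sample(prev$animal[prev$sex == "F"])
    n_pairs <- min(length(males), length(females))
    if (n_pairs == 0L) {
      stop_sswool("generation %d has no mating pairs", g,
                  class = "sswool_config_error")
    }
    n_off <- n_pairs * config$offspring_per_mating
    pair <- rep(seq_len(n_pairs), each = config$offspring_per_mating)
    gen <- data.frame(animal = sprintf("G%d_%04d", g, seq_len(n_off)),
                      sire = males[pair], dam = females[pair],
                      sex = sample(c("M", "F"), n_off, replace = TRUE),
                      generation = g, stringsAsFactors = FALSE)
    ped <- rbind(ped, gen)
    prev <- gen
  }
  rownames(ped) <- NULL
  ped
}

#' Simulate a marker map
#'
#' Markers are placed at sorted uniform positions along each chromosome.
#'
#' @param config a [sim_config()].
#' @return marker map data.frame (`snp`, `chrom`, `pos`, `a1`, `a2`).
#' @export
simulate_marker_map <- function(config) {
  set.seed(derive_seed(config$seed, "map"))
  chroms <- as.character(seq_len(config$n_chromosomes))
  m <- config$markers_per_chromosome
  maps <- lapply(chroms, function(ch) {
    pos <- sort(sample.int(config$chromosome_length_bp, m))
    data.frame(snp = sprintf("snp%s_%04d", ch, seq_len(m)),
               chrom = ch, pos = pos, a1 = "A", a2 = "C",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  out
}

# One gamete from a parent: recombine its two haplotypes with Poisson
# crossovers at 1 cM/Mb (Haldane), per chromosome.
recombine_gamete <- function(h1, h2, map_pos, chrom_index) {
  phase <- logical(length(h1))
  for (ci in seq_along(chrom_index)) {
    idx <- chrom_index[[ci]]
    pos <- map_pos[idx]
    span <- max(pos)
    n_x <- stats::rpois(1L, span * 1e-8)  # 1 cM/Mb
    start <- stats::runif(1) < 0.5
    if (n_x == 0L) {
      phase[idx] <- start
    } else {
      xpos <- sort(stats::runif(n_x, 0, span))
      n_before <- findInterval(pos, xpos)
      phase[idx] <- xor(start, n_before %% 2L == 1L)
    }
  }
  ifelse(phase, h2, h1)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder haplotypes are drawn in Hardy-Weinberg proportions at allele
#' frequencies sampled uniformly from `founder_maf_range`; descendants
#' receive one recombinant gamete per known parent (Haldane map, 1 cM/Mb).
#' A gamete from an unknown parent is drawn from the founder frequencies.
#'
#' @param pedigree pedigree in topological order (see [simulate_pedigree()]).
#' @param map marker map (see [simulate_marker_map()]).
#' @param config a [sim_config()].
#' @return integer dosage matrix, individuals x markers (0/1/2), with
#'   attribute `founder_freq` (the drawn founder allele frequencies).
#' @export
simulate_genotypes <- function(pedigree, map, config) {
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- nrow(pedigree); m <- nrow(map)
  p <- stats::runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  chrom_index <- split(seq_len(m), factor(map$chrom, levels = unique(map$chrom)))
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  idx <- seq_len(n); names(idx) <- pedigree$animal
  si <- unname(idx[pedigree$sire]); di <- unname(idx[pedigree$dam])
  draw_founder_gamete <- function() as.integer(stats::runif(m) < p)
  for (i in seq_len(n)) {
    H1[i, ] <- if (is.na(si[i])) draw_founder_gamete() else
      recombine_gamete(H1[si[i], ], H2[si[i], ], map$pos, chrom_index)
    H2[i, ] <- if (is.na(di[i])) draw_founder_gamete() else
      recombine_gamete(H1[di[i], ], H2[di[i], ], map$pos, chrom_index)
  }
  geno <- H1 + H2
  dimnames(geno) <- list(pedigree$animal, map$snp)
  attr(geno, "founder_freq") <- p
  geno
}

# Symmetric PSD square root (tolerates zero-variance traits).
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Assemble a covariance matrix from per-trait variances and "T1:T2"-named
# correlations, projecting to the nearest PSD matrix if needed.
build_cov <- function(vars, corr_targets) {
  traits <- names(vars)
  k <- length(traits)
  R <- diag(k); dimnames(R) <- list(traits, traits)
  for (nm in names(corr_targets)) {
    pr <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    if (all(pr %in% traits)) {
      R[pr[1], pr[2]] <- R[pr[2], pr[1]] <- corr_targets[[nm]]
    }
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  }
  S <- diag(sqrt(vars), k) %*% R %*% diag(sqrt(vars), k)
  dimnames(S) <- list(traits, traits)
  S
}

#' Simulate phenotypes with polygenic + QTL architecture
#'
#' True breeding values are the sum of explicit QTL effects on centred
#' dosages and an infinitesimal polygenic term bred down the pedigree
#' (parent average plus Mendelian sampling, variance halved per known
#' parent). Phenotypes add fixed effects (flock, birth year, season; level
#' values drawn once from `N(0, (0.5 sd_p)^2)`) and a residual. Phenotypic
#' variance is 1 per trait, so `sigma2_a = h2` and `sigma2_e = 1 - h2`.
#'
#' @param pedigree pedigree from [simulate_pedigree()] (needs `sex` column
#'   when `phenotype_sex = "F"`).
#' @param genotypes dosage matrix from [simulate_genotypes()].
#' @param map marker map matching `genotypes` columns.
#' @param config a [sim_config()].
#' @return list with `phenotypes` (data.frame: `animal`, `flock`, `year`,
#'   `season`, `sex`, one column per trait), `truth` (true breeding values,
#'   QTL positions/effects, true (co)variances, genotyped ids) — the
#'   genotyped ids are a random subset of phenotyped animals of size
#'   `genotyped_fraction`.
#' @export
simulate_phenotypes <- function(pedigree, genotypes, map, config) {
  set.seed(derive_seed(config$seed, "phenotypes"))
  traits <- names(config$target_h2)
  k <- length(traits)
  n <- nrow(pedigree)
  sigma2_a <- config$target_h2
  sigma2_e <- 1 - config$target_h2
  Sig_a <- build_cov(sigma2_a, config$genetic_correlation_targets)
  Sig_e <- build_cov(sigma2_e, config$residual_correlation_targets %||% numeric())
  qvf <- config$qtl_variance_fraction

  founders <- which(is.na(pedigree$sire) & is.na(pedigree$dam))

  # explicit QTL on centred dosages, scaled to qvf * sigma2_a among founders
  Q <- matrix(0, n, k, dimnames = list(pedigree$animal, traits))
  qtl <- NULL
  if (config$n_qtl > 0L && qvf > 0) {
    qtl_idx <- sort(sample.int(ncol(genotypes), config$n_qtl))
    beta <- matrix(stats::rnorm(config$n_qtl * k), config$n_qtl, k) %*%
      chol_cor(Sig_a)
    pbar <- colMeans(genotypes[founders, qtl_idx, drop = FALSE]) / 2
    Zq <- sweep(genotypes[, qtl_idx, drop = FALSE], 2L, 2 * pbar)
    # each QTL contributes an equal share qvf * sigma2_a / n_qtl of the
    # additive variance (measured among founders), so every planted locus is
    # individually detectable
    vq <- apply(Zq[founders, , drop = FALSE], 2L, stats::var)
    for (t in seq_len(k)) {
      target_per_qtl <- qvf * sigma2_a[t] / config$n_qtl
      s <- ifelse(target_per_qtl <= 0 | beta[, t]^2 * vq <= 0, 0,
                  sqrt(target_per_qtl / (beta[, t]^2 * vq)))
      beta[, t] <- beta[, t] * s
    }
    Q <- Zq %*% beta
    dimnames(Q) <- list(pedigree$animal, traits)
    qtl <- data.frame(snp = colnames(genotypes)[qtl_idx],
                      chrom = map$chrom[qtl_idx], pos = map$pos[qtl_idx])
    qtl <- cbind(qtl, as.data.frame(beta))
    names(qtl)[-(1:3)] <- paste0("effect_", traits)
  }

  # infinitesimal polygenic term bred down the pedigree
  L_poly <- psd_sqrt((1 - qvf) * Sig_a)
  idx <- seq_len(n); names(idx) <- pedigree$animal
  si <- unname(idx[pedigree$sire]); di <- unname(idx[pedigree$dam])
  PG <- matrix(0, n, k)
  for (i in seq_len(n)) {
    n_known <- (!is.na(si[i])) + (!is.na(di[i]))
    pa <- (if (is.na(si[i])) 0 else 0.5 * PG[si[i], ]) +
      (if (is.na(di[i])) 0 else 0.5 * PG[di[i], ])
    ms_scale <- sqrt(1 - 0.25 * n_known)
    PG[i, ] <- pa + ms_scale * drop(L_poly %*% stats::rnorm(k))
  }
  tbv <- Q + PG

  # fixed effects and residuals
  lev <- config$fixed_effect_levels
  flock <- factor(sample.int(lev[[1]], n, replace = TRUE))
  year <- factor(sample.int(lev[[2]], n, replace = TRUE))
  season <- factor(sample.int(lev[[3]], n, replace = TRUE))
  E <- matrix(stats::rnorm(n * k), n, k) %*% psd_sqrt(Sig_e)
  y <- tbv + E
  for (t in seq_len(k)) {
    sd_fix <- 0.5 * 1  # phenotypic SD is 1 by construction
    fe <- stats::rnorm(lev[[1]], 0, sd_fix)[flock] +
      stats::rnorm(lev[[2]], 0, sd_fix)[year] +
      stats::rnorm(lev[[3]], 0, sd_fix)[season]
    y[, t] <- y[, t] + fe
  }
  colnames(y) <- traits

  phen <- data.frame(animal = pedigree$animal, flock = flock, year = year,
                     season = season,
                     sex = pedigree$sex %||% rep("F", n),
                     stringsAsFactors = FALSE)
  phen <- cbind(phen, as.data.frame(y))
  if (config$phenotype_sex == "F" && !is.null(pedigree$sex)) {
    phen <- phen[phen$sex == "F", , drop = FALSE]
  }
  rownames(phen) <- NULL
  genotyped <- sort(sample(phen$animal,
                           max(2L, round(config$genotyped_fraction * nrow(phen)))))
  truth <- list(
    true_breeding_values = tbv,
    qtl = qtl,
    sigma2_a = sigma2_a, sigma2_e = sigma2_e,
    cov_a = Sig_a, cov_e = Sig_e,
    genotyped_ids = genotyped
  )
  list(phenotypes = phen, truth = truth)
}

# Cholesky-style factor of the correlation structure of S (unit row scale),
# used to give raw QTL effects the target cross-trait correlation before
# per-trait rescaling.
chol_cor <- function(S) {
  d <- sqrt(diag(S))
  d[d == 0] <- 1
  R <- S / outer(d, d)
  t(psd_sqrt(R))
}

#' Simulate a gene annotation on the synthetic genome
#'
#' Places genes at uniform positions on the simulated chromosomes with
#' log-normal lengths (median ~20 kb), 1-based inclusive coordinates.
#'
#' @param n_genes number of genes.
#' @param config a [sim_config()] (for chromosome count/length).
#' @param gene_ids optional ids (default `gene00001`, ...), e.g. the row
#'   names of a simulated expression atlas so GWAS and expression share a
#'   gene universe.
#' @return gene annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
simulate_gene_annotation <- function(n_genes, config, gene_ids = NULL) {
  set.seed(derive_seed(config$seed, "gene_annotation"))
  gene_ids <- gene_ids %||% sprintf("gene%05d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  chrom <- as.character(sample.int(config$n_chromosomes, n_genes, replace = TRUE))
  len <- pmin(round(stats::rlnorm(n_genes, log(2e4), 0.8)),
              config$chromosome_length_bp %/% 2)
  start <- floor(stats::runif(n_genes, 1, config$chromosome_length_bp - len))
  ann <- data.frame(gene_id = gene_ids, chrom = chrom,
                    start = as.integer(start),
                    end = as.integer(start + len - 1),
                    strand = sample(c("+", "-"), n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
  ann <- ann[order(as.numeric(ann$chrom), ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

# ---- Expression atlas -------------------------------------------------------

#' Build a sample-metadata template for the expression atlas
#'
#' Emulates a multi-tissue atlas: `n_tissues` tissues distributed over the 13
#' organ systems, `samples_per_tissue` samples each, with developmental-stage
#' and sex labels cycled over samples.
#'
#' @param n_tissues number of tissues/cell types (default 87).
#' @param samples_per_tissue samples per tissue (default 6).
#' @return data.frame (`sample_id`, `tissue`, `organ_system`, `age_stage`,
#'   `sex`).
#' @export
atlas_metadata_template <- function(n_tissues = 87L, samples_per_tissue = 6L) {
  systems <- c("CNS", "Cardio", "Skin", "Muscle", "Liver", "Lung", "Kidney",
               "GI", "Endoc", "Immune", "Male_R", "Fem_R", "Embryonic")
  if (samples_per_tissue < 2L) {
    stop_sswool("need >= 2 samples per tissue", class = "sswool_config_error")
  }
  sys_of_tissue <- systems[(seq_len(n_tissues) - 1L) %% length(systems) + 1L]
  tissue <- sprintf("%s_t%02d", sys_of_tissue,
                    stats::ave(seq_len(n_tissues), sys_of_tissue,
                               FUN = seq_along))
  df <- data.frame(
    tissue = rep(tissue, each = samples_per_tissue),
    organ_system = rep(sys_of_tissue, each = samples_per_tissue),
    stringsAsFactors = FALSE)
  ns <- nrow(df)
  df$sample_id <- sprintf("s%04d", seq_len(ns))
  df$age_stage <- rep_len(c("adult", "lamb", "embryo"), ns)
  df$sex <- rep_len(c("M", "F"), ns)
  df[, c("sample_id", "tissue", "organ_system", "age_stage", "sex")]
}

#' Simulate a multi-tissue TPM expression atlas with planted specific genes
#'
#' Each gene gets a baseline log2 expression drawn once; planted
#' tissue-specific genes get `+log2(fold_change)` in their target tissue;
#' i.i.d. Gaussian noise is added per sample; the matrix is then rescaled so
#' every sample (column) sums to 1e6 (TPM).
#'
#' @param n_genes number of genes.
#' @param metadata sample metadata (see [atlas_metadata_template()]).
#' @param spec_fraction fraction of genes planted as specific *per target
#'   tissue* (disjoint sets across tissues), in (0, 0.5).
#' @param fold_change linear fold change of planted genes in their tissue
#'   (> 1).
#' @param seed integer seed.
#' @param spec_tissues tissues that receive planted genes (default: all in
#'   `metadata`; the per-tissue count times the number of target tissues must
#'   not exceed `n_genes`).
#' @param noise_sd per-sample log2 noise SD (default 1).
#' @return list with `tpm` (genes x samples matrix, columns sum to 1e6),
#'   `metadata`, and `truth` (list `planted`: tissue -> gene ids).
#' @export
simulate_expression_atlas <- function(n_genes, metadata,
                                      spec_fraction = 0.10, fold_change = 8,
                                      seed = 1L,
                                      spec_tissues = unique(metadata$tissue),
                                      noise_sd = 1) {
  if (spec_fraction <= 0 || spec_fraction >= 0.5) {
    stop_sswool("spec_fraction must lie in (0, 0.5)", class = "sswool_config_error")
  }
  if (fold_change <= 1) {
    stop_sswool("fold_change must exceed 1", class = "sswool_config_error")
  }
  if (any(table(metadata$tissue) < 2L)) {
    stop_sswool("every tissue needs >= 2 samples", class = "sswool_config_error")
  }
  spec_tissues <- unique(spec_tissues)
  if (!all(spec_tissues %in% metadata$tissue)) {
    stop_sswool("spec_tissues not present in metadata: %s",
                paste(setdiff(spec_tissues, metadata$tissue), collapse = ", "),
                class = "sswool_config_error")
  }
  set.seed(derive_seed(seed, "atlas"))
  n_spec <- floor(spec_fraction * n_genes)
  if (n_spec * length(spec_tissues) > n_genes) {
    stop_sswool(paste0("cannot plant %d genes in each of %d tissues with only ",
                       "%d genes; reduce spec_fraction or spec_tissues"),
                n_spec, length(spec_tissues), n_genes,
                class = "sswool_config_error")
  }
  ns <- nrow(metadata)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  base <- stats::rnorm(n_genes, mean = 3, sd = 2)
  logx <- matrix(base, n_genes, ns) +
    matrix(stats::rnorm(n_genes * ns, 0, noise_sd), n_genes, ns)
  pool <- sample.int(n_genes)  # disjoint allocation of planted genes
  planted <- list()
  offset <- 0L
  for (tis in spec_tissues) {
    gidx <- pool[offset + seq_len(n_spec)]
    offset <- offset + n_spec
    cols <- which(metadata$tissue == tis)
    logx[gidx, cols] <- logx[gidx, cols] + log2(fold_change)
    planted[[tis]] <- sort(gene_ids[gidx])
  }
  x <- 2^logx
  tpm <- sweep(x, 2L, colSums(x), "/") * 1e6
  dimnames(tpm) <- list(gene_ids, metadata$sample_id)
  list(tpm = tpm, metadata = metadata, truth = list(planted = planted))
}
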