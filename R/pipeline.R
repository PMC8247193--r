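# End-to-end orchestration on synthetic data: simulate -> QC -> REML ->
# WssGWAS -> tissue specificity -> enrichment, with deterministic per-stage
# seeds and tab-separated outputs plus a JSON manifest per run directory.

#' Pipeline configuration with the study's printed analysis settings
#'
#' Defaults: 20-SNP sliding windows, top 10 windows as QTL regions, top 1%
#' of windows for gene lists, top 10% of genes as tissue-specific, 20-kb
#' gene extensions and 10000 cyclical permutations for enrichment.
#'
#' @param sim a [sim_config()] for the genetic simulation.
#' @param gwas_traits traits taken through WssGWAS (default: first two of
#'   the simulated traits, to keep a full run light).
#' @param correlation_pairs list of trait pairs for bivariate REML (default:
#'   the consecutive pairs of `gwas_traits`).
#' @param n_atlas_genes,atlas_spec_fraction,atlas_fold_change expression
#'   atlas size and planted-signal settings.
#' @param window_size,top_k,top_fraction,tissue_fraction,extension_bp,n_perm
#'   analysis parameters (defaults are the published analysis settings).
#' @param stages stages to execute, in dependency order.
#' @param seed global seed; every stage derives its own stream.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            gwas_traits = names(sim$target_h2)[1:2],
                            correlation_pairs = NULL,
                            n_atlas_genes = 4000L,
                            atlas_spec_fraction = 0.01,
                            atlas_fold_change = 8,
                            window_size = 20L,
                            top_k = 10L,
                            top_fraction = 0.01,
                            tissue_fraction = 0.10,
                            extension_bp = 20000L,
                            n_perm = 10000L,
                            stages = c("simulate", "qc", "reml", "wssgwas",
                                       "tissuespec", "enrich"),
                            seed = 1L) {
  if (is.null(correlation_pairs) && length(gwas_traits) >= 2L) {
    correlation_pairs <- list(gwas_traits[1:2])
  }
  structure(list(sim = sim, gwas_traits = gwas_traits,
                 correlation_pairs = correlation_pairs,
                 n_atlas_genes = as.integer(n_atlas_genes),
                 atlas_spec_fraction = atlas_spec_fraction,
                 atlas_fold_change = atlas_fold_change,
                 window_size = as.integer(window_size),
                 top_k = as.integer(top_k), top_fraction = top_fraction,
                 tissue_fraction = tissue_fraction,
                 extension_bp = as.integer(extension_bp),
                 n_perm = as.integer(n_perm), stages = stages,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the synthetic-data pipeline end-to-end
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' tables under `out_dir` and a manifest (`manifest.json`) with the full
#' configuration. Re-running with an identical configuration reproduces
#' identical files. A stage whose prerequisite was neither run nor found on
#' disk raises a dependency error.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly; the stage results are also returned in the
#'   attribute `state`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, "simulate")

  need <- function(what, stage) {
    if (!exists(what, envir = st)) {
      stop_sswool("stage '%s' needs '%s' from an earlier stage; enable it",
                  stage, what, class = "sswool_dependency_error")
    }
    get(what, envir = st)
  }

  if ("simulate" %in% config$stages) {
    st$pedigree <- simulate_pedigree(sim)
    st$map <- simulate_marker_map(sim)
    st$genotypes <- simulate_genotypes(st$pedigree, st$map, sim)
    ph <- simulate_phenotypes(st$pedigree, st$genotypes, st$map, sim)
    st$phenotypes <- ph$phenotypes
    st$truth <- ph$truth
    write_pedigree(st$pedigree[, c("animal", "sire", "dam")],
                   file.path(out_dir, "pedigree.tsv"))
    write_table(st$phenotypes, file.path(out_dir, "phenotypes.tsv"))
    write_genotypes(st$genotypes[ph$truth$genotyped_ids, , drop = FALSE],
                    st$map, file.path(out_dir, "genotypes"), "plink_text")
    message(sprintf("simulate: %d animals, %d phenotyped, %d genotyped, %d markers",
                    nrow(st$pedigree), nrow(st$phenotypes),
                    length(ph$truth$genotyped_ids), ncol(st$genotypes)))
  }

  if ("qc" %in% config$stages) {
    geno_g <- need("genotypes", "qc")[need("truth", "qc")$genotyped_ids, , drop = FALSE]
    qc <- qc_filter(geno_g, need("map", "qc"))
    st$geno_qc <- qc$genotypes
    st$map_qc <- qc$map
    st$phen_qc <- phenotype_outlier_filter(
      need("phenotypes", "qc"),
      traits = names(sim$target_h2))
    jsonlite::write_json(qc$report, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    message(sprintf("qc: %d -> %d markers, %d individuals removed",
                    qc$report$n_markers_in, qc$report$n_markers_out,
                    qc$report$removed_individuals))
  }

  if ("reml" %in% config$stages) {
    ped <- need("pedigree", "reml")
    phen <- need("phen_qc", "reml")
    A <- numerator_relationship(ped)
    st$A <- A
    fits <- lapply(names(sim$target_h2), function(tr) {
      f <- reml_fit(phen, tr, A)
      data.frame(trait = tr, sigma2_a = f$sigma2_a, sigma2_e = f$sigma2_e,
                 h2 = unname(f$h2), h2_se = unname(f$h2_se),
                 converged = f$converged, n_iterations = f$n_iterations)
    })
    st$vc_table <- do.call(rbind, fits)
    write_table(st$vc_table, file.path(out_dir, "variance_components.tsv"))
    cors <- lapply(config$correlation_pairs %||% list(), function(pr) {
      f <- reml_fit(phen, pr, A)
      data.frame(trait1 = pr[1], trait2 = pr[2],
                 r_g = unname(f$r_g), r_g_se = unname(f$r_g_se),
                 r_p = unname(f$r_p), converged = f$converged)
    })
    if (length(cors)) {
      st$cor_table <- do.call(rbind, cors)
      write_table(st$cor_table, file.path(out_dir, "genetic_correlations.tsv"))
    }
    message(sprintf("reml: h2 = %s",
                    paste(sprintf("%s %.2f", st$vc_table$trait, st$vc_table$h2),
                          collapse = ", ")))
  }

  if ("wssgwas" %in% config$stages) {
    phen <- need("phen_qc", "wssgwas")
    vc <- need("vc_table", "wssgwas")
    all_windows <- list(); all_regions <- list(); st$effects <- list()
    for (tr in config$gwas_traits) {
      v <- vc[vc$trait == tr, ]
      ws <- run_wssgwas(phen, tr, need("pedigree", "wssgwas"),
                        need("geno_qc", "wssgwas"),
                        sigma2_a = v$sigma2_a, sigma2_e = v$sigma2_e)
      wv <- window_variances(ws$u, ws$Zc, need("map_qc", "wssgwas"),
                             v$sigma2_a, config$window_size)
      wv$trait <- tr
      all_windows[[tr]] <- wv
      reg <- top_windows(wv, config$top_k)
      reg$trait <- tr
      all_regions[[tr]] <- reg
      st$effects[[tr]] <- ws$u
    }
    st$windows <- do.call(rbind, all_windows)
    st$qtl_regions <- do.call(rbind, all_regions)
    write_table(st$windows[, c("trait", "chrom", "start_bp", "end_bp",
                               "pct_variance", "rank", "truncated")],
                file.path(out_dir, "window_variances.tsv"))
    write_table(st$qtl_regions, file.path(out_dir, "qtl_regions.tsv"))
    message(sprintf("wssgwas: %d windows per trait, top-%d regions written",
                    sum(st$windows$trait == config$gwas_traits[1]),
                    config$top_k))
  }

  if ("tissuespec" %in% config$stages) {
    meta <- atlas_metadata_template()
    # plant specific genes in one representative tissue per organ system
    spec_tissues <- meta$tissue[match(unique(meta$organ_system),
                                      meta$organ_system)]
    atlas <- simulate_expression_atlas(
      config$n_atlas_genes, meta,
      spec_fraction = config$atlas_spec_fraction,
      fold_change = config$atlas_fold_change,
      spec_tissues = spec_tissues,
      seed = derive_seed(config$seed, "atlas"))
    st$atlas <- atlas
    scaled <- scale_expression(atlas$tpm)
    st$scaled <- scaled
    systems <- unique(meta$organ_system)
    st$gene_sets <- lapply(stats::setNames(systems, systems), function(sy) {
      tissue_specific_genes(tissue_specificity(scaled, meta, sy),
                            config$tissue_fraction)
    })
    sets_df <- data.frame(
      organ_system = rep(names(st$gene_sets), lengths(st$gene_sets)),
      gene_id = unlist(st$gene_sets, use.names = FALSE))
    write_table(sets_df, file.path(out_dir, "tissue_specific_genes.tsv"))
    message(sprintf("tissuespec: %d organ systems, %d genes per set",
                    length(st$gene_sets), length(st$gene_sets[[1]])))
  }

  if ("enrich" %in% config$stages) {
    effects <- need("effects", "enrich")
    gene_sets <- need("gene_sets", "enrich")
    ann <- simulate_gene_annotation(config$n_atlas_genes, sim,
                                    gene_ids = rownames(need("atlas", "enrich")$tpm))
    st$annotation <- ann
    st$enrichment <- enrich_all(effects, gene_sets, ann,
                                need("map_qc", "enrich"),
                                extension_bp = config$extension_bp,
                                n_perm = config$n_perm,
                                seed = derive_seed(config$seed, "enrich"))
    write_table(st$enrichment, file.path(out_dir, "enrichment.tsv"))
    message(sprintf("enrich: %d trait x set tests, min FDR %.3g",
                    nrow(st$enrichment), min(st$enrichment$fdr, na.rm = TRUE)))
  }

  manifest <- list(seed = config$seed, stages = config$stages,
                   parameters = config[setdiff(names(config), c("sim"))],
                   sim = unclass(sim),
                   package_version = as.character(utils::packageVersion("sswool")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- out_dir
  attr(out, "state") <- as.list(st)
  invisible(out)
}
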