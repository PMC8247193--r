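#!/usr/bin/env Rscript
# Simulate the study-like population: pedigree, gene-dropped genotypes,
# six correlated traits with planted QTL, and a gene annotation. Writes all
# fixtures in standard formats under results/data/.
source("analysis/config.R")

ped <- simulate_pedigree(study_config)
map <- simulate_marker_map(study_config)
geno <- simulate_genotypes(ped, map, study_config)
ph <- simulate_phenotypes(ped, geno, map, study_config)
ann <- simulate_gene_annotation(N_ATLAS_GENES, study_config)

write_pedigree(ped[, c("animal", "sire", "dam")],
               file.path(DATA_DIR, "pedigree.tsv"))
write_table(ph$phenotypes, file.path(DATA_DIR, "phenotypes.tsv"))
write_genotypes(geno[ph$truth$genotyped_ids, , drop = FALSE], map,
                file.path(DATA_DIR, "genotypes"), "plink_text")
# BED4 (0-based half-open on disk; readers convert back)
writeLines(sprintf("%s\t%d\t%d\t%s", ann$chrom, ann$start - 1L, ann$end,
                   ann$gene_id),
           file.path(DATA_DIR, "genes.bed"))
jsonlite::write_json(
  list(qtl = ph$truth$qtl, sigma2_a = as.list(ph$truth$sigma2_a),
       genotyped_ids = ph$truth$genotyped_ids),
  file.path(DATA_DIR, "truth.json"), auto_unbox = TRUE, digits = NA)

tbv <- ph$truth$true_breeding_values
founders <- which(is.na(ped$sire))
message(sprintf("simulated %d animals (%d founders), %d phenotyped females, %d genotyped",
                nrow(ped), length(founders), nrow(ph$phenotypes),
                length(ph$truth$genotyped_ids)))
message(sprintf("markers: %d on %d chromosomes; planted QTL: %d carrying %.0f%% of sigma2_a",
                ncol(geno), study_config$n_chromosomes, study_config$n_qtl,
                100 * study_config$qtl_variance_fraction))
message(sprintf("realized founder additive variance (MFD): %.3f (target %.3f)",
                var(tbv[founders, "MFD"]), study_config$target_h2[["MFD"]]))
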