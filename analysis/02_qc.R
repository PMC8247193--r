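#!/usr/bin/env Rscript
# Marker/individual quality control and phenotype outlier filtering, applied
# to the simulated data exactly as the array-data rules prescribe: call rate
# >= 90%, MAF >= 1%, HWE p >= 1e-6, mapped autosomal SNPs only; phenotype
# records beyond 3 SD set to missing.
source("analysis/config.R")

gt <- read_genotypes(file.path(DATA_DIR, "genotypes"), "plink_text")
qc <- qc_filter(gt$genotypes, gt$map)
phen <- utils::read.delim(file.path(DATA_DIR, "phenotypes.tsv"),
                          colClasses = c(animal = "character"))
phen_f <- phenotype_outlier_filter(phen, traits = names(study_config$target_h2))

write_genotypes(qc$genotypes, qc$map, file.path(DATA_DIR, "genotypes_qc"),
                "plink_text")
write_table(phen_f, file.path(DATA_DIR, "phenotypes_qc.tsv"))
jsonlite::write_json(qc$report, file.path(RES_DIR, "qc_report.json"),
                     auto_unbox = TRUE, pretty = TRUE)

n_out <- sum(is.na(phen_f[names(study_config$target_h2)])) -
  sum(is.na(phen[names(study_config$target_h2)]))
message(sprintf("markers: %d in, %d out (%s)",
                qc$report$n_markers_in, qc$report$n_markers_out,
                paste(names(unlist(qc$report$removed_markers)),
                      unlist(qc$report$removed_markers),
                      sep = "=", collapse = ", ")))
message(sprintf("individuals removed: %d; phenotype outliers set missing: %d",
                qc$report$removed_individuals, n_out))
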