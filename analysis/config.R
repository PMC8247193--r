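# Shared configuration for the numbered analysis scripts. All randomness
# derives from this single seed; re-running any script reproduces its outputs.
suppressMessages(library(sswool))

SEED <- 20260926L
DATA_DIR <- "results/data"
RES_DIR <- "results"
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

# Desk-scale emulation of the study design: a multi-generation pedigree with
# phenotyped females, six traits at the published heritabilities and genetic
# correlations (sim_config defaults), the published 50/8/2 fixed-effect
# structure, and ~17% of phenotyped animals genotyped.
study_config <- sim_config(
  n_founders = 800L,
  n_generations = 2L,
  offspring_per_mating = 3L,
  n_chromosomes = 5L,
  markers_per_chromosome = 400L,
  chromosome_length_bp = 5e7,
  n_qtl = 25L,
  qtl_variance_fraction = 0.4,
  seed = SEED)

GWAS_TRAITS <- c("MFD", "LW")
CORRELATION_PAIRS <- list(c("GFW", "LW"), c("MFD", "MSL"), c("CN", "LW"))
N_ATLAS_GENES <- 4000L
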