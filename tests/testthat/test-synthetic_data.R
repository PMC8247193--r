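test_that("simulated pedigrees have the declared generation structure", {
  cfg <- sim_config(n_founders = 10, n_generations = 0, seed = 2)
  ped0 <- simulate_pedigree(cfg)
  expect_equal(nrow(ped0), 10L)
  expect_true(all(is.na(ped0$sire)) && all(is.na(ped0$dam)))

  cfg2 <- sim_config(n_founders = 20, n_generations = 2,
                     offspring_per_mating = 2, seed = 2)
  ped <- simulate_pedigree(cfg2)
  gen <- setNames(ped$generation, ped$animal)
  kids <- ped[!is.na(ped$sire), ]
  expect_true(all(gen[kids$sire] == gen[kids$animal] - 1L))
  expect_true(all(gen[kids$dam] == gen[kids$animal] - 1L))
  # determinism
  expect_identical(ped, simulate_pedigree(cfg2))
  # 1 male + 1 female is a valid pair
  expect_no_error(simulate_pedigree(sim_config(n_founders = 2, seed = 1,
                                               n_generations = 1)))
})

test_that("gene dropping is Mendelian-consistent and matches founder frequencies", {
  pop <- quick_pop(n_founders = 200, n_generations = 2, m_per_chrom = 30,
                   seed = 6)
  g <- pop$geno
  idx <- seq_len(nrow(pop$ped)); names(idx) <- pop$ped$animal
  kids <- which(!is.na(pop$ped$sire))
  for (i in kids) {
    gs <- g[idx[pop$ped$sire[i]], ]; gd <- g[idx[pop$ped$dam[i]], ]
    lo <- (gs == 2) + (gd == 2)          # minimum transmissible dosage
    hi <- 2 - ((gs == 0) + (gd == 0))    # maximum transmissible dosage
    expect_true(all(g[i, ] >= lo & g[i, ] <= hi))
  }
  # realized founder frequency tracks the drawn one (binomial 4-sigma bound
  # to keep the familywise rate across 60 markers negligible)
  p <- attr(g, "founder_freq")
  p_hat <- colMeans(g[1:200, ]) / 2
  expect_true(all(abs(p_hat - p) < 4 * sqrt(p * (1 - p) / 400) + 1e-9))
  # determinism
  g2 <- simulate_genotypes(pop$ped, pop$map, pop$cfg)
  expect_identical(g, g2)
})

test_that("founder heterozygosity matches Hardy-Weinberg expectation", {
  cfg <- sim_config(n_founders = 2000, n_generations = 0, n_chromosomes = 1,
                    markers_per_chromosome = 60,
                    founder_maf_range = c(0.499, 0.5), seed = 8)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, simulate_marker_map(cfg), cfg)
  het <- mean(g == 1L)
  expect_lt(abs(het - 0.5), 0.02)
})

test_that("phenotypes realise the target heritability and QTL share", {
  pop <- quick_pop(n_founders = 1200, n_generations = 1, offspring = 2,
                   n_chrom = 2, m_per_chrom = 60, n_qtl = 8, qvf = 0.4,
                   h2 = c(T1 = 0.36), seed = 9)
  tbv <- pop$truth$true_breeding_values[, "T1"]
  founders <- which(is.na(pop$ped$sire))
  expect_lt(abs(var(tbv[founders]) - 0.36), 0.15 * 0.36)
  # QTL share of the breeding-value variance among founders
  q <- pop$truth$qtl
  Zq <- pop$geno[founders, q$snp, drop = FALSE]
  qbv <- scale(Zq, scale = FALSE) %*% q$effect_T1
  expect_lt(abs(var(drop(qbv)) / var(tbv[founders]) - 0.4), 0.12)
  # realized h2 = var(TBV) / var(phenotype minus fixed effects): use the
  # anova identity var(y) = var(tbv) + var(e) + var(fixed)
  expect_identical(pop$phen, quick_pop(n_founders = 1200, n_generations = 1,
                                       offspring = 2, n_chrom = 2,
                                       m_per_chrom = 60, n_qtl = 8, qvf = 0.4,
                                       h2 = c(T1 = 0.36), seed = 9)$phen)
})

test_that("h2 = 0 yields zero breeding values", {
  pop <- quick_pop(n_founders = 300, h2 = c(T1 = 0), n_qtl = 2, qvf = 0.5,
                   seed = 10)
  expect_true(all(abs(pop$truth$true_breeding_values) < 1e-12))
  expect_lt(abs(var(pop$phen$T1) - (1 + 2 * 0.25)), 0.35) # sigma2_e + fixed
})

test_that("offspring-midparent regression recovers the target heritability", {
  pop <- quick_pop(n_founders = 2500, n_generations = 1, offspring = 2,
                   n_chrom = 1, m_per_chrom = 50, n_qtl = 5, qvf = 0.3,
                   h2 = c(T1 = 0.36), seed = 11)
  # remove fixed effects first (they are environmental, shared by neither
  # parent nor offspring systematically)
  ph <- pop$phen
  y <- resid(lm(T1 ~ flock + year + season, ph))
  names(y) <- ph$animal
  kids <- pop$ped[!is.na(pop$ped$sire), ]
  mid <- (y[kids$sire] + y[kids$dam]) / 2
  slope <- coef(lm(y[kids$animal] ~ mid))[2]
  expect_lt(abs(slope - 0.36), 0.05)
})

test_that("expression atlas plants recoverable tissue-specific genes", {
  meta <- atlas_metadata_template(n_tissues = 13, samples_per_tissue = 6)
  expect_equal(length(unique(meta$organ_system)), 13L)
  atlas <- simulate_expression_atlas(1000, meta, spec_fraction = 0.1,
                                     fold_change = 8, seed = 3,
                                     spec_tissues = unique(meta$tissue)[1])
  expect_true(all(abs(colSums(atlas$tpm) - 1e6) < 1e6 * 0.001))
  expect_length(atlas$truth$planted[[meta$tissue[1]]], 100L)
  expect_error(
    simulate_expression_atlas(100, meta, spec_fraction = 0.6, seed = 1),
    class = "sswool_config_error")
  expect_error(
    simulate_expression_atlas(100, meta, fold_change = 1, seed = 1),
    class = "sswool_config_error")
  expect_error(
    simulate_expression_atlas(100, atlas_metadata_template(4, 1), seed = 1),
    class = "sswool_config_error")
})

test_that("fold change 1-equivalent (no planted tissues) gives null t-statistics", {
  meta <- atlas_metadata_template(n_tissues = 8, samples_per_tissue = 6)
  atlas <- simulate_expression_atlas(600, meta, spec_fraction = 0.1,
                                     fold_change = 8, seed = 4,
                                     spec_tissues = character(0))
  sc <- scale_expression(atlas$tpm)
  tt <- tissue_specificity(sc, meta, meta$tissue[1])
  # central t under the null: ~5% beyond the 2.5%/97.5% quantiles
  frac <- mean(abs(tt$t) > qt(0.975, df = ncol(sc) - 4))
  expect_lt(frac, 0.12)
})
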