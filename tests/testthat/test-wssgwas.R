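test_that("ssGBLUP with no genotyped animals equals dense pedigree BLUP", {
  pop <- quick_pop(n_founders = 30, n_generations = 2, seed = 31)
  A <- numerator_relationship(pop$ped)
  Ainv <- a_inverse(pop$ped, attr(A, "F"))
  sol <- solve_mme(pop$phen, "T1", Ainv, 0.3, 0.7)
  oracle <- dense_blup_oracle(pop$phen, "T1", pop$ped, A, 0.3, 0.7)
  expect_lt(max(abs(sol$a_hat - oracle$a_hat)), 1e-8)
  expect_lt(max(abs(sol$beta - oracle$beta)), 1e-8)
  expect_lt(sol$residual_norm, 1e-8)
})

test_that("shrinkage limit: huge variance ratio gives OLS fixed effects and zero GEBV", {
  pop <- quick_pop(n_founders = 30, seed = 32)
  Ainv <- a_inverse(pop$ped)
  sol <- solve_mme(pop$phen, "T1", Ainv, sigma2_a = 1e-8, sigma2_e = 1)
  expect_lt(max(abs(sol$a_hat)), 1e-4)
  ols <- coef(lm(T1 ~ flock + year + season, pop$phen))
  expect_equal(unname(sol$beta), unname(ols), tolerance = 1e-4)
})

test_that("duplicating the dataset leaves estimates unchanged", {
  pop <- quick_pop(n_founders = 30, seed = 33)
  Ainv <- a_inverse(pop$ped)
  sol1 <- solve_mme(pop$phen, "T1", Ainv, 0.3, 0.7)
  # doubled records double the data part of the normal equations; doubling
  # the variance ratio (sigma2_e doubled) scales the relationship penalty to
  # match, so the solution is unchanged
  dup <- rbind(pop$phen, pop$phen)
  sol2 <- solve_mme(dup, "T1", Ainv, 0.3, 0.7 * 2)
  expect_lt(max(abs(sol1$a_hat - sol2$a_hat)), 1e-8)
})

test_that("backsolved SNP effects reproduce GEBV on full-rank toys", {
  set.seed(34)
  for (rep in 1:3) {
    g <- matrix(rbinom(10 * 30, 2, 0.5), 10, 30,
                dimnames = list(paste0("i", 1:10), paste0("s", 1:30)))
    gr <- genomic_relationship(g, rep(0.5, 30))  # external p: full rank
    a_g <- rnorm(10)
    u <- backsolve_snp_effects(gr$Z, gr$weights, gr$lambda, gr$G, a_g)
    expect_lt(max(abs(gr$Z %*% u - a_g)), 1e-6)
    # variance of reconstructed genomic values equals var(a_g)
    expect_equal(var(drop(gr$Z %*% u)), var(a_g), tolerance = 1e-6)
    # linearity and the zero case
    expect_equal(backsolve_snp_effects(gr$Z, gr$weights, gr$lambda, gr$G,
                                       2 * a_g), 2 * u, tolerance = 1e-9)
    expect_equal(backsolve_snp_effects(gr$Z, gr$weights, gr$lambda, gr$G,
                                       rep(0, 10)), rep(0, 30),
                 ignore_attr = TRUE)
  }
})

test_that("weight update and normalisation follow the printed formulas", {
  expect_equal(update_weights(2, 0.5), 2)     # 4 * 2*0.25 = 2
  expect_equal(update_weights(0, 0.3), 0)
  expect_equal(update_weights(5, 0), 0)       # monomorphic
  expect_equal(normalize_weights(c(2, 2)), c(1, 1))
  expect_equal(normalize_weights(c(3, 1)), c(1.5, 0.5))
  set.seed(35)
  d <- runif(100)
  expect_equal(sum(normalize_weights(d)), 100, tolerance = 1e-10)
  expect_error(normalize_weights(c(0, 0)), class = "sswool_degenerate_error")
})

test_that("weight trace is conserved across reweighting iterations", {
  pop <- quick_pop(n_founders = 60, n_qtl = 4, qvf = 0.5, seed = 36,
                   gf = 0.6)
  gids <- pop$truth$genotyped_ids
  ws <- run_wssgwas(pop$phen, "T1", pop$ped, pop$geno[gids, ],
                    sigma2_a = 0.3, sigma2_e = 0.7, n_reweight = 3)
  m <- ncol(pop$geno)
  for (w in ws$weight_history) expect_equal(sum(w), m, tolerance = 1e-10)
  expect_length(ws$effect_history, 4L)
})

test_that("n_reweight = 0 reproduces unweighted ssGBLUP", {
  pop <- quick_pop(n_founders = 50, seed = 37, gf = 0.5)
  gids <- pop$truth$genotyped_ids
  w0 <- run_wssgwas(pop$phen, "T1", pop$ped, pop$geno[gids, ],
                    sigma2_a = 0.3, sigma2_e = 0.7, n_reweight = 0)
  w1 <- run_wssgwas(pop$phen, "T1", pop$ped, pop$geno[gids, ],
                    sigma2_a = 0.3, sigma2_e = 0.7, n_reweight = 1)
  expect_identical(w0$u, w1$effect_history[[1]])
  expect_true(all(w0$weights == 1))
})

test_that("window variances use the empirical variance and flag short chromosomes", {
  # single-SNP windows: var over equally frequent dosages 0/1/2 with effect u
  Zc <- matrix(c(0, 1, 2) - 1, 3, 1)  # centred at 2p = 1
  mp <- data.frame(snp = "s1", chrom = "1", pos = 100L)
  u <- 0.7
  wv <- window_variances(u, Zc, mp, sigma2_a = 0.5, window_size = 1L)
  expect_equal(wv$pct_variance, var(c(0, 1, 2) * u) / 0.5 * 100)
  # u = 0 everywhere -> all pct zero
  pop <- quick_pop(n_founders = 30, seed = 38)
  Z0 <- scale(pop$geno, scale = FALSE)
  wv0 <- window_variances(rep(0, ncol(Z0)), Z0, pop$map, 1)
  expect_true(all(wv0$pct_variance == 0))
  # chromosome shorter than the window is truncated and excluded from ranks
  expect_true(all(window_variances(rep(0.1, ncol(Z0)), Z0, pop$map, 1,
                                   window_size = 100L)$truncated))
})

test_that("window percentages are invariant to SNP relabeling and chromosome order", {
  pop <- quick_pop(n_founders = 40, n_chrom = 2, m_per_chrom = 30, seed = 39)
  u <- rnorm(60, 0, 0.05)
  Zc <- scale(pop$geno, scale = FALSE)
  wv1 <- window_variances(u, Zc, pop$map, 0.3)
  map2 <- pop$map
  map2$snp <- paste0("renamed_", map2$snp)
  wv2 <- window_variances(u, Zc, map2, 0.3)
  expect_equal(wv1$pct_variance, wv2$pct_variance)
  # reversed chromosome block order
  ord <- c(which(pop$map$chrom == "2"), which(pop$map$chrom == "1"))
  wv3 <- window_variances(u[ord], Zc[, ord], pop$map[ord, ], 0.3)
  key <- function(d) d[order(d$chrom, d$start_bp), "pct_variance"]
  expect_equal(key(wv1), key(wv3))
})

test_that("top regions merge overlapping windows and honour k", {
  wt <- data.frame(chrom = c("1", "1", "1", "2"),
                   first_snp = paste0("s", 1:4), last_snp = paste0("e", 1:4),
                   start_bp = c(100L, 150L, 5000L, 100L),
                   end_bp = c(200L, 260L, 5100L, 220L),
                   pct_variance = c(5, 4, 3, 2), truncated = FALSE)
  wt$rank <- rank(-wt$pct_variance)
  t1 <- top_windows(wt, k = 1L)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$start_bp, 100L)
  expect_equal(t1$end_bp, 260L)   # rank-2 window overlaps and extends
  expect_equal(t1$n_windows, 2L)
  t3 <- suppressWarnings(top_windows(wt, k = 5L))
  expect_equal(nrow(t3), 3L)
  expect_equal(t3$sum_pct_variance, c(9, 3, 2))
})

test_that("top-percent windows map to overlapping genes with a ceiling", {
  wt <- data.frame(chrom = rep("1", 100),
                   first_snp = paste0("s", 1:100),
                   last_snp = paste0("e", 1:100),
                   start_bp = seq(1L, by = 1000L, length.out = 100),
                   end_bp = seq(900L, by = 1000L, length.out = 100),
                   pct_variance = seq(100, 1), truncated = FALSE)
  wt$rank <- seq_len(100)
  ann <- data.frame(gene_id = c("inWin", "spansWin", "far"),
                    chrom = "1", start = c(200L, 1L, 50000L),
                    end = c(800L, 2000L, 60000L), strand = "+")
  got <- top_percent_snps(wt, ann, fraction = 0.01)  # ceiling -> 1 window
  expect_setequal(got, c("inWin", "spansWin"))
  expect_warning(out <- top_percent_snps(wt, ann[0, ], 0.01))
  expect_length(out, 0L)
})
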