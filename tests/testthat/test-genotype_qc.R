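test_that("allele frequencies ignore missing calls and flag empty markers", {
  g <- rbind(c(0, 2, 0, NA), c(1, 2, 0, NA), c(2, NA, 0, NA))
  p <- allele_frequencies(g)
  expect_equal(unname(p[1]), 0.5)
  expect_equal(unname(p[2]), 1.0)
  expect_equal(unname(p[3]), 0)
  expect_true(is.na(p[4]))
  expect_equal(unname(attr(p, "all_missing")), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("HWE exact test matches the enumeration oracle on all totals <= 50", {
  worst <- 0
  for (n in 1:50) {
    for (nAA in 0:n) {
      for (nAa in 0:(n - nAA)) {
        naa <- n - nAA - nAa
        worst <- max(worst, abs(hwe_exact_test(nAA, nAa, naa) -
                                  hwe_enumeration_oracle(nAA, nAa, naa)))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("HWE boundary cases behave as declared", {
  expect_equal(hwe_exact_test(7, 0, 0), 1)     # monomorphic
  expect_lt(hwe_exact_test(0, 100, 0), 1e-6)   # all-heterozygote excess
  expect_equal(hwe_exact_test(5, 0, 5), hwe_enumeration_oracle(5, 0, 5))
})

test_that("qc_filter removes by the declared reasons and is idempotent", {
  set.seed(13)
  n <- 40
  g <- matrix(rbinom(n * 6, 2, 0.4), n, 6,
              dimnames = list(sprintf("i%02d", 1:n), sprintf("s%d", 1:6)))
  g[1:8, 2] <- NA                      # call rate 0.8 < 0.9
  g[, 3] <- rbinom(n, 2, 0.003)        # MAF below 1%
  g[, 4] <- 1L                         # all heterozygous: HWE failure
  map <- data.frame(snp = colnames(g),
                    chrom = c("1", "1", "1", "1", "X", "0"),
                    pos = c(100L, 200L, 300L, 400L, 500L, 600L))
  # ind_call_min relaxed so the planted marker missingness does not trip the
  # individual filter (6 markers: one missing call = 0.83 individual rate)
  res <- qc_filter(g, map, ind_call_min = 0.7)
  expect_equal(res$report$removed_markers$unmapped, 1L)
  expect_equal(res$report$removed_markers$sex_chromosome, 1L)
  expect_equal(res$report$removed_markers$low_call_rate, 1L)
  expect_equal(res$report$removed_markers$low_maf, 1L)
  expect_equal(res$report$removed_markers$hwe_fail, 1L)
  expect_equal(ncol(res$genotypes), 1L)
  expect_equal(res$map$snp, "s1")
  # counts reconcile with input minus output
  expect_equal(sum(unlist(res$report$removed_markers)),
               res$report$n_markers_in - res$report$n_markers_out)
  # idempotence
  res2 <- qc_filter(res$genotypes, res$map, ind_call_min = 0.7)
  expect_identical(res2$genotypes, res$genotypes)
  expect_identical(res2$map, res$map)
})

test_that("individuals below the call-rate threshold are removed first", {
  set.seed(14)
  g <- matrix(rbinom(200, 2, 0.5), 20, 10)
  dimnames(g) <- list(sprintf("i%02d", 1:20), sprintf("s%d", 1:10))
  g[1, 1:9] <- NA  # individual call rate 0.1
  map <- data.frame(snp = colnames(g), chrom = "1", pos = 1:10 * 100L)
  res <- qc_filter(g, map)
  expect_equal(res$report$removed_individuals, 1L)
  expect_false("i01" %in% rownames(res$genotypes))
})

test_that("phenotype outlier filter applies the 3-SD rule single-pass", {
  # (0,0,0,0,100): SD = 44.7, |100-20| = 80 < 3 SD, so retained
  ph <- data.frame(animal = letters[1:5], T1 = c(0, 0, 0, 0, 100),
                   T2 = c(rep(0, 4), 1), T3 = rep(7, 5))
  out <- phenotype_outlier_filter(ph, traits = c("T1", "T2", "T3"))
  expect_false(anyNA(out$T1))
  expect_identical(out$T3, ph$T3)  # zero SD: untouched
  # a genuine outlier is removed; value exactly at 3 SD is retained
  x <- c(rep(0, 30), 9)
  s <- sd(x); m <- mean(x)
  stopifnot(abs(9 - m) > 3 * s)
  ph2 <- data.frame(animal = seq_along(x), T1 = x)
  expect_true(is.na(phenotype_outlier_filter(ph2, "T1")$T1[31]))
  # strict inequality: a value exactly at k_sd SDs is retained
  z <- c(-1, 0, 1)  # SD = 1; with k_sd = 1 the extremes sit exactly at 1 SD
  expect_false(anyNA(phenotype_outlier_filter(
    data.frame(animal = 1:3, T1 = z), "T1", k_sd = 1)$T1))
})

test_that("composite LD r2 is symmetric, sign-invariant and null-calibrated", {
  set.seed(15)
  g <- cbind(a = rep(0:2, 4), b = rev(rep(0:2, 4)),
             c = rbinom(12, 2, 0.5))
  expect_equal(ld_r2(g, "a", "a"), 1)
  expect_equal(ld_r2(g, "a", "b"), 1)  # reverse pattern, sign-invariant
  expect_equal(ld_r2(g, "a", "c"), ld_r2(g, "c", "a"))
  # allele-label flip leaves r2 unchanged
  g2 <- g; g2[, "c"] <- 2 - g2[, "c"]
  expect_equal(ld_r2(g, "a", "c"), ld_r2(g2, "a", "c"))
  # monomorphic marker flagged
  g3 <- cbind(g, d = rep(1L, 12))
  expect_warning(r <- ld_r2(g3, "a", "d"))
  expect_true(is.na(r))
  # independent markers: mean r2 of order 1/n
  n <- 5000
  gi <- cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.5))
  expect_lt(ld_r2(gi, 1, 2), 0.01)
})

test_that("LD decays with distance on a recombining chromosome", {
  # small founder pool + several generations: drift builds LD that
  # recombination erodes with distance
  pop <- quick_pop(n_founders = 20, n_generations = 4, offspring = 3,
                   n_chrom = 1, m_per_chrom = 60, chrom_len = 2e8,
                   n_qtl = 2, seed = 16)
  dec <- ld_decay(pop$geno, pop$map, bin_width_bp = 4e7, max_dist_bp = 2e8)
  expect_true(all(dec$n_pairs[1:4] > 0))
  filled <- dec[dec$n_pairs > 0, ]
  # rank test: near bins show more LD than far bins
  expect_gt(filled$mean_r2[1], filled$mean_r2[nrow(filled)])
  # binning: a single pair lands in the right bin
  g2 <- pop$geno[, 1:2]
  map2 <- data.frame(snp = colnames(g2), chrom = "1", pos = c(1e6, 5.1e7))
  d2 <- ld_decay(g2, map2, bin_width_bp = 1e7, max_dist_bp = 1e8)
  expect_equal(which(d2$n_pairs == 1L), 6L)  # 50 Mb into bin (50,60] Mb
})
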