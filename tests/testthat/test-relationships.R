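test_that("numerator relationship matrix reproduces textbook cases", {
  # unrelated founders
  f <- data.frame(animal = c("a", "b"), sire = NA_character_,
                  dam = NA_character_)
  expect_equal(unname(numerator_relationship(f)), diag(2),
               ignore_attr = TRUE)
  # sire-dam-offspring trio
  trio <- data.frame(animal = c("s", "d", "o"), sire = c(NA, NA, "s"),
                     dam = c(NA, NA, "d"))
  A <- numerator_relationship(trio)
  expect_equal(A["s", "o"], 0.5)
  expect_equal(A["o", "o"], 1)
  # offspring of paternal half sibs: F = 0.125
  ped <- data.frame(animal = c("f", "m1", "m2", "h1", "h2", "x"),
                    sire = c(NA, NA, NA, "f", "f", "h1"),
                    dam = c(NA, NA, NA, "m1", "m2", "h2"))
  Ax <- numerator_relationship(ped)
  expect_equal(Ax["x", "x"], 1.125)
  expect_equal(unname(attr(Ax, "F")["x"]), 0.125)
})

test_that("A is PSD and A^-1 inverts A on random pedigrees", {
  for (seed in 1:4) {
    ped <- sort_pedigree(random_pedigree(150, seed = seed))
    A <- numerator_relationship(ped)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
    Ainv <- as.matrix(a_inverse(ped, attr(A, "F")))
    expect_lt(max(abs(A %*% Ainv - diag(nrow(A)))), 1e-8)
  }
  # founders only -> identity; non-inbred trio has the known closed form
  f <- data.frame(animal = c("a", "b"), sire = NA_character_,
                  dam = NA_character_)
  expect_equal(as.matrix(a_inverse(f)), diag(2), ignore_attr = TRUE)
  trio <- data.frame(animal = c("s", "d", "o"), sire = c(NA, NA, "s"),
                     dam = c(NA, NA, "d"))
  expect_equal(as.matrix(a_inverse(trio)),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3),
               ignore_attr = TRUE)
})

test_that("A22 subsetting honours order and validates ids", {
  ped <- sort_pedigree(random_pedigree(30, seed = 5))
  A <- numerator_relationship(ped)
  ids <- sample(ped$animal, 10)
  expect_identical(subset_a22(A, ids), A[ids, ids])
  expect_equal(subset_a22(A, ped$animal), A, ignore_attr = TRUE)
  expect_error(subset_a22(A, "nope"), class = "sswool_lookup_error")
  # trio with only offspring genotyped
  trio <- data.frame(animal = c("s", "d", "o"), sire = c(NA, NA, "s"),
                     dam = c(NA, NA, "d"))
  expect_equal(unname(subset_a22(numerator_relationship(trio), "o")),
               matrix(1), ignore_attr = TRUE)
})

test_that("genomic relationship matches the naive double-loop oracle", {
  set.seed(6)
  g <- matrix(rbinom(20 * 50, 2, runif(50, 0.1, 0.9)), 20, 50, byrow = TRUE,
              dimnames = list(paste0("i", 1:20), paste0("s", 1:50)))
  g[3, 7] <- NA
  p <- allele_frequencies(g)
  w <- runif(50, 0.5, 2)
  gr <- genomic_relationship(g, p, w)
  # naive oracle: explicit loops over pairs and markers
  used <- which(!is.na(p) & p > 0 & p < 1)
  lam <- 1 / sum(2 * p[used] * (1 - p[used]))
  G0 <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    s <- 0
    for (k in used) {
      zi <- ifelse(is.na(g[i, k]), 0, g[i, k] - 2 * p[k])
      zj <- ifelse(is.na(g[j, k]), 0, g[j, k] - 2 * p[k])
      s <- s + w[k] * zi * zj
    }
    G0[i, j] <- s * lam
  }
  expect_lt(max(abs(gr$G - G0)), 1e-10)
})

test_that("genomic relationship has VanRaden scale and handles degeneracy", {
  set.seed(7)
  p_true <- runif(400, 0.2, 0.8)
  g <- sapply(p_true, function(p) rbinom(300, 2, p))
  rownames(g) <- paste0("i", 1:300)
  gr <- genomic_relationship(g, allele_frequencies(g))
  expect_lt(abs(mean(diag(gr$G)) - 1), 0.02)
  # identical genotypes: off-diagonal equals the diagonals
  g2 <- rbind(a = c(0L, 1L, 2L, 1L), b = c(0L, 1L, 2L, 1L))
  gr2 <- genomic_relationship(g2, rep(0.5, 4))
  expect_equal(gr2$G[1, 2], gr2$G[1, 1])
  # hom-ref individual at m SNPs with p = 0.5: self-relationship = 2
  g3 <- rbind(a = rep(0L, 6), b = rep(1L, 6))
  expect_equal(genomic_relationship(g3, rep(0.5, 6))$G[1, 1], 2)
  # all markers fixed -> degenerate error
  g4 <- rbind(a = rep(2L, 3), b = rep(2L, 3))
  expect_error(genomic_relationship(g4, allele_frequencies(g4)),
               class = "sswool_degenerate_error")
})

test_that("tuning matches moments of A22 and blending keeps G invertible", {
  pop <- quick_pop(n_founders = 60, seed = 8)
  gids <- pop$truth$genotyped_ids
  A22 <- subset_a22(numerator_relationship(pop$ped), gids)
  geno <- pop$geno[gids, ]
  gr <- genomic_relationship(geno, allele_frequencies(geno))
  tb <- tune_and_blend(gr$G, A22)
  off <- upper.tri(A22)
  tuned <- tb$alpha + tb$beta * gr$G
  expect_equal(mean(diag(tuned)), mean(diag(A22)), tolerance = 1e-10)
  expect_equal(mean(tuned[off]), mean(A22[off]), tolerance = 1e-10)
  # blended matrix deviates from A22 moments by at most (1-w)|delta|
  expect_lt(abs(mean(diag(tb$G_w)) - mean(diag(A22))),
            0.05 * abs(mean(diag(gr$G)) - mean(diag(A22))) + 1e-10)
  expect_no_error(chol(tb$G_w))
  # fixed point: G already matching A22 moments
  tb2 <- tune_and_blend(A22, A22)
  expect_equal(tb2$beta, 1, tolerance = 1e-10)
  expect_equal(tb2$alpha, 0, tolerance = 1e-10)
  expect_equal(tb2$G_w, A22, tolerance = 1e-10)
  # unblended singular G fails with an explicit error
  Gs <- tcrossprod(matrix(rnorm(nrow(A22) * 2), ncol = 2))  # rank 2
  expect_error(tune_and_blend(Gs, A22, blend_weight = 1),
               class = "sswool_linear_algebra_error")
})

test_that("H^-1 has the declared block structure", {
  pop <- quick_pop(n_founders = 80, n_generations = 2, seed = 9, gf = 0.35)
  ped <- pop$ped
  A <- numerator_relationship(ped)
  Ainv <- a_inverse(ped, attr(A, "F"))
  gids <- pop$truth$genotyped_ids
  A22 <- subset_a22(A, gids)
  geno <- pop$geno[gids, ]
  gr <- genomic_relationship(geno, allele_frequencies(geno))
  G_w <- tune_and_blend(gr$G, A22)$G_w
  H <- h_inverse(Ainv, A22, G_w, gids)
  # non-genotyped block equals A^-1 exactly
  ng <- setdiff(ped$animal, gids)
  expect_identical(as.matrix(H[ng, ng]), as.matrix(Ainv[ng, ng]))
  # dense oracle: invert H^-1 and check the genotyped block against
  # H = A + correction structure via the defining formula
  Hi <- as.matrix(H)
  expect_lt(max(abs(Hi - (as.matrix(Ainv) +
    {
      corr <- matrix(0, nrow(A), nrow(A), dimnames = dimnames(A))
      corr[gids, gids] <- solve(G_w) - solve(A22)
      corr
    }))), 1e-8)
  expect_lt(max(abs(Hi - t(Hi))), 1e-12)
  # no genotyped animals: H^-1 = A^-1
  expect_equal(as.matrix(h_inverse(Ainv, A22[0, 0], G_w[0, 0], character(0))),
               as.matrix(Ainv))
  # all animals genotyped: H^-1 = G_w^-1
  A22f <- A
  grf <- genomic_relationship(pop$geno, allele_frequencies(pop$geno))
  G_wf <- tune_and_blend(grf$G, A22f)$G_w
  Hf <- h_inverse(Ainv, A22f, G_wf, ped$animal)
  expect_lt(max(abs(as.matrix(Hf) - solve(G_wf))), 1e-6)
})
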