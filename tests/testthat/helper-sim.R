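# Shared fixtures, built in code at test time.

# Small population: pedigree, genome, genotypes, phenotypes, truth.
quick_pop <- function(n_founders = 60, n_generations = 2, offspring = 2,
                      n_chrom = 2, m_per_chrom = 40, chrom_len = 5e7,
                      n_qtl = 4, qvf = 0.4, h2 = c(T1 = 0.3),
                      rg = NULL, gf = 0.5, seed = 1, maf = c(0.05, 0.5)) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                    offspring_per_mating = offspring, n_chromosomes = n_chrom,
                    markers_per_chromosome = m_per_chrom,
                    chromosome_length_bp = chrom_len,
                    founder_maf_range = maf,
                    n_qtl = n_qtl, qtl_variance_fraction = qvf,
                    target_h2 = h2, genetic_correlation_targets = rg,
                    fixed_effect_levels = c(6, 3, 2),
                    genotyped_fraction = gf, phenotype_sex = "both",
                    seed = seed)
  ped <- simulate_pedigree(cfg)
  map <- simulate_marker_map(cfg)
  geno <- simulate_genotypes(ped, map, cfg)
  ph <- simulate_phenotypes(ped, geno, map, cfg)
  list(cfg = cfg, ped = ped, map = map, geno = geno,
       phen = ph$phenotypes, truth = ph$truth)
}

# Random non-generational pedigree: each animal may draw parents among
# earlier animals. Exercises inbreeding and single-known-parent cases.
random_pedigree <- function(n, seed = 1) {
  set.seed(seed)
  animal <- sprintf("a%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    if (runif(1) < 0.8) sire[i] <- animal[sample.int(i - 1L, 1)]
    if (runif(1) < 0.8) {
      repeat {
        d <- animal[sample.int(i - 1L, 1)]
        if (is.na(sire[i]) || d != sire[i]) break
      }
      dam[i] <- d
    }
  }
  data.frame(animal = animal, sire = sire, dam = dam,
             stringsAsFactors = FALSE)
}

# Exact-probability enumeration oracle for the HWE conditional test:
# absolute probabilities from factorials (totals <= 50 keep factorial(2n)
# within double range).
hwe_enumeration_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    factorial(n) / (factorial(hr) * factorial(h) * factorial(hc)) *
      2^h * factorial(nA) * factorial(na) / factorial(2 * n)
  }, numeric(1))
  p_obs <- prob[hets == n_Aa]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# Dense generalized-least-squares oracle for pedigree BLUP: solves the
# mixed-model equations with a dense inverse of A, independently of the
# package's sparse path.
dense_blup_oracle <- function(phen, trait, ped, A, sigma2_a, sigma2_e,
                              fixed = c("flock", "year", "season")) {
  dat <- phen[!is.na(phen[[trait]]), , drop = FALSE]
  for (f in fixed) dat[[f]] <- droplevels(as.factor(dat[[f]]))
  X <- stats::model.matrix(stats::reformulate(fixed), dat)
  W <- matrix(0, nrow(dat), nrow(ped))
  W[cbind(seq_len(nrow(dat)), match(dat$animal, ped$animal))] <- 1
  k <- sigma2_e / sigma2_a
  C <- rbind(cbind(crossprod(X), crossprod(X, W)),
             cbind(crossprod(W, X), crossprod(W) + k * solve(A)))
  rhs <- c(crossprod(X, dat[[trait]]), crossprod(W, dat[[trait]]))
  sol <- solve(C, rhs)
  list(beta = sol[seq_len(ncol(X))],
       a_hat = setNames(sol[-seq_len(ncol(X))], ped$animal))
}
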