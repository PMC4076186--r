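test_that("theta hits the boundary cases and the ratio-of-sums identity", {
  ## complete differentiation: two fixed populations
  ds <- genotype_dataset(paste0("i", 1:20), rep(c("A", "B"), each = 10),
                         "L1", matrix(rep(c(1L, 2L), each = 10)),
                         matrix(rep(c(1L, 2L), each = 10)))
  expect_equal(wc_theta(ds)$theta, 1)
  expect_error(wc_theta(subset_genotypes(ds, populations = "A")), ">= 2")

  ## identical populations: theta near zero
  set.seed(9)
  g1 <- sample(1:5, 100, replace = TRUE); g2 <- sample(1:5, 100, replace = TRUE)
  ds2 <- genotype_dataset(paste0("i", 1:200), rep(c("A", "B"), each = 100),
                          "L1", matrix(c(g1, g1)), matrix(c(g2, g2)))
  expect_lt(abs(wc_theta(ds2)$theta), 0.02)

  ## multilocus theta is a ratio of sums, not a mean of per-locus values
  cfg <- sim_config(n_pops = 2, pop_sizes = 25, n_loci = 2,
                    alleles_per_locus = c(2L, 12L), fst_target = 0.15,
                    seed = 5)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 2, 0.15, 5)
  ds3 <- simulate_pedigree_sample(fr, cfg)$dataset
  res <- wc_theta(ds3)
  expect_false(isTRUE(all.equal(res$theta, mean(res$per_locus$theta))))
  expect_equal(res$theta, res$a / (res$a + res$b + res$c))
})

test_that("theta is invariant to allele relabelling and locus order", {
  cfg <- sim_config(n_pops = 3, pop_sizes = 20, n_loci = 4,
                    alleles_per_locus = 5, fst_target = 0.08, seed = 19)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 3, 0.08, 19)
  ds <- simulate_pedigree_sample(fr, cfg)$dataset
  base <- wc_theta(ds)$theta
  relab <- genotype_dataset(ds$individuals, ds$populations, ds$loci,
                            ds$allele1 * 7L + 3L, ds$allele2 * 7L + 3L)
  expect_equal(wc_theta(relab)$theta, base, tolerance = 1e-12)
  perm <- subset_genotypes(ds, loci = rev(ds$loci))
  expect_equal(wc_theta(perm)$theta, base, tolerance = 1e-12)
})

test_that("theta recovers the Balding-Nichols target", {
  cfg <- sim_config(n_pops = 20, pop_sizes = 30, n_loci = 50,
                    alleles_per_locus = 8, fst_target = 0.05, seed = 7)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 20, 0.05, 7)
  ds <- simulate_pedigree_sample(fr, cfg)$dataset
  expect_lt(abs(wc_theta(ds)$theta - 0.05), 0.01)
})

test_that("permutation p-values are seeded and powered", {
  cfg <- sim_config(n_pops = 2, pop_sizes = 30, n_loci = 9,
                    alleles_per_locus = 8, fst_target = 0.2, seed = 3)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 2, 0.2, 3)
  ds <- simulate_pedigree_sample(fr, cfg)$dataset
  res <- fst_permutation_p(ds, "pop1", "pop2", iterations = 999, seed = 8)
  expect_lte(res$p, 0.001)
  expect_identical(res$p,
                   fst_permutation_p(ds, "pop1", "pop2", iterations = 999,
                                     seed = 8)$p)
})

test_that("locus bootstrap collapses on identical loci and covers the
           estimate", {
  ## all loci identical copies -> zero-width interval at the point estimate
  set.seed(4)
  g1 <- sample(1:4, 60, replace = TRUE); g2 <- sample(1:4, 60, replace = TRUE)
  a1 <- matrix(g1, 60, 5); a2 <- matrix(g2, 60, 5)
  ds <- genotype_dataset(paste0("i", 1:60), rep(c("A", "B"), each = 30),
                         paste0("L", 1:5), a1, a2)
  ci <- fst_bootstrap_ci(ds, iterations = 500, seed = 2)
  expect_equal(ci$lower, ci$theta, tolerance = 1e-12)
  expect_equal(ci$upper, ci$theta, tolerance = 1e-12)
  ## single locus: undefined interval
  ci1 <- fst_bootstrap_ci(subset_genotypes(ds, loci = "L1"),
                          iterations = 10, seed = 2)
  expect_true(is.na(ci1$lower))
})

test_that("bootstrap intervals achieve near-nominal coverage", {
  ## oracle: the large-n limit of the estimator for known population
  ## frequencies is sum(s2) / sum(s2 / r + pbar (1 - pbar))
  realized_theta <- function(fr) {
    num <- den <- 0
    pops <- names(fr); r <- length(pops)
    for (lc in names(fr[[1]])) {
      alleles <- sort(unique(unlist(lapply(pops, function(pp)
        names(fr[[pp]][[lc]]$p)))))
      P <- vapply(pops, function(pp) {
        p <- fr[[pp]][[lc]]$p
        setNames(ifelse(alleles %in% names(p), p[alleles], 0), alleles)
      }, numeric(length(alleles)))
      pbar <- rowMeans(P)
      s2 <- apply(P, 1, function(x) sum((x - mean(x))^2) / (r - 1))
      num <- num + sum(s2)
      den <- den + sum(s2 / r + pbar * (1 - pbar))
    }
    num / den
  }
  hits <- vapply(1:60, function(s) {
    cfg <- sim_config(n_pops = 4, pop_sizes = 30, n_loci = 9,
                      alleles_per_locus = 6, fst_target = 0.08, seed = s)
    fr <- derive_population_frequencies(sample_base_frequencies(cfg), 4,
                                        0.08, s)
    ds <- simulate_pedigree_sample(fr, cfg)$dataset
    ci <- fst_bootstrap_ci(ds, iterations = 300, seed = s)
    target <- realized_theta(fr)
    ci$lower <= target && target <= ci$upper
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("pairwise matrix is symmetric with an empty diagonal and a
           Bonferroni flag", {
  sim <- generate_study_like_dataset(seed = 2)
  ds <- subset_genotypes(sim$dataset,
                         populations = c("pop1", "pop4", "pop7"))
  m <- pairwise_fst(ds, iterations = 99, seed = 1)
  expect_true(isSymmetric(m$theta))
  expect_true(all(is.na(diag(m$theta))))
  expect_equal(m$bonferroni_alpha, 0.05 / 3)
  expect_true(all(m$p > 0 & m$p <= 1, na.rm = TRUE))
})

test_that("the ENA-corrected theta reduces to the plain estimator without
           nulls and stays near the truth with them", {
  cfg <- sim_config(n_pops = 2, pop_sizes = 60, n_loci = 8,
                    alleles_per_locus = 6, fst_target = 0.05, seed = 33)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 2, 0.05, 33)
  ds <- simulate_pedigree_sample(fr, cfg)$dataset
  est <- estimate_null_all(ds, steps = 300, dememorization = 300, seed = 1)
  est$flagged <- FALSE; est$r_em <- 0
  res <- ena_corrected_theta(ds, est)
  expect_equal(res$theta, res$raw_theta, tolerance = 1e-12)

  ## planted nulls: corrected estimate stays within noise of the target
  ths <- vapply(1:10, function(s) {
    cfg <- sim_config(n_pops = 2, pop_sizes = 100, n_loci = 12,
                      alleles_per_locus = 8, fst_target = 0.05,
                      null_freqs = rep(c(0.2, 0), each = 6), seed = s)
    fr <- derive_population_frequencies(sample_base_frequencies(cfg), 2,
                                        0.05, s)
    sim <- simulate_pedigree_sample(fr, cfg)
    obs <- apply_null_alleles(sim$dataset, cfg$null_freqs, s)
    est <- estimate_null_all(obs, steps = 400, dememorization = 400, seed = s)
    ena_corrected_theta(obs, est)$theta
  }, numeric(1))
  expect_lt(abs(mean(ths) - 0.05), 0.015)
})
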