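test_that("moment estimators match their closed forms", {
  expect_equal(estimate_null_moment(0.4, 0.8, "brookfield1"), 2 / 9)
  expect_equal(estimate_null_moment(0.4, 0.8, "chakraborty"), 1 / 3)
  expect_equal(estimate_null_moment(0.6, 0.6, "chakraborty"), 0)
  expect_equal(estimate_null_moment(0.7, 0.6, "brookfield1"), 0)  # clamped
  expect_equal(estimate_null_moment(0, 0, "chakraborty"), 0)      # monomorphic
})

test_that("EM null estimation finds no signal in Hardy-Weinberg data and
           saturates on blanks", {
  ## exact HW counts at p = q = 0.5, no blanks
  tab <- matrix(0L, 2, 2); tab[1, 1] <- 25L; tab[2, 2] <- 25L; tab[1, 2] <- 50L
  em <- estimate_null_em(list(counts = tab, n_blank = 0L), max_iter = 5000)
  expect_lt(em$null_freq, 1e-6)
  ## log-likelihood never decreases
  expect_true(all(diff(em$loglik_trace) > -1e-9))
  ## all genotypes blank -> null frequency 1
  em2 <- estimate_null_em(list(counts = matrix(0L, 0, 0), n_blank = 10L))
  expect_equal(em2$null_freq, 1)
})

test_that("EM recovers a planted null frequency and shrinks its bias with n", {
  est_at <- function(n, seed) {
    cfg <- sim_config(n_pops = 1, pop_sizes = n, n_loci = 1,
                      alleles_per_locus = 8, seed = seed)
    fr <- derive_population_frequencies(sample_base_frequencies(cfg), 1, 0,
                                        seed)
    ds <- simulate_pedigree_sample(fr, cfg)$dataset
    obs <- apply_null_alleles(ds, 0.2, seed = seed)
    gc <- patchkin:::genotype_counts(obs, "pop1", "L1")
    estimate_null_em(gc)$null_freq
  }
  expect_equal(est_at(500, 9), 0.2, tolerance = 0.25)   # +-0.05
  ## consistency: average error decreases from n = 50 to n = 800
  err <- function(n) mean(abs(vapply(1:6, function(s) est_at(n, s),
                                     numeric(1)) - 0.2))
  expect_lt(err(800), err(50) + 0.01)
})

test_that("expected blank count is n r^2", {
  expect_equal(expected_blank_count(0.139, 259), 259 * 0.139^2)
  expect_gt(expected_blank_count(0.139, 259), 4.9)  # ~5 blanks expected
  expect_equal(expected_blank_count(0, 100), 0)
  expect_equal(expected_blank_count(1, 100), 100)
})

test_that("genotype adjustment is the identity without estimates and only
           re-labels homozygotes otherwise", {
  sim <- generate_study_like_dataset(seed = 6)
  ds <- sim$dataset
  est <- estimate_null_all(ds, steps = 300, dememorization = 300, seed = 1)
  ## identity when nothing is flagged
  est0 <- est; est0$flagged <- FALSE
  ds0 <- adjust_genotypes(ds, est0)
  expect_identical(ds0$allele1, ds$allele1)
  expect_identical(ds0$allele2, ds$allele2)
  ## real adjustment: count conserved, only hom -> (i, sentinel) re-labels
  adj <- adjust_genotypes(ds, est)
  expect_equal(dim(adj$allele1), dim(ds$allele1))
  changed <- which(adj$allele2 != ds$allele2 |
                     is.na(adj$allele2) != is.na(ds$allele2))
  expect_true(length(changed) > 0)
  expect_true(all(adj$allele2[changed] == null_sentinel()))
  expect_true(all(ds$allele1[changed] == ds$allele2[changed]))    # were homs
  expect_identical(adj$allele1[changed], ds$allele1[changed])
  ## allele sets unchanged apart from the sentinel
  vis <- function(m) sort(unique(m[!is.na(m) & m != null_sentinel()]))
  expect_identical(vis(cbind(adj$allele1, adj$allele2)),
                   vis(cbind(ds$allele1, ds$allele2)))
})

test_that("re-label counts follow the EM expectation on simulated data", {
  cfg <- sim_config(n_pops = 1, pop_sizes = 800, n_loci = 1,
                    alleles_per_locus = 6, seed = 12)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 1, 0, 12)
  ds <- simulate_pedigree_sample(fr, cfg)$dataset
  obs <- apply_null_alleles(ds, 0.25, seed = 12)
  est <- estimate_null_all(obs, steps = 500, dememorization = 500, seed = 1)
  expect_true(est$flagged[1])
  adj <- adjust_genotypes(obs, est)
  n_relab <- sum(adj$allele2 == null_sentinel(), na.rm = TRUE)
  ## expected total: sum over classes of n_hom_i * 2r / (p_i + 2r)
  gc <- patchkin:::genotype_counts(obs, "pop1", "L1")
  em <- estimate_null_em(gc)
  r <- em$null_freq; p <- em$p_visible
  hom <- diag(gc$counts)
  expected <- sum(hom * 2 * r / (p + 2 * r))
  expect_equal(n_relab, expected, tolerance = 0.1)
})

test_that("null correction relieves Hardy-Weinberg disequilibrium", {
  relieved <- vapply(1:30, function(s) {
    cfg <- sim_config(n_pops = 1, pop_sizes = 150, n_loci = 1,
                      alleles_per_locus = 6, seed = s)
    fr <- derive_population_frequencies(sample_base_frequencies(cfg), 1, 0, s)
    ds <- simulate_pedigree_sample(fr, cfg)$dataset
    obs <- apply_null_alleles(ds, 0.25, seed = s)
    est <- estimate_null_all(obs, steps = 2000, dememorization = 1000,
                             seed = s)
    if (!est$flagged[1]) return(NA)          # no detected excess, no claim
    adj <- adjust_genotypes(obs, est)
    gc_b <- patchkin:::genotype_counts(obs, "pop1", "L1")
    gc_a <- patchkin:::genotype_counts(adj, "pop1", "L1")
    ## sentinel hets enter as a distinct allele class, which is the point:
    ## the visible/null heterozygotes restore genotypic equilibrium
    hwe_exact_mc(gc_a$counts, steps = 2000, dememorization = 1000, seed = s) >
      hwe_exact_mc(gc_b$counts, steps = 2000, dememorization = 1000, seed = s)
  }, logical(1))
  expect_gte(mean(relieved, na.rm = TRUE), 0.9)
})
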