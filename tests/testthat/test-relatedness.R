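test_that("k-vector helpers respect the canonical relationship points", {
  expect_equal(relatedness_r(canonical_k("UR")), 0)
  expect_equal(relatedness_r(canonical_k("HS")), 0.25)
  expect_equal(relatedness_r(canonical_k("FS")), 0.5)
  expect_equal(relatedness_r(canonical_k("PO")), 0.5)
  expect_error(relatedness_r(c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(canonical_k("XX"), "unknown")
})

test_that("single-locus dyad likelihood matches the hand-derived biallelic
           case and reduces correctly", {
  p <- c("1" = 0.5, "2" = 0.5)
  g <- c(1L, 1L)
  expect_equal(dyad_locus_likelihood(g, g, p, 0, canonical_k("UR")), 0.0625)
  expect_equal(dyad_locus_likelihood(g, g, p, 0, canonical_k("HS")), 0.09375)
  expect_equal(dyad_locus_likelihood(g, g, p, 0, canonical_k("FS")), 0.140625)
  ## k = UR is the product of unconditional genotype probabilities
  q <- c("1" = 0.2, "2" = 0.3, "3" = 0.5)
  expect_equal(dyad_locus_likelihood(c(1L, 2L), c(3L, 3L), q, 0,
                                     canonical_k("UR")),
               (2 * 0.2 * 0.3) * (0.5 * 0.5))
  ## a vanishing null frequency reduces to the no-null computation
  for (cat in c("UR", "HS", "FS", "PO")) {
    k <- canonical_k(cat)
    qn <- q * (1 - 1e-12)
    expect_equal(dyad_locus_likelihood(c(2L, 2L), c(2L, 3L), qn, 1e-12, k),
                 dyad_locus_likelihood(c(2L, 2L), c(2L, 3L), q, 0, k),
                 tolerance = 1e-9)
  }
  expect_error(dyad_locus_likelihood(g, g, p, 0, c(0.5, 0.6, 0.1)), "sum")
  expect_error(dyad_locus_likelihood(c(9L, 9L), c(1L, 1L), p, 0,
                                     canonical_k("UR")), "absent")
})

test_that("likelihoods agree exactly with pedigree enumeration for 2-3
           allele loci", {
  ## rational frequencies, exactly representable in binary
  freq_sets <- list(c("1" = 0.5, "2" = 0.5),
                    c("1" = 0.25, "2" = 0.75),
                    c("1" = 0.25, "2" = 0.25, "3" = 0.5))
  for (p in freq_sets) {
    alleles <- as.integer(names(p))
    genos <- list()
    for (a in alleles) for (b in alleles) if (a <= b)
      genos[[length(genos) + 1]] <- c(a, b)
    for (g1 in genos) for (g2 in genos) {
      for (cat in c("UR", "HS", "FS", "PO")) {
        expect_equal(
          dyad_locus_likelihood(g1, g2, p, 0, canonical_k(cat)),
          ped_enum_joint(g1, g2, p, cat),
          tolerance = 1e-12,
          label = sprintf("%s (%s)-(%s)", cat, paste(g1, collapse = "/"),
                          paste(g2, collapse = "/")))
      }
    }
  }
})

test_that("locus likelihoods are a probability distribution over ordered
           genotype pairs", {
  p <- c("1" = 0.2, "2" = 0.3, "3" = 0.5)
  alleles <- as.integer(names(p))
  genos <- list()
  for (a in alleles) for (b in alleles) if (a <= b)
    genos[[length(genos) + 1]] <- c(a, b)
  for (k in list(c(1, 0, 0), c(0.3, 0.5, 0.2), c(0, 0, 1))) {
    tot <- 0
    for (g1 in genos) for (g2 in genos)
      tot <- tot + dyad_locus_likelihood(g1, g2, p, 0, k)
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("classification uses the conservative tie rule and ignores
           uninformative loci", {
  ## monomorphic-only loci: all categories tie, UR wins
  ds <- genotype_dataset(c("x", "y"), c("p", "p"), c("L1", "L2"),
                         rbind(c(1L, 2L), c(1L, 2L)),
                         rbind(c(1L, 2L), c(1L, 2L)))
  d <- ml_relationship(ds, "x", "y", min_informative = 0L)
  expect_equal(d$category, "UR")
  ## adding a monomorphic locus never changes the ranking
  cfg <- sim_config(n_pops = 1, pop_sizes = 20, n_loci = 6,
                    alleles_per_locus = 5, seed = 44)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 1, 0, 44)
  sim <- simulate_pedigree_sample(fr, cfg)
  ds2 <- sim$dataset
  ds3 <- genotype_dataset(ds2$individuals, ds2$populations,
                          c(ds2$loci, "mono"),
                          cbind(ds2$allele1, 9L), cbind(ds2$allele2, 9L))
  d2 <- dyad_relationships(ds2, min_informative = 0L)
  d3 <- dyad_relationships(ds3, min_informative = 0L)
  expect_equal(d3$category, d2$category)
  expect_equal(d3$loglik_FS - d3$loglik_UR, d2$loglik_FS - d2$loglik_UR,
               tolerance = 1e-9)
})

test_that("simulated full-sib dyads are recovered and unrelated dyads stay
           near zero relatedness", {
  n_fam <- 100
  plan <- list(replicate(n_fam, list(category = "FS", size = 2L),
                         simplify = FALSE))
  cfg <- sim_config(n_pops = 1, pop_sizes = 2L * n_fam + 50L, n_loci = 20,
                    alleles_per_locus = 8, family_plan = plan, seed = 77)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 1, 0, 77)
  ds <- simulate_pedigree_sample(fr, cfg)$dataset
  af <- allele_frequencies(ds)
  fs <- do.call(rbind, lapply(seq_len(n_fam), function(k)
    ml_relationship(ds, ds$individuals[2 * k - 1], ds$individuals[2 * k],
                    freqs = af)))
  expect_gte(mean(fs$category == "FS"), 0.7)
  expect_lt(abs(mean(fs$r) - 0.5), 0.05)
  ur <- do.call(rbind, lapply(seq_len(40), function(k)
    ml_relationship(ds, ds$individuals[2 * n_fam + k],
                    ds$individuals[2 * k], freqs = af)))
  expect_lte(mean(ur$r), 0.05)
})

test_that("dyad frequency tables count classifications over n(n-1)/2 pairs
           and are deterministic", {
  sim <- generate_study_like_dataset(seed = 15)
  ds <- subset_genotypes(sim$dataset, populations = c("pop1", "pop5"))
  est <- estimate_null_all(ds, steps = 300, dememorization = 300, seed = 1)
  tab <- dyad_frequency_table(ds, compare_nulls = TRUE, null_estimates = est)
  tab2 <- dyad_frequency_table(ds, compare_nulls = TRUE, null_estimates = est)
  expect_identical(tab, tab2)
  dy <- dyad_relationships(ds, pairs = "within", estimate_k = FALSE)
  for (pp in tab$population) {
    n_hs <- sum(dy$category == "HS" & dy$pop1 == pp)
    expect_equal(tab$hs_nna[tab$population == pp],
                 n_hs / pair_count(tab$n[tab$population == pp]))
  }
  ## a sample without planted kin stays at the false-positive floor
  expect_lte(tab$fs_nna[tab$population == "pop5"], 0.03)
})
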