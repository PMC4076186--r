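test_that("base frequency draws respect the Dirichlet limits and the seed", {
  cfg <- sim_config(n_loci = 3, alleles_per_locus = c(1L, 4L, 4L),
                    base_freq_concentration = 1e6, seed = 5)
  bf <- sample_base_frequencies(cfg)
  expect_equal(unname(bf$base$L1$p), 1)                       # single allele
  expect_true(all(abs(bf$base$L2$p - 0.25) < 0.01))           # near-uniform
  bf2 <- sample_base_frequencies(cfg)
  expect_identical(bf, bf2)                                    # determinism
})

test_that("Balding-Nichols frequencies have variance F p (1-p)", {
  cfg <- sim_config(n_loci = 1, alleles_per_locus = 2,
                    base_freq_concentration = 1e9, seed = 3)
  base <- sample_base_frequencies(cfg)          # p ~ 0.5 each
  fr <- derive_population_frequencies(base, 4000, 0.2, seed = 3)
  p1 <- vapply(fr, function(cell) cell$L1$p[["1"]], numeric(1))
  expect_equal(mean(p1), 0.5, tolerance = 0.02)
  ## closed form: F p (1-p) = 0.05
  expect_equal(var(p1), 0.05, tolerance = 0.1)
  ## F = 0 returns base unchanged
  fr0 <- derive_population_frequencies(base, 3, 0, seed = 3)
  for (pp in names(fr0)) expect_equal(fr0[[pp]]$L1$p, base$base$L1$p)
})

test_that("forced identity-by-descent makes every individual homozygous", {
  cfg <- sim_config(n_pops = 1, pop_sizes = 40, n_loci = 5,
                    alleles_per_locus = 6, inbreeding_f = 1, seed = 8)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 1, 0, 8)
  ds <- simulate_pedigree_sample(fr, cfg)$dataset
  expect_true(all(ds$allele1 == ds$allele2))
})

test_that("observed heterozygosity recovers (1 - F) He under inbreeding", {
  cfg <- sim_config(n_pops = 1, pop_sizes = 600, n_loci = 12,
                    alleles_per_locus = 8, inbreeding_f = 0.3, seed = 21)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 1, 0, 21)
  ds <- simulate_pedigree_sample(fr, cfg)$dataset
  summ <- locus_summary(ds, hwe = "none")
  expect_equal(mean(summ$ho) / mean(summ$he), 0.7, tolerance = 0.05)
})

test_that("pedigree truth matches shared-parent counts and empty plans", {
  plan <- list(list(list(category = "FS", size = 3),
                    list(category = "HS", size = 3)))
  cfg <- sim_config(n_pops = 1, pop_sizes = 10, n_loci = 2,
                    alleles_per_locus = 4, family_plan = plan, seed = 2)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 1, 0, 2)
  sim <- simulate_pedigree_sample(fr, cfg)
  dy <- true_dyad_categories(sim$truth$pedigree, include_unrelated = TRUE)
  ped <- sim$truth$pedigree
  ## exhaustive consistency: category == shared-parent count mapping
  for (r in seq_len(nrow(dy))) {
    i <- match(dy$id1[r], ped$individual); j <- match(dy$id2[r], ped$individual)
    shared <- sum(c(ped$mother[i], ped$father[i]) %in%
                    c(ped$mother[j], ped$father[j]))
    expect_equal(dy$category[r], c("UR", "HS", "FS")[shared + 1])
  }
  expect_equal(nrow(dy), pair_count(10))
  expect_equal(sum(dy$category == "FS"), 3)   # C(3,2) within the FS family
  expect_equal(sum(dy$category == "HS"), 3)
  ## the bundle's sparse table lists exactly the related pairs
  expect_equal(nrow(sim$truth$dyads), 6)
  expect_true(all(sim$truth$dyads$category %in% c("HS", "FS")))
  ## no families -> no related pairs, every dyad UR
  cfg0 <- sim_config(n_pops = 1, pop_sizes = 8, n_loci = 2, seed = 2)
  sim0 <- simulate_pedigree_sample(fr, cfg0)
  expect_equal(nrow(sim0$truth$dyads), 0)
  dy0 <- true_dyad_categories(sim0$truth$pedigree, include_unrelated = TRUE)
  expect_true(all(dy0$category == "UR"))
  ## plan exceeding the population errors at config time
  expect_error(sim_config(n_pops = 1, pop_sizes = 4,
                          family_plan = list(list(list(category = "FS",
                                                       size = 5)))),
               "exceeds")
})

test_that("full-sib offspring dyad genotypes match exhaustive enumeration", {
  ## one 2-allele locus, many independent FS families of 2
  n_fam <- 4000
  plan <- list(replicate(n_fam, list(category = "FS", size = 2L),
                         simplify = FALSE))
  cfg <- sim_config(n_pops = 1, pop_sizes = 2L * n_fam, n_loci = 1,
                    alleles_per_locus = 2, base_freq_concentration = 1e9,
                    family_plan = plan, seed = 13)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 1, 0, 13)
  ds <- simulate_pedigree_sample(fr, cfg)$dataset
  p <- fr$pop1$L1$p
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "/")
  sib1 <- seq(1, 2 * n_fam, by = 2); sib2 <- sib1 + 1
  obs <- table(key(ds$allele1[sib1, 1], ds$allele2[sib1, 1]),
               key(ds$allele1[sib2, 1], ds$allele2[sib2, 1])) / n_fam
  genos <- list(c(1L, 1L), c(1L, 2L), c(2L, 2L))
  for (g1 in genos) for (g2 in genos) {
    expected <- ped_enum_joint(g1, g2, p, "FS")
    got <- tryCatch(obs[key(g1[1], g1[2]), key(g2[1], g2[2])],
                    error = function(e) 0)
    expect_lt(abs(unname(got) - expected), 0.02)
  }
})

test_that("null-allele masking follows the hidden-gamete model", {
  cfg <- sim_config(n_pops = 1, pop_sizes = 4000, n_loci = 2,
                    alleles_per_locus = 6, seed = 31)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg), 1, 0, 31)
  ds <- simulate_pedigree_sample(fr, cfg)$dataset
  r <- 0.3
  obs <- apply_null_alleles(ds, c(r, 0), seed = 31)
  ## blank fraction ~ r^2 at the affected locus, none at the clean locus
  expect_equal(mean(is.na(obs$allele1[, 1])), r^2, tolerance = 0.2)
  expect_equal(mean(is.na(obs$allele1[, 2])), 0)
  ## homozygote excess grows monotonically with the null frequency
  hom_frac <- vapply(c(0, 0.15, 0.35), function(rr) {
    o <- apply_null_alleles(ds, c(rr, 0), seed = 7)
    g1 <- o$allele1[, 1]; g2 <- o$allele2[, 1]
    mean(g1[!is.na(g1)] == g2[!is.na(g1)])
  }, numeric(1))
  expect_true(all(diff(hom_frac) > 0))
  ## visible/visible genotypes are never altered
  same <- !is.na(obs$allele1[, 1]) &
    obs$allele1[, 1] == ds$allele1[, 1] & obs$allele2[, 1] == ds$allele2[, 1]
  het_kept <- ds$allele1[, 1] != ds$allele2[, 1] & !is.na(obs$allele1[, 1]) &
    obs$allele1[, 1] != obs$allele2[, 1]
  expect_true(all(same[het_kept]))
})

test_that("the study-like generator reproduces the survey dimensions", {
  sim <- generate_study_like_dataset(seed = 4)
  ds <- sim$dataset
  expect_equal(length(ds$individuals), 259L)
  expect_equal(length(ds$loci), 9L)
  expect_equal(unname(population_sizes(ds)),
               c(52L, 43L, 36L, 24L, 13L, 53L, 14L, 24L))
  expect_silent(validate_genotype_dataset(ds))
  sim2 <- generate_study_like_dataset(seed = 4)
  expect_identical(ds$allele1, sim2$dataset$allele1)
  ## truth bundle serializes to JSON
  path <- tempfile(fileext = ".json")
  write_truth_bundle(sim$truth, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
  unlink(path)
})
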