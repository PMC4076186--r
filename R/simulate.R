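#' Simulation configuration
#'
#' Bundles the parameters of the synthetic microsatellite generator:
#' population layout, locus panel, Dirichlet base frequencies,
#' Balding-Nichols differentiation, inbreeding, family plans (full-sib and
#' half-sib blocks), per-locus null-allele frequencies and a uniform
#' genotyping error rate. One global seed governs all draws; each stage
#' derives its own stream so stages are independently reproducible.
#'
#' @param n_pops Number of population samples.
#' @param pop_sizes Integer vector (recycled to `n_pops`) of sample sizes.
#' @param n_loci Number of loci.
#' @param alleles_per_locus Scalar or per-locus integer vector.
#' @param base_freq_concentration Symmetric Dirichlet concentration for the
#'   base (ancestral) allele frequencies; large values give near-uniform
#'   frequencies.
#' @param fst_target Balding-Nichols differentiation parameter in [0, 1).
#' @param inbreeding_f Probability that an offspring's second gamete is an
#'   identical-by-descent copy of its first; yields expected observed
#'   heterozygosity (1 - F) * He.
#' @param family_plan `NULL`, or a list with one element per population:
#'   each a list of `list(category = "FS"|"HS", size = k)` blocks
#'   (`k >= 2`); remaining individuals are unrelated.
#' @param null_freqs Scalar or per-locus null-allele frequencies in [0, 1).
#' @param error_rate Uniform random allele-replacement rate in [0, 1);
#'   0 by default.
#' @param seed Integer master seed.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_pops = 1L, pop_sizes = 30L, n_loci = 10L,
                       alleles_per_locus = 8L, base_freq_concentration = 1,
                       fst_target = 0, inbreeding_f = 0, family_plan = NULL,
                       null_freqs = 0, error_rate = 0, seed = 1L) {
  pop_sizes <- rep_len(as.integer(pop_sizes), n_pops)
  alleles_per_locus <- rep_len(as.integer(alleles_per_locus), n_loci)
  null_freqs <- rep_len(as.numeric(null_freqs), n_loci)
  stopifnot(n_pops >= 1L, all(pop_sizes >= 1L), n_loci >= 1L,
            all(alleles_per_locus >= 1L), base_freq_concentration > 0,
            fst_target >= 0, fst_target < 1,
            inbreeding_f >= 0, inbreeding_f <= 1,
            all(null_freqs >= 0), all(null_freqs < 1),
            error_rate >= 0, error_rate < 1)
  if (!is.null(family_plan)) {
    if (length(family_plan) != n_pops)
      stop("family_plan needs one element per population")
    for (i in seq_len(n_pops)) {
      for (fam in family_plan[[i]]) {
        if (!fam$category %in% c("FS", "HS")) stop("family category must be FS or HS")
        if (fam$size < 2L) stop("family sizes must be >= 2")
      }
      tot <- sum(vapply(family_plan[[i]], function(f) f$size, numeric(1)))
      if (tot > pop_sizes[i])
        stop("family plan exceeds population size in population ", i)
    }
  }
  structure(list(n_pops = n_pops, pop_sizes = pop_sizes, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus,
                 base_freq_concentration = base_freq_concentration,
                 fst_target = fst_target, inbreeding_f = inbreeding_f,
                 family_plan = family_plan, null_freqs = null_freqs,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

## fixed seed splitting: independent, reproducible per-stage streams
derive_seed <- function(seed, stage) {
  offs <- c(base = 101L, popfreq = 211L, pedigree = 307L, nulls = 401L,
            error = 503L)
  as.integer((as.numeric(seed) * 7919 + offs[[stage]] * 104729) %% 2147483647)
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1  # degenerate guard
  x / sum(x)
}

#' Draw base (ancestral) allele frequencies
#'
#' Per locus, a symmetric Dirichlet draw with the configured concentration.
#'
#' @param config A `sim_config`.
#' @return An `allele_freq_table` with a single population `"base"`.
#' @export
sample_base_frequencies <- function(config) {
  set.seed(derive_seed(config$seed, "base"))
  loci <- paste0("L", seq_len(config$n_loci))
  cell <- lapply(seq_len(config$n_loci), function(l) {
    k <- config$alleles_per_locus[l]
    p <- rdirichlet1(rep(config$base_freq_concentration, k))
    list(p = setNames(p, as.character(seq_len(k))), null = 0,
         n_typed = NA_integer_)
  })
  structure(setNames(list(setNames(cell, loci)), "base"),
            class = "allele_freq_table")
}

#' Derive differentiated population frequencies (Balding-Nichols)
#'
#' Per population and locus, frequencies are drawn from a Dirichlet with
#' parameters `p * (1 - F) / F` around the base frequencies `p`, so each
#' allele frequency has expectation `p` and variance `F p (1 - p)` — the
#' Balding-Nichols construction, which gives the simulator an analytic
#' F_ST oracle.
#'
#' @param base An `allele_freq_table` with one population (e.g. from
#'   [sample_base_frequencies()]).
#' @param n_pops Number of populations to derive.
#' @param fst_target F in [0, 1); 0 returns the base unchanged per
#'   population (no sampling).
#' @param seed Integer seed.
#' @return An `allele_freq_table` with populations `pop1..popK`.
#' @export
derive_population_frequencies <- function(base, n_pops, fst_target, seed) {
  stopifnot(fst_target >= 0, fst_target < 1)
  basecell <- base[[1L]]
  loci <- names(basecell)
  set.seed(derive_seed(seed, "popfreq"))
  pops <- paste0("pop", seq_len(n_pops))
  out <- lapply(pops, function(pp) {
    cell <- lapply(loci, function(lc) {
      p <- basecell[[lc]]$p
      if (fst_target == 0 || length(p) == 1L) return(basecell[[lc]])
      q <- rdirichlet1(p * (1 - fst_target) / fst_target)
      list(p = setNames(q, names(p)), null = 0, n_typed = NA_integer_)
    })
    setNames(cell, loci)
  })
  structure(setNames(out, pops), class = "allele_freq_table")
}

## draw one gamete per row from frequency vector p (names = labels)
draw_gametes <- function(p, n) {
  as.integer(names(p))[sample.int(length(p), n, replace = TRUE, prob = p)]
}

#' Simulate a multi-population sample with known pedigree
#'
#' Founders (parents) are random unions of gametes from each population's
#' allele frequencies. Each full-sib (FS) family is a single sampled parent
#' pair with independent Mendelian offspring; each half-sib (HS) family
#' shares one parent (the "mother", a labelling convention only) with a
#' distinct mate per offspring. Individuals outside family blocks are
#' unrelated. With probability `inbreeding_f` an offspring's second gamete
#' is replaced by an identical-by-descent copy of its first, so observed
#' heterozygosity has expectation (1 - F) He.
#'
#' @param freqs An `allele_freq_table` with one entry per population.
#' @param config A `sim_config` (family plan, inbreeding, sizes, seed).
#' @return A list with `dataset` (`genotype_dataset`) and `truth`
#'   (`truth_bundle`): pedigree (parent pair per individual), the true
#'   within-population dyad categories implied by shared-parent counts
#'   (0/1/2 -> UR/HS/FS; the table lists related pairs, any absent pair
#'   being UR), and the configuration echo.
#' @export
simulate_pedigree_sample <- function(freqs, config) {
  set.seed(derive_seed(config$seed, "pedigree"))
  pops <- names(freqs)[seq_len(config$n_pops)]
  loci <- names(freqs[[1L]])
  L <- length(loci)
  ids <- character(0); poplab <- character(0)
  mother <- character(0); father <- character(0)
  a1 <- NULL; a2 <- NULL
  parent_counter <- 0L

  for (pi in seq_along(pops)) {
    pp <- pops[pi]
    npop <- config$pop_sizes[pi]
    plan <- if (is.null(config$family_plan)) list() else config$family_plan[[pi]]
    pfreq <- freqs[[pp]]
    draw_parent <- function() {
      parent_counter <<- parent_counter + 1L
      g <- vapply(loci, function(lc) {
        p <- pfreq[[lc]]$p
        c(draw_gametes(p, 1L), draw_gametes(p, 1L))
      }, numeric(2))
      list(id = paste0("par", parent_counter), g = g)  # g: 2 x L
    }
    offspring_of <- function(pa, pb) {
      g1 <- vapply(seq_len(L), function(l) pa$g[sample.int(2L, 1L), l], numeric(1))
      g2 <- vapply(seq_len(L), function(l) pb$g[sample.int(2L, 1L), l], numeric(1))
      if (runif(1) < config$inbreeding_f) g2 <- g1  # IBD copy of first gamete
      rbind(g1, g2)
    }
    n_done <- 0L
    for (fam in plan) {
      if (identical(fam$category, "FS")) {
        pa <- draw_parent(); pb <- draw_parent()
        for (o in seq_len(fam$size)) {
          g <- offspring_of(pa, pb)
          ids <- c(ids, sprintf("%s_i%03d", pp, n_done + o))
          poplab <- c(poplab, pp)
          mother <- c(mother, pa$id); father <- c(father, pb$id)
          a1 <- rbind(a1, g[1L, ]); a2 <- rbind(a2, g[2L, ])
        }
      } else {  # HS: shared mother, distinct father per offspring
        pa <- draw_parent()
        for (o in seq_len(fam$size)) {
          pb <- draw_parent()
          g <- offspring_of(pa, pb)
          ids <- c(ids, sprintf("%s_i%03d", pp, n_done + o))
          poplab <- c(poplab, pp)
          mother <- c(mother, pa$id); father <- c(father, pb$id)
          a1 <- rbind(a1, g[1L, ]); a2 <- rbind(a2, g[2L, ])
        }
      }
      n_done <- n_done + fam$size
    }
    while (n_done < npop) {
      n_done <- n_done + 1L
      pa <- draw_parent(); pb <- draw_parent()
      g <- offspring_of(pa, pb)
      ids <- c(ids, sprintf("%s_i%03d", pp, n_done))
      poplab <- c(poplab, pp)
      mother <- c(mother, pa$id); father <- c(father, pb$id)
      a1 <- rbind(a1, g[1L, ]); a2 <- rbind(a2, g[2L, ])
    }
  }

  if (config$error_rate > 0) {
    set.seed(derive_seed(config$seed, "error"))
    for (m in c("a1", "a2")) {
      mat <- get(m)
      hit <- which(runif(length(mat)) < config$error_rate)
      for (h in hit) {
        lc <- loci[(h - 1L) %/% length(ids) + 1L]
        pp <- poplab[(h - 1L) %% length(ids) + 1L]
        mat[h] <- draw_gametes(freqs[[pp]][[lc]]$p, 1L)
      }
      assign(m, mat)
    }
  }

  ds <- genotype_dataset(ids, poplab, loci, a1, a2)
  pedigree <- data.frame(individual = ids, population = poplab,
                         mother = mother, father = father,
                         stringsAsFactors = FALSE)
  truth <- structure(
    list(pedigree = pedigree,
         dyads = true_dyad_categories(pedigree),
         true_null_freqs = setNames(config$null_freqs, loci),
         fst_target = config$fst_target,
         frequencies = freqs,
         config = config),
    class = "truth_bundle")
  list(dataset = ds, truth = truth)
}

#' True dyad categories implied by a pedigree
#'
#' Shared-parent counts 0/1/2 map to UR/HS/FS for within-population
#' pairs. By default only related pairs (HS/FS) are listed — any pair
#' absent from the table is UR by construction — which keeps the truth
#' bundle small for large simulations. `include_unrelated = TRUE`
#' enumerates every pair explicitly (quadratic; meant for small
#' pedigrees and exhaustive checks).
#'
#' @param pedigree Data frame with columns `individual`, `population`,
#'   `mother`, `father`.
#' @param include_unrelated List UR pairs too (default FALSE).
#' @return Data frame `id1,id2,population,category`.
#' @export
true_dyad_categories <- function(pedigree, include_unrelated = FALSE) {
  empty <- data.frame(id1 = character(0), id2 = character(0),
                      population = character(0), category = character(0),
                      stringsAsFactors = FALSE)
  out <- list()
  for (pp in unique(pedigree$population)) {
    sub <- pedigree[pedigree$population == pp, ]
    n <- nrow(sub)
    if (n < 2L) next
    if (include_unrelated) {
      pr <- combn(n, 2L)
      i <- pr[1L, ]; j <- pr[2L, ]
    } else {
      ## candidate related pairs: individuals grouped by a shared parent
      groups <- split(rep(seq_len(n), 2L), c(sub$mother, sub$father))
      pairs <- unique(do.call(rbind, lapply(groups, function(g) {
        g <- sort(unique(g))
        if (length(g) < 2L) return(NULL)
        t(combn(g, 2L))
      })))
      if (is.null(pairs) || !nrow(pairs)) next
      i <- pairs[, 1L]; j <- pairs[, 2L]
    }
    shared <- (sub$mother[i] == sub$mother[j] |
                 sub$mother[i] == sub$father[j]) +
              (sub$father[i] == sub$mother[j] |
                 sub$father[i] == sub$father[j])
    out[[pp]] <- data.frame(
      id1 = sub$individual[i], id2 = sub$individual[j],
      population = pp,
      category = c("UR", "HS", "FS")[shared + 1L],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Overlay null alleles on a simulated dataset
#'
#' A hidden null allele is inserted at gamete level: each allele copy
#' independently becomes null with the locus's null frequency (visible
#' frequencies renormalize implicitly). Observed genotypes follow the
#' classic null-allele model: visible/visible unchanged, visible/null
#' recorded as a visible homozygote, null/null recorded as a blank.
#'
#' @param ds A `genotype_dataset`.
#' @param null_freqs Scalar or per-locus vector in [0, 1).
#' @param seed Integer seed.
#' @return A `genotype_dataset` with the observed (masked) genotypes.
#' @export
apply_null_alleles <- function(ds, null_freqs, seed) {
  L <- length(ds$loci)
  null_freqs <- rep_len(as.numeric(null_freqs), L)
  stopifnot(all(null_freqs >= 0), all(null_freqs < 1))
  set.seed(derive_seed(seed, "nulls"))
  a1 <- ds$allele1; a2 <- ds$allele2
  n <- nrow(a1)
  for (l in seq_len(L)) {
    r <- null_freqs[l]
    if (r == 0) next
    null1 <- runif(n) < r
    null2 <- runif(n) < r
    typed <- !is.na(a1[, l])
    both <- typed & null1 & null2
    only1 <- typed & null1 & !null2
    only2 <- typed & !null1 & null2
    a1[both, l] <- NA_integer_; a2[both, l] <- NA_integer_
    a1[only1, l] <- a2[only1, l]   # visible/null looks homozygous
    a2[only2, l] <- a1[only2, l]
  }
  genotype_dataset(ds$individuals, ds$populations, ds$loci, a1, a2)
}

#' Generate a study-like blooming-jellyfish dataset
#'
#' A single call producing a dataset with the statistical structure of a
#' small-scale bloom survey: 8 population samples of sizes
#' 52, 43, 36, 24, 13, 53, 14, 24 (259 individuals), 9 microsatellite loci
#' with allele pools of 4 to 18, weak among-sample differentiation
#' (Balding-Nichols F = 0.02), inbreeding F = 0.25, per-locus null alleles
#' up to 0.12, and family plans planting full-sib and half-sib blocks in
#' five of the eight samples so that within-sample HS/FS dyad frequencies
#' fall in the few-per-mille to few-percent range.
#'
#' @param seed Integer seed.
#' @return A list with `dataset` and `truth`, as
#'   [simulate_pedigree_sample()].
#' @export
generate_study_like_dataset <- function(seed = 1L) {
  sizes <- c(52L, 43L, 36L, 24L, 13L, 53L, 14L, 24L)
  plan <- list(
    list(list(category = "HS", size = 7L), list(category = "FS", size = 2L)),   # pop1
    list(list(category = "HS", size = 5L), list(category = "FS", size = 2L)),   # pop2
    list(list(category = "HS", size = 5L)),                                     # pop3
    list(list(category = "FS", size = 2L)),                                     # pop4
    list(),                                                                     # pop5
    list(list(category = "HS", size = 8L), list(category = "HS", size = 4L),
         list(category = "FS", size = 3L)),                                     # pop6
    list(),                                                                     # pop7
    list(list(category = "HS", size = 3L), list(category = "FS", size = 2L))    # pop8
  )
  cfg <- sim_config(
    n_pops = 8L, pop_sizes = sizes, n_loci = 9L,
    alleles_per_locus = c(4L, 8L, 16L, 5L, 8L, 7L, 18L, 7L, 8L),
    base_freq_concentration = 0.8, fst_target = 0.02, inbreeding_f = 0.25,
    family_plan = plan,
    null_freqs = c(0.02, 0.10, 0.12, 0.05, 0.10, 0.04, 0.12, 0.00, 0.03),
    error_rate = 0, seed = seed)
  base <- sample_base_frequencies(cfg)
  freqs <- derive_population_frequencies(base, cfg$n_pops, cfg$fst_target,
                                         cfg$seed)
  sim <- simulate_pedigree_sample(freqs, cfg)
  sim$dataset <- apply_null_alleles(sim$dataset, cfg$null_freqs, cfg$seed)
  sim
}

#' Serialize a truth bundle to JSON
#'
#' @param truth A `truth_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bundle <- function(truth, path) {
  cfg <- truth$config
  obj <- list(
    pedigree = truth$pedigree,
    dyads = truth$dyads,
    true_null_freqs = as.list(truth$true_null_freqs),
    fst_target = truth$fst_target,
    config = list(n_pops = cfg$n_pops, pop_sizes = cfg$pop_sizes,
                  n_loci = cfg$n_loci,
                  alleles_per_locus = cfg$alleles_per_locus,
                  base_freq_concentration = cfg$base_freq_concentration,
                  fst_target = cfg$fst_target,
                  inbreeding_f = cfg$inbreeding_f,
                  null_freqs = cfg$null_freqs,
                  error_rate = cfg$error_rate, seed = cfg$seed))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
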