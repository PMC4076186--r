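#' Run configuration for the full analysis
#'
#' @param input Path to a GenePop (`.gen`) or long-form CSV file, or a
#'   `genotype_dataset`; `NULL` to simulate via `sim`.
#' @param sim Optional `sim_config` used when `input` is `NULL` (default:
#'   the study-like generator).
#' @param null_mode `"raw"`, `"corrected"` or `"both"` (default): which
#'   dataset(s) the relatedness and F-statistics stages analyse.
#' @param hwe_steps,hwe_dememorization Markov-chain settings.
#' @param ld_iterations,permutations,fst_iterations,bootstrap_iterations
#'   Iteration counts (all >= 1).
#' @param min_confidence Sibship edge threshold.
#' @param seed Master seed.
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @return A `run_config`.
#' @export
run_config <- function(input = NULL, sim = NULL,
                       null_mode = c("both", "raw", "corrected"),
                       hwe_steps = 1000L, hwe_dememorization = 10000L,
                       ld_iterations = 999L, permutations = 1000L,
                       fst_iterations = 999L, bootstrap_iterations = 50000L,
                       min_confidence = 0.95, seed = 1L, out_dir = NULL) {
  null_mode <- match.arg(null_mode)
  counts <- c(hwe_steps, ld_iterations, permutations, fst_iterations,
              bootstrap_iterations)
  if (any(counts < 1L)) stop("iteration counts must be >= 1")
  structure(list(input = input, sim = sim, null_mode = null_mode,
                 hwe_steps = as.integer(hwe_steps),
                 hwe_dememorization = as.integer(hwe_dememorization),
                 ld_iterations = as.integer(ld_iterations),
                 permutations = as.integer(permutations),
                 fst_iterations = as.integer(fst_iterations),
                 bootstrap_iterations = as.integer(bootstrap_iterations),
                 min_confidence = min_confidence,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full analysis workflow
#'
#' Genotype ingest (or simulation), diversity and Hardy-Weinberg summary,
#' linkage-disequilibrium screen, null-allele estimation and correction,
#' dyad classification and HS/FS frequencies (with and without null
#' accommodation), kin-aggregation permutation tests, paired t-test
#' comparisons of the two modes, sibship networks, and F-statistics (raw
#' and ENA-corrected) with bootstrap CI. Identical seeds give identical
#' bundles.
#'
#' @param config A `run_config` (or arguments forwarded to [run_config()]).
#' @return A `report_bundle` list with one element per stage.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  ## ingest
  if (is.null(config$input)) {
    sim <- if (is.null(config$sim)) generate_study_like_dataset(seed)
           else {
             base <- sample_base_frequencies(config$sim)
             fr <- derive_population_frequencies(base, config$sim$n_pops,
                                                 config$sim$fst_target,
                                                 config$sim$seed)
             s <- simulate_pedigree_sample(fr, config$sim)
             s$dataset <- apply_null_alleles(s$dataset,
                                             config$sim$null_freqs,
                                             config$sim$seed)
             s
           }
    ds <- sim$dataset; truth <- sim$truth
  } else if (inherits(config$input, "genotype_dataset")) {
    ds <- config$input; truth <- NULL
  } else {
    ds <- if (grepl("\\.csv$", config$input, ignore.case = TRUE))
      read_genotype_csv(config$input) else read_genepop(config$input)
    truth <- NULL
  }
  validate_genotype_dataset(ds)
  pops <- unique(ds$populations)

  ## diversity + HWE
  summ <- locus_summary(ds, hwe = "mc", steps = config$hwe_steps,
                        dememorization = config$hwe_dememorization,
                        seed = seed)
  global_hwe <- vapply(ds$loci, function(lc)
    fisher_combine_p(summ$hwe_p[summ$locus == lc]), numeric(1))

  ## LD screen (per population, all locus pairs), Bonferroni threshold
  ld <- NULL
  if (length(ds$loci) >= 2L) {
    prs <- combn(ds$loci, 2L)
    rows <- list()
    s <- seed
    for (pp in pops) for (c0 in seq_len(ncol(prs))) {
      s <- s + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        population = pp, locus_a = prs[1L, c0], locus_b = prs[2L, c0],
        p = ld_genotypic_test(ds, prs[1L, c0], prs[2L, c0], pp,
                              iterations = config$ld_iterations, seed = s),
        stringsAsFactors = FALSE)
    }
    ld <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    ld$bonferroni_alpha <- bonferroni_threshold(0.05, ncol(prs))
  }

  ## null alleles + corrected dataset
  nulls <- estimate_null_all(ds, seed = seed)
  corrected <- adjust_genotypes(ds, nulls)

  ## F_IS (raw and corrected datasets)
  fis_raw <- fis_weir_cockerham(ds, randomizations = 0L,
                                n_boot = min(1000L, config$bootstrap_iterations),
                                seed = seed)
  fis_cor <- if (config$null_mode != "raw")
    fis_weir_cockerham(corrected, randomizations = 0L,
                       n_boot = min(1000L, config$bootstrap_iterations),
                       seed = seed) else NULL

  ## relatedness: dyad table + HS/FS frequencies, both modes
  dyfreq <- dyad_frequency_table(ds,
                                 compare_nulls = config$null_mode != "raw",
                                 null_estimates = nulls)
  ttests <- NULL
  if (config$null_mode != "raw") {
    hs <- paired_t_test(dyfreq$hs_nna, dyfreq$hs_na)
    fs <- paired_t_test(dyfreq$fs_nna, dyfreq$fs_na)
    ttests <- data.frame(comparison = c("HS", "FS"),
                         t = c(hs$t, fs$t), df = c(hs$df, fs$df),
                         p = c(hs$p, fs$p), stringsAsFactors = FALSE)
  }

  ## kin aggregation permutation test
  kin <- if (length(pops) >= 2L)
    relatedness_permutation_test(ds, n_permutations = config$permutations,
                                 seed = seed,
                                 with_nulls = config$null_mode == "corrected")
    else NULL

  ## sibship networks
  dy_within <- dyad_relationships(ds, pairs = "within", estimate_k = FALSE,
                                  with_nulls = config$null_mode == "corrected",
                                  null_estimates = nulls)
  parts <- sibship_partitions(ds, dyads = dy_within,
                              min_confidence = config$min_confidence)
  network_summary <- vapply(names(parts), function(pp)
    network_report(parts[[pp]], pp), character(1))

  ## F-statistics
  fst <- if (length(pops) >= 2L)
    pairwise_fst(ds, iterations = config$fst_iterations, seed = seed)
    else NULL
  global_ci <- if (length(pops) >= 2L)
    fst_bootstrap_ci(ds, iterations = config$bootstrap_iterations,
                     seed = seed) else NULL
  ena <- if (length(pops) >= 2L && config$null_mode != "raw")
    ena_corrected_theta(ds, nulls) else NULL

  bundle <- structure(list(
    dataset = ds, truth = truth, locus_summary = summ,
    global_hwe = global_hwe, ld = ld, null_estimates = nulls,
    corrected = corrected, fis = fis_raw, fis_corrected = fis_cor,
    dyad_frequencies = dyfreq, t_tests = ttests, kin_permutation = kin,
    sibship = parts, network_summary = network_summary, fst = fst,
    global_theta = global_ci, ena = ena, seed = seed,
    schema = "patchkin-bundle-1"), class = "report_bundle")
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' Write a report bundle as TSV/JSON files
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  tsv(bundle$locus_summary, "locus_summary.tsv")
  if (!is.null(bundle$ld)) tsv(bundle$ld, "linkage_disequilibrium.tsv")
  tsv(bundle$null_estimates, "null_estimates.tsv")
  tsv(bundle$dyad_frequencies, "dyad_frequencies.tsv")
  if (!is.null(bundle$t_tests)) tsv(bundle$t_tests, "null_comparison_t_tests.tsv")
  tsv(bundle$fis$per_locus, "fis_per_locus.tsv")
  if (!is.null(bundle$fst)) {
    utils::write.table(bundle$fst$theta, file.path(dir, "fst_theta.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(bundle$fst$p, file.path(dir, "fst_p.tsv"),
                       sep = "\t", quote = FALSE)
  }
  writeLines(bundle$network_summary, file.path(dir, "sibship_networks.txt"))
  summary <- list(
    schema = bundle$schema, seed = bundle$seed,
    n_individuals = length(bundle$dataset$individuals),
    n_loci = length(bundle$dataset$loci),
    fis_overall = bundle$fis$overall,
    fis_ci = bundle$fis$ci,
    fis_corrected_overall = if (!is.null(bundle$fis_corrected))
      bundle$fis_corrected$overall else NULL,
    global_theta = bundle$global_theta,
    ena_theta = if (!is.null(bundle$ena)) bundle$ena$theta else NULL,
    raw_theta = if (!is.null(bundle$ena)) bundle$ena$raw_theta else NULL,
    t_tests = bundle$t_tests)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("patchkin report bundle (seed ", x$seed, ")\n", sep = "")
  print(x$dataset)
  cat("overall F_IS:", round(x$fis$overall, 4), "\n")
  if (!is.null(x$global_theta))
    cat(sprintf("global theta: %.5f (95%% CI %.5f-%.5f)\n",
                x$global_theta$theta, x$global_theta$lower,
                x$global_theta$upper))
  if (!is.null(x$ena))
    cat(sprintf("ENA-corrected theta: %.5f (raw %.5f)\n",
                x$ena$theta, x$ena$raw_theta))
  cat("sibship networks:\n")
  for (s in x$network_summary) cat(" ", s, "\n")
  invisible(x)
}
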