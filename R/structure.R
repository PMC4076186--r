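#' Weir-Cockerham theta (F_ST)
#'
#' Variance components per allele and locus — a (among populations), b
#' (among individuals within populations), c (within individuals) — with
#' theta estimated as the ratio of sums `sum(a) / sum(a + b + c)` over
#' alleles and loci (never a mean of per-locus estimates). Blanks are
#' excluded per locus (pairwise deletion). Negative estimates are reported
#' as computed.
#'
#' @param ds A `genotype_dataset`.
#' @param pops Populations to include (>= 2); default all.
#' @param exclude_alleles Allele labels treated as a dropped class:
#'   genotypes carrying them are excluded per locus; used by the ENA
#'   correction to remove the null class.
#' @return List with `theta` (multilocus), `per_locus` (data frame), and
#'   the summed components `a`, `b`, `c`.
#' @export
wc_theta <- function(ds, pops = unique(ds$populations),
                     exclude_alleles = integer(0)) {
  if (length(pops) < 2L) stop("need >= 2 populations for theta")
  asum <- bsum <- csum <- 0
  per <- data.frame(locus = ds$loci, theta = NA_real_,
                    stringsAsFactors = FALSE)
  for (li in seq_along(ds$loci)) {
    cp <- wc_components_locus(ds, ds$loci[li], pops, exclude_alleles)
    if (is.null(cp)) next
    a <- cp$a; b <- cp$b; cc <- cp$c
    ok <- is.finite(a) & is.finite(b) & is.finite(cc)
    if (!any(ok)) next
    den <- sum(a[ok] + b[ok] + cc[ok])
    if (den != 0) per$theta[li] <- sum(a[ok]) / den
    asum <- asum + sum(a[ok]); bsum <- bsum + sum(b[ok])
    csum <- csum + sum(cc[ok])
  }
  theta <- if ((asum + bsum + csum) != 0) asum / (asum + bsum + csum)
           else NA_real_
  list(theta = theta, per_locus = per, a = asum, b = bsum, c = csum)
}

#' Permutation p-value for a pairwise theta
#'
#' Individuals (genotype rows) are permuted between the two samples with
#' sizes preserved; `p = (# permuted theta >= observed + 1) / (iter + 1)`.
#'
#' @param ds A `genotype_dataset`.
#' @param pop_a,pop_b Population labels.
#' @param iterations Default 999.
#' @param seed Integer seed.
#' @return List with `theta` (observed) and `p`.
#' @export
fst_permutation_p <- function(ds, pop_a, pop_b, iterations = 999L, seed = 1L) {
  sub <- subset_genotypes(ds, populations = c(pop_a, pop_b))
  obs <- wc_theta(sub, c(pop_a, pop_b))$theta
  n <- length(sub$individuals)
  set.seed(as.integer(seed))
  hits <- 0L
  for (it in seq_len(iterations)) {
    perm <- sub
    perm$populations <- sub$populations[sample.int(n)]
    th <- wc_theta(perm, c(pop_a, pop_b))$theta
    if (!is.na(th) && th >= obs - 1e-12) hits <- hits + 1L
  }
  list(theta = obs, p = (hits + 1) / (iterations + 1))
}

#' Pairwise theta matrix with permutation p-values
#'
#' @param ds A `genotype_dataset`.
#' @param iterations Permutations per pair (default 999).
#' @param seed Integer seed.
#' @param alpha Family-wise level for the Bonferroni flag (default 0.05
#'   over the number of pairwise tests).
#' @return An `fst_matrix`: `theta` and `p` matrices, `bonferroni_alpha`,
#'   `significant` logical matrix.
#' @export
pairwise_fst <- function(ds, iterations = 999L, seed = 1L, alpha = 0.05) {
  pops <- unique(ds$populations)
  k <- length(pops)
  th <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pv <- th
  s <- as.integer(seed)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    s <- s + 1L
    res <- fst_permutation_p(ds, pops[i], pops[j], iterations, seed = s)
    th[i, j] <- th[j, i] <- res$theta
    pv[i, j] <- pv[j, i] <- res$p
  }
  bonf <- bonferroni_threshold(alpha, k * (k - 1L) / 2L)
  structure(list(theta = th, p = pv, bonferroni_alpha = bonf,
                 significant = !is.na(pv) & pv < bonf),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  k <- nrow(x$theta)
  m <- matrix("", k, k, dimnames = dimnames(x$theta))
  m[lower.tri(m)] <- sprintf("%.4f", x$theta[lower.tri(x$theta)])
  m[upper.tri(m)] <- sprintf("%.4f", x$p[upper.tri(x$p)])
  cat("pairwise theta (below diagonal) and permutation p (above);",
      "Bonferroni alpha =", signif(x$bonferroni_alpha, 3), "\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Bootstrap confidence interval for multilocus theta
#'
#' Loci resampled with replacement; percentile 2.5/97.5 bounds.
#'
#' @param ds A `genotype_dataset`.
#' @param pops Populations (default all).
#' @param iterations Default 50000.
#' @param seed Integer seed.
#' @return List with `theta`, `lower`, `upper`. A single locus gives an
#'   undefined (NA) interval.
#' @export
fst_bootstrap_ci <- function(ds, pops = unique(ds$populations),
                             iterations = 50000L, seed = 1L) {
  obs <- wc_theta(ds, pops)
  L <- length(ds$loci)
  if (L < 2L)
    return(list(theta = obs$theta, lower = NA_real_, upper = NA_real_))
  ## per-locus component sums, resampled in aggregate (ratio of sums)
  comp <- t(vapply(ds$loci, function(lc) {
    cp <- wc_components_locus(ds, lc, pops)
    if (is.null(cp)) return(c(a = 0, b = 0, c = 0))
    ok <- is.finite(cp$a) & is.finite(cp$b) & is.finite(cp$c)
    c(a = sum(cp$a[ok]), b = sum(cp$b[ok]), c = sum(cp$c[ok]))
  }, numeric(3)))
  set.seed(as.integer(seed))
  draws <- replicate(iterations, {
    pick <- sample.int(L, replace = TRUE)
    s <- colSums(comp[pick, , drop = FALSE])
    if (sum(s) == 0) NA_real_ else s[["a"]] / sum(s)
  })
  qs <- quantile(draws, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(theta = obs$theta, lower = qs[1L], upper = qs[2L])
}

#' ENA-corrected multilocus theta
#'
#' Null-allele-robust theta: allele frequencies are re-estimated per
#' population and locus by the EM null model, the observed homozygote
#' excess is re-labelled as visible/null heterozygotes
#' ([adjust_genotypes()]), and the Weir-Cockerham components are computed
#' excluding the null class: genotypes carrying it are dropped per locus,
#' leaving a sample whose homozygote/heterozygote proportions emulate a
#' clean Hardy-Weinberg draw at the conditional visible frequencies. With
#' all null estimates at zero the result equals [wc_theta()] exactly.
#'
#' @param ds A `genotype_dataset` (raw, uncorrected).
#' @param null_estimates A `null_estimates` table; computed when `NULL`.
#' @param pops Populations (default all).
#' @return List as [wc_theta()], plus `raw_theta` for comparison.
#' @export
ena_corrected_theta <- function(ds, null_estimates = NULL,
                                pops = unique(ds$populations)) {
  if (is.null(null_estimates)) null_estimates <- estimate_null_all(ds)
  raw <- wc_theta(ds, pops)
  adj <- adjust_genotypes(ds, null_estimates)
  ena <- wc_theta(adj, pops, exclude_alleles = .NULL_SENTINEL)
  c(ena, list(raw_theta = raw$theta))
}
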