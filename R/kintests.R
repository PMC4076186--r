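#' Mean pairwise relatedness between (or within) samples
#'
#' Arithmetic mean of dyad relatedness `r` over all pairs with one member
#' in each population (all within-sample pairs when `pop_a == pop_b`).
#'
#' @param dyads Data frame from [dyad_relationships()] (needs `pop1`,
#'   `pop2`, `r`).
#' @param pop_a,pop_b Population labels.
#' @return Mean r, or `NA` when no valid dyads exist (flagged absent).
#' @export
mean_pairwise_r <- function(dyads, pop_a, pop_b) {
  sel <- (dyads$pop1 == pop_a & dyads$pop2 == pop_b) |
         (dyads$pop1 == pop_b & dyads$pop2 == pop_a)
  v <- dyads$r[sel]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Intra/inter-population mean relatedness matrix
#'
#' Symmetric matrix of mean pairwise r for every population pair; the
#' diagonal holds within-sample means. Dyad r values are computed once
#' over all pairs with pooled allele frequencies so that permutation tests
#' can re-index them.
#'
#' @param ds A `genotype_dataset`.
#' @param with_nulls Accommodate null alleles (EM estimates).
#' @param min_informative Passed to [dyad_relationships()]; default 1 so
#'   every typed dyad contributes.
#' @param dyads Optional precomputed all-pairs dyad table.
#' @return List with `mean_r` (matrix), `n_dyads` (matrix), `dyads`.
#' @export
relatedness_matrix <- function(ds, with_nulls = FALSE, min_informative = 1L,
                               dyads = NULL) {
  if (is.null(dyads))
    dyads <- dyad_relationships(ds, pairs = "all", freq_scope = "pooled",
                                with_nulls = with_nulls,
                                min_informative = min_informative)
  pops <- unique(ds$populations)
  k <- length(pops)
  m <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  nd <- matrix(0L, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k)) for (j in i:k) {
    sel <- (dyads$pop1 == pops[i] & dyads$pop2 == pops[j]) |
           (dyads$pop1 == pops[j] & dyads$pop2 == pops[i])
    v <- dyads$r[sel]; v <- v[!is.na(v)]
    if (length(v)) { m[i, j] <- m[j, i] <- mean(v) }
    nd[i, j] <- nd[j, i] <- length(v)
  }
  list(mean_r = m, n_dyads = nd, dyads = dyads)
}

#' Permutation test of kin aggregation
#'
#' Tests, for every population pair (and within every sample on the
#' diagonal), whether mean relatedness is higher than expected by chance.
#' Individuals' population labels are permuted globally each iteration
#' (sample sizes preserved); dyad r values are computed once and
#' re-indexed under the permuted labels. One-tailed upper p-values with
#' the add-one correction.
#'
#' @param ds A `genotype_dataset` with >= 2 populations.
#' @param n_permutations Default 1000.
#' @param seed Integer seed; identical seeds give identical results.
#' @param with_nulls Accommodate null alleles in the dyad likelihoods.
#' @param recompute Recompute dyad r from permuted per-population allele
#'   frequencies each iteration instead of re-indexing (slow; default
#'   FALSE).
#' @return A `kin_permutation` object: `observed` (mean-r matrix), `p`
#'   (p-value matrix), `n_permutations`, `seed`.
#' @export
relatedness_permutation_test <- function(ds, n_permutations = 1000L,
                                         seed = 1L, with_nulls = FALSE,
                                         recompute = FALSE) {
  pops <- unique(ds$populations)
  if (length(pops) < 2L) stop("need >= 2 populations")
  rm0 <- relatedness_matrix(ds, with_nulls = with_nulls)
  obs <- rm0$mean_r
  dy <- rm0$dyads
  n <- length(ds$individuals)
  i1 <- match(dy$id1, ds$individuals)
  i2 <- match(dy$id2, ds$individuals)
  rv <- dy$r
  k <- length(pops)
  popf <- factor(ds$populations, levels = pops)
  count_ge <- matrix(0L, k, k, dimnames = list(pops, pops))
  set.seed(as.integer(seed))
  for (b in seq_len(n_permutations)) {
    lab <- if (recompute) NULL else as.integer(popf)[sample.int(n)]
    if (recompute) {
      perm <- ds
      perm$populations <- ds$populations[sample.int(n)]
      rmb <- relatedness_matrix(perm, with_nulls = with_nulls)
      mb <- rmb$mean_r
    } else {
      p1 <- lab[i1]; p2 <- lab[i2]
      mb <- matrix(NA_real_, k, k)
      for (a in seq_len(k)) for (bb in a:k) {
        sel <- (p1 == a & p2 == bb) | (p1 == bb & p2 == a)
        v <- rv[sel]; v <- v[!is.na(v)]
        if (length(v)) mb[a, bb] <- mb[bb, a] <- mean(v)
      }
    }
    ge <- !is.na(mb) & !is.na(obs) & (mb >= obs - 1e-12)
    count_ge <- count_ge + ge
  }
  p <- (count_ge + 1) / (n_permutations + 1)
  p[is.na(obs)] <- NA_real_
  ## intra cells for singleton samples are absent
  sizes <- population_sizes(ds)
  for (pp in pops) if (sizes[[pp]] < 2L) p[pp, pp] <- NA_real_
  structure(list(observed = obs, p = p, n_permutations = n_permutations,
                 seed = as.integer(seed)),
            class = "kin_permutation")
}

#' @export
print.kin_permutation <- function(x, ...) {
  cat("Kin-aggregation permutation test (", x$n_permutations,
      " permutations, seed ", x$seed, ")\n", sep = "")
  cat("one-tailed p (mean r could be higher than observed):\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Paired two-tailed t-test
#'
#' Classic paired t on the differences (df = n - 1). All-zero differences
#' return p = 1 by convention (no evidence of any difference); constant
#' non-zero differences return p = 0.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (sd(d) <= 1e-12 * (max(abs(d)) + 1)) {  # constant differences
    if (all(abs(d) <= 1e-12 * (max(abs(x), abs(y)) + 1)))
      return(list(t = 0, df = length(d) - 1L, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
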