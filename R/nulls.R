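#' Moment estimators of null-allele frequency
#'
#' Closed-form estimators from the observed and expected heterozygosity:
#' Chakraborty's `(He - Ho) / (He + Ho)` and Brookfield's first estimator
#' `(He - Ho) / (1 + He)`. Negative estimates (heterozygote excess) are
#' clamped to zero.
#'
#' @param ho Observed heterozygosity in [0, 1].
#' @param he Expected heterozygosity in (0, 1]; 0 returns 0 (monomorphic).
#' @param method `"chakraborty"` or `"brookfield1"`.
#' @return Estimated null-allele frequency (>= 0).
#' @export
estimate_null_moment <- function(ho, he, method = c("chakraborty", "brookfield1")) {
  method <- match.arg(method)
  stopifnot(ho >= 0, ho <= 1, he >= 0, he <= 1)
  if (he == 0) return(0)
  r <- switch(method,
              chakraborty = (he - ho) / (he + ho),
              brookfield1 = (he - ho) / (1 + he))
  max(0, r)
}

#' EM estimation of null-allele frequency at one locus
#'
#' Treats the null as an extra allele class. E-step: each observed
#' homozygote (i,i) is split between true (i,i) and (i,null) in ratio
#' `p_i : 2 p_null`; each blank is attributed to (null,null) (optionally
#' excluded). M-step: gamete counts renormalize the frequency vector.
#' The observed-data log-likelihood is non-decreasing across iterations
#' and is returned as a trace.
#'
#' @param counts Genotype counts for one (population, locus) cell — the
#'   list from the internal counter or a square count matrix.
#' @param n_blank Number of blank genotypes (ignored when `counts` is the
#'   internal list, which carries it).
#' @param include_blanks Treat blanks as (null,null) observations
#'   (default TRUE); when FALSE the likelihood conditions on amplification.
#' @param max_iter,tol Convergence controls.
#' @return List with `p_visible` (named, sums to 1 - null), `null_freq`,
#'   `loglik_trace`, `n_iter`, `converged`.
#' @export
estimate_null_em <- function(counts, n_blank = 0L, include_blanks = TRUE,
                             max_iter = 2000L, tol = 1e-10) {
  if (is.list(counts) && !is.null(counts$n_blank)) n_blank <- counts$n_blank
  gt <- as_genotype_table(counts)
  up <- gt$counts
  k <- nrow(up)
  n_vis <- sum(up)
  if (n_vis < 1L) {
    ## all genotypes blank: boundary, null frequency -> 1
    return(list(p_visible = numeric(0), null_freq = 1,
                loglik_trace = numeric(0), n_iter = 0L, converged = TRUE))
  }
  labels <- rownames(up)
  nb <- if (include_blanks) n_blank else 0L
  n <- n_vis + nb
  ## init: visible frequencies from raw counts, small null mass
  p <- (rowSums(up) + colSums(up)) / (2 * n_vis)
  pn <- if (nb > 0) max(0.05, sqrt(nb / n)) else 0.05
  p <- p * (1 - pn)
  het_idx <- which(upper.tri(up) & up > 0, arr.ind = TRUE)
  hom <- unname(diag(up))
  loglik <- function(p, pn) {
    ll <- 0
    if (nrow(het_idx)) {
      ll <- ll + sum(up[het_idx] *
                       log(2 * p[het_idx[, 1L]] * p[het_idx[, 2L]]))
    }
    ll <- ll + sum(ifelse(hom > 0, hom * log(p^2 + 2 * p * pn), 0))
    if (nb > 0) ll <- ll + nb * log(pn^2)
    ll
  }
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    ## E-step: expected gamete counts
    cnt <- numeric(k); cnull <- 0
    if (nrow(het_idx)) {
      for (r in seq_len(nrow(het_idx))) {
        i <- het_idx[r, 1L]; j <- het_idx[r, 2L]
        cnt[i] <- cnt[i] + up[i, j]
        cnt[j] <- cnt[j] + up[i, j]
      }
    }
    for (i in seq_len(k)) {
      if (hom[i] == 0) next
      w_true <- p[i] / (p[i] + 2 * pn)       # P(true hom | obs hom)
      cnt[i] <- cnt[i] + hom[i] * (2 * w_true + 1 * (1 - w_true))
      cnull <- cnull + hom[i] * (1 - w_true)
    }
    cnull <- cnull + 2 * nb
    tot <- sum(cnt) + cnull
    p <- cnt / tot
    pn <- cnull / tot
    trace <- c(trace, loglik(p, pn))
    if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol) break
  }
  ## boundary detection: EM approaches a zero null frequency only
  ## sublinearly, so snap to the boundary when it fits at least as well
  if (pn < 0.05 && pn > 0) {
    p0 <- p / (1 - pn)
    ll0 <- loglik(p0, 0)
    if (is.finite(ll0) && ll0 >= trace[length(trace)] - 1e-8) {
      p <- p0; pn <- 0
      if (ll0 >= trace[length(trace)]) trace <- c(trace, ll0)
    }
  }
  names(p) <- labels
  list(p_visible = p, null_freq = unname(pn), loglik_trace = trace,
       n_iter = length(trace), converged = it < max_iter)
}

#' Expected number of blank genotypes under the random-null model
#'
#' With null frequency `r`, a null/null genotype (complete amplification
#' failure) has probability `r^2`, so `n r^2` blanks are expected among
#' `n` individuals.
#'
#' @param null_freq Null-allele frequency in [0, 1].
#' @param n Number of individuals.
#' @return Expected blank count.
#' @export
expected_blank_count <- function(null_freq, n) {
  stopifnot(null_freq >= 0, null_freq <= 1, n >= 0)
  n * null_freq^2
}

#' Estimate null alleles for every (population, locus) cell
#'
#' Runs the moment estimators and the EM at every cell and flags loci with
#' a one-sided homozygote-excess signal (exact HWE p below `flag_alpha`
#' together with observed heterozygosity below expected).
#'
#' @param ds A `genotype_dataset`.
#' @param include_blanks Passed to [estimate_null_em()].
#' @param flag_alpha Detection threshold (default 0.05).
#' @param steps,dememorization,seed Markov-chain settings for the
#'   flagging test.
#' @return A `null_estimates` object: data frame with columns
#'   `population, locus, n_typed, n_blank, ho, he, r_chakraborty,
#'   r_brookfield1, r_em, expected_blanks, flagged`.
#' @export
estimate_null_all <- function(ds, include_blanks = TRUE, flag_alpha = 0.05,
                              steps = 2000L, dememorization = 2000L,
                              seed = 1L) {
  summ <- locus_summary(ds, hwe = "mc", steps = steps,
                        dememorization = dememorization, seed = seed)
  rows <- lapply(seq_len(nrow(summ)), function(i) {
    pp <- summ$population[i]; lc <- summ$locus[i]
    gc <- genotype_counts(ds, pp, lc)
    if (gc$n == 0L) {
      em <- list(null_freq = NA_real_)
      rc <- rb <- NA_real_
    } else {
      em <- estimate_null_em(gc, include_blanks = include_blanks)
      rc <- estimate_null_moment(summ$ho[i], summ$he[i], "chakraborty")
      rb <- estimate_null_moment(summ$ho[i], summ$he[i], "brookfield1")
    }
    flag <- !is.na(summ$hwe_p[i]) && summ$hwe_p[i] < flag_alpha &&
      !is.na(summ$ho[i]) && summ$ho[i] < summ$he[i]
    data.frame(population = pp, locus = lc, n_typed = summ$n_typed[i],
               n_blank = summ$n_blank[i], ho = summ$ho[i], he = summ$he[i],
               r_chakraborty = rc, r_brookfield1 = rb,
               r_em = em$null_freq,
               expected_blanks = if (is.na(em$null_freq)) NA_real_ else
                 expected_blank_count(em$null_freq,
                                      summ$n_typed[i] + summ$n_blank[i]),
               flagged = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("null_estimates", class(out))
  out
}

#' Null-allele correction of a genotype dataset
#'
#' For each flagged (population, locus) cell the expected excess of
#' observed homozygotes implied by the EM fit is re-labelled as
#' visible/null heterozygotes `(i, null_sentinel())`, deterministically:
#' integer re-label counts per allele class are apportioned
#' largest-residual-first (ties by allele order) and applied to the first
#' individuals in input order. Unflagged cells are untouched; allele sets
#' never change and the genotype count is conserved. The result is the
#' "corrected dataset" consumed by the with/without-correction
#' comparisons downstream.
#'
#' @param ds A `genotype_dataset`.
#' @param estimates A `null_estimates` table from [estimate_null_all()].
#' @return A corrected `genotype_dataset`.
#' @export
adjust_genotypes <- function(ds, estimates) {
  a1 <- ds$allele1; a2 <- ds$allele2
  flagged <- estimates[estimates$flagged & !is.na(estimates$r_em) &
                         estimates$r_em > 0, , drop = FALSE]
  for (i in seq_len(nrow(flagged))) {
    pp <- flagged$population[i]; lc <- flagged$locus[i]
    r <- flagged$r_em[i]
    idx <- which(ds$populations == pp)
    g1 <- a1[idx, lc]; g2 <- a2[idx, lc]
    hom <- !is.na(g1) & g1 == g2 & g1 != .NULL_SENTINEL
    if (!any(hom)) next
    gc <- genotype_counts(ds, pp, lc)
    em <- estimate_null_em(gc)
    p <- em$p_visible
    hom_alleles <- unique(g1[hom])
    expect <- vapply(hom_alleles, function(a) {
      pa <- p[as.character(a)]
      if (is.na(pa) || (pa + 2 * r) <= 0) return(0)
      sum(g1[hom] == a) * (2 * r / (pa + 2 * r))  # E[# (a,null) | obs homs]
    }, numeric(1))
    total <- round(sum(expect))
    base <- floor(expect)
    resid <- expect - base
    extra <- total - sum(base)
    if (extra > 0) {
      ord <- order(-resid, hom_alleles)  # largest residual first, ties by allele
      base[ord[seq_len(min(extra, length(ord)))]] <-
        base[ord[seq_len(min(extra, length(ord)))]] + 1
    }
    for (ai in seq_along(hom_alleles)) {
      a <- hom_alleles[ai]
      avail <- which(hom & g1 == a)
      k <- min(base[ai], length(avail))  # cap at homozygotes present
      if (k < base[ai])
        warning("null correction capped at available homozygotes (",
                pp, ", ", lc, ", allele ", a, ")")
      if (k > 0) {
        sel <- avail[seq_len(k)]         # first-in-order: deterministic
        g2[sel] <- .NULL_SENTINEL
      }
    }
    a1[idx, lc] <- g1; a2[idx, lc] <- g2
  }
  genotype_dataset(ds$individuals, ds$populations, ds$loci, a1, a2)
}
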