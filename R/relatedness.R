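## Maximum-likelihood dyadic relatedness from co-dominant genotypes.
##
## The model is the classic IBD k-coefficient mixture: a dyad shares 0, 1
## or 2 alleles identical by descent with probabilities (k0, k1, k2), and
## the joint probability of two single-locus genotypes is
##   P(g1, g2 | k) = k0 P(g1)P(g2) + k1 P(g1)T1(g2|g1) + k2 P(g1)T2(g2|g1)
## with T1/T2 the one- and two-gene transition probabilities. Relatedness
## r = k2 + k1/2. Canonical relationships sit at fixed k points:
## UR = (1,0,0), HS = (1/2,1/2,0), FS = (1/4,1/2,1/4), PO = (0,1,0).

.K_CANON <- list(UR = c(1, 0, 0), HS = c(0.5, 0.5, 0),
                 FS = c(0.25, 0.5, 0.25), PO = c(0, 1, 0))
## tie-break priority: least related first (conservative)
.CAT_PRIORITY <- c("UR", "HS", "FS", "PO")

#' Canonical IBD k-vector of a relationship category
#'
#' @param category One of `"UR"`, `"HS"`, `"FS"`, `"PO"`.
#' @return Numeric `(k0, k1, k2)`.
#' @export
canonical_k <- function(category) {
  if (!category %in% names(.K_CANON)) stop("unknown category: ", category)
  .K_CANON[[category]]
}

#' Relatedness coefficient from a k-vector
#'
#' @param k Numeric `(k0, k1, k2)` summing to 1.
#' @return `r = k2 + k1 / 2`.
#' @export
relatedness_r <- function(k) {
  if (any(k < -1e-9) || abs(sum(k) - 1) > 1e-9)
    stop("k must be non-negative and sum to 1")
  k[3] + k[2] / 2
}

## internal allele-frequency lookup: label 0 encodes the null allele
.freq_of <- function(a, p, pn) ifelse(a == 0L, pn, unname(p[as.character(a)]))

## P(unordered genotype (a,b)) under the frequency vector
.geno_prob <- function(a, b, p, pn) {
  fa <- .freq_of(a, p, pn); fb <- .freq_of(b, p, pn)
  if (a == b) fa * fb else 2 * fa * fb
}

## one-gene transition: P(g2 = (c,d) | one gene IBD with a random gene of g1)
.t1 <- function(a, b, c, d, p, pn) {
  K <- function(x) {  # P((c,d) | one gene is an IBD copy of x)
    if (c == d) {
      if (c == x) .freq_of(c, p, pn) else 0
    } else {
      (if (c == x) .freq_of(d, p, pn) else 0) +
      (if (d == x) .freq_of(c, p, pn) else 0)
    }
  }
  (K(a) + K(b)) / 2
}

## two-gene transition: g2 is an IBD copy of g1
.t2 <- function(a, b, c, d) as.numeric((a == c && b == d) || (a == d && b == c))

## compatible true genotypes for an observed genotype under the null model;
## rows of a 2-column matrix (0 = null allele)
.expand_obs <- function(g, pn) {
  if (is.na(g[1L])) {
    if (pn > 0) return(matrix(c(0L, 0L), 1L)) else return(NULL)  # blank
  }
  if (g[2L] == .NULL_SENTINEL) return(matrix(c(g[1L], 0L), 1L))
  if (g[1L] == g[2L] && pn > 0)
    return(rbind(c(g[1L], g[1L]), c(g[1L], 0L)))
  matrix(g, 1L)
}

## per-locus mixture coefficients (C0, C1, C2) for an observed dyad, summed
## over compatible true genotype pairs; NULL when the locus is uninformative
## for this dyad (missing data without a null model)
dyad_locus_coefs <- function(g1, g2, p, pn = 0) {
  e1 <- .expand_obs(g1, pn); e2 <- .expand_obs(g2, pn)
  if (is.null(e1) || is.null(e2)) return(NULL)
  C <- c(0, 0, 0)
  for (i in seq_len(nrow(e1))) for (j in seq_len(nrow(e2))) {
    a <- e1[i, 1L]; b <- e1[i, 2L]; cc <- e2[j, 1L]; d <- e2[j, 2L]
    p1 <- .geno_prob(a, b, p, pn)
    C[1] <- C[1] + p1 * .geno_prob(cc, d, p, pn)
    C[2] <- C[2] + p1 * .t1(a, b, cc, d, p, pn)
    C[3] <- C[3] + p1 * .t2(a, b, cc, d)
  }
  C
}

#' Single-locus dyad likelihood
#'
#' `P(g1, g2 | k)` for one locus. With a positive null frequency, observed
#' homozygotes are expanded over `{(i,i), (i,null)}` and blanks over
#' `{(null,null)}`, weighted by their frequencies.
#'
#' @param g1,g2 Length-2 integer genotypes (`NA, NA` = blank; the second
#'   slot may carry [null_sentinel()]).
#' @param p Named numeric vector of visible allele frequencies.
#' @param null_freq Null-allele frequency (default 0); `p` plus
#'   `null_freq` must sum to 1.
#' @param k Numeric `(k0, k1, k2)`, non-negative, summing to 1.
#' @return The joint probability.
#' @export
dyad_locus_likelihood <- function(g1, g2, p, null_freq = 0, k) {
  if (any(k < -1e-9) || abs(sum(k) - 1) > 1e-9)
    stop("k must be non-negative and sum to 1")
  if (abs(sum(p) + null_freq - 1) > 1e-6)
    stop("frequencies (visible + null) must sum to 1")
  obs <- c(g1[!is.na(g1)], g2[!is.na(g2)])
  obs <- obs[obs != .NULL_SENTINEL]
  if (length(obs) && !all(as.character(obs) %in% names(p)))
    stop("genotype carries an allele absent from the frequency vector")
  C <- dyad_locus_coefs(g1, g2, p, null_freq)
  if (is.null(C)) return(1)
  sum(k * C)
}

## grid + refinement maximizer of sum_l log(k %*% C_l) over the k simplex
.ml_k <- function(coefs) {
  ## coefs: L x 3 matrix
  obj <- function(K) {  # K: m x 3
    lik <- K %*% t(coefs)          # m x L
    lik[lik < 1e-300] <- 1e-300
    rowSums(log(lik))
  }
  grid_simplex <- function(center, half, step) {
    k0 <- seq(max(0, center[1] - half), min(1, center[1] + half), by = step)
    k1 <- seq(max(0, center[2] - half), min(1, center[2] + half), by = step)
    g <- expand.grid(k0 = k0, k1 = k1)
    g <- g[g$k0 + g$k1 <= 1 + 1e-12, ]
    cbind(g$k0, g$k1, pmax(0, 1 - g$k0 - g$k1))
  }
  K <- grid_simplex(c(0.5, 0.5, 0), 1, 0.05)
  best <- K[which.max(obj(K)), ]
  step <- 0.05
  for (it in 1:3) {
    step <- step / 5
    K <- grid_simplex(best[1:2], step * 6, step)
    best <- K[which.max(obj(K)), ]
  }
  best / sum(best)
}

## count of loci informative for dyad ML: both genotypes present (or null-
## modelled) and locus polymorphic
.informative <- function(coefs_list, poly) {
  sum(vapply(seq_along(coefs_list),
             function(l) !is.null(coefs_list[[l]]) && poly[l], logical(1)))
}

#' Classify one dyad by maximum likelihood
#'
#' Multiplies single-locus dyad likelihoods across loci (in the log
#' domain), ranks the enabled relationship categories by likelihood, and
#' maximizes the likelihood over the k simplex (grid refinement to below
#' 1e-3, then normalization) to obtain the ML k-vector and relatedness r.
#' At exact likelihood ties the least-related category wins
#' (UR before HS before FS before PO).
#'
#' @param ds A `genotype_dataset`.
#' @param id1,id2 Individual identifiers.
#' @param freqs An `allele_freq_table`; default: frequencies of the
#'   population containing the dyad (pooled over the two populations for a
#'   cross-population pair).
#' @param null_freqs Optional named-by-locus null frequencies to
#'   accommodate (e.g. EM estimates); `NULL` disables the null model.
#' @param categories Enabled categories (default UR/HS/FS; PO available).
#' @param min_informative Minimum informative loci for reporting r
#'   (default 5; below it `r` is `NA` and the dyad is flagged).
#' @return A one-row data frame (see [dyad_relationships()]).
#' @export
ml_relationship <- function(ds, id1, id2, freqs = NULL, null_freqs = NULL,
                            categories = c("UR", "HS", "FS"),
                            min_informative = 5L) {
  i <- match(id1, ds$individuals); j <- match(id2, ds$individuals)
  if (is.na(i) || is.na(j)) stop("unknown individual id")
  if (is.null(freqs)) {
    af <- allele_frequencies(ds)
    pops <- unique(c(ds$populations[i], ds$populations[j]))
    freqs <- if (length(pops) == 1L) af[pops] else pool_frequencies(af, pops)
  }
  fcell <- freqs[[1L]]
  row <- .classify_dyad(ds, i, j, fcell, null_freqs, categories,
                        min_informative)
  row
}

.classify_dyad <- function(ds, i, j, fcell, null_freqs, categories,
                           min_informative) {
  loci <- ds$loci
  coefs_list <- vector("list", length(loci))
  poly <- logical(length(loci))
  for (l in seq_along(loci)) {
    lc <- loci[l]
    ent <- fcell[[lc]]
    if (is.null(ent)) next
    pn <- if (!is.null(null_freqs)) unname(null_freqs[lc]) else ent$null
    if (is.na(pn)) pn <- 0
    p <- ent$p
    if (pn > 0 && abs(sum(p) + pn - 1) > 1e-6) p <- p * (1 - pn) / sum(p)
    g1 <- c(ds$allele1[i, lc], ds$allele2[i, lc])
    g2 <- c(ds$allele1[j, lc], ds$allele2[j, lc])
    coefs_list[[l]] <- dyad_locus_coefs(g1, g2, p, pn)
    poly[l] <- length(p) > 1L
  }
  used <- !vapply(coefs_list, is.null, logical(1))
  if (!any(used)) {
    return(data.frame(id1 = ds$individuals[i], id2 = ds$individuals[j],
                      pop1 = ds$populations[i], pop2 = ds$populations[j],
                      category = NA_character_, confidence = NA_real_,
                      k0 = NA_real_, k1 = NA_real_, k2 = NA_real_,
                      r = NA_real_, n_loci = 0L, n_informative = 0L,
                      unclassifiable = TRUE,
                      loglik_UR = NA_real_, loglik_HS = NA_real_,
                      loglik_FS = NA_real_, loglik_PO = NA_real_,
                      stringsAsFactors = FALSE))
  }
  coefs <- do.call(rbind, coefs_list[used])
  ll <- vapply(.CAT_PRIORITY, function(cat) {
    if (!cat %in% categories) return(NA_real_)
    lik <- coefs %*% .K_CANON[[cat]]
    lik[lik < 1e-300] <- 1e-300
    sum(log(lik))
  }, numeric(1))
  enabled <- .CAT_PRIORITY[.CAT_PRIORITY %in% categories]
  llv <- ll[enabled]
  best <- enabled[which(llv >= max(llv) - 1e-9)][1L]  # priority tie-break
  conf <- {
    w <- exp(llv - max(llv))
    unname(w[best] / sum(w))
  }
  n_inf <- .informative(coefs_list, poly)
  kml <- .ml_k(coefs)
  r <- if (n_inf >= min_informative) relatedness_r(kml) else NA_real_
  data.frame(id1 = ds$individuals[i], id2 = ds$individuals[j],
             pop1 = ds$populations[i], pop2 = ds$populations[j],
             category = best, confidence = conf,
             k0 = kml[1], k1 = kml[2], k2 = kml[3], r = r,
             n_loci = sum(used), n_informative = n_inf,
             unclassifiable = FALSE,
             loglik_UR = unname(ll["UR"]), loglik_HS = unname(ll["HS"]),
             loglik_FS = unname(ll["FS"]), loglik_PO = unname(ll["PO"]),
             stringsAsFactors = FALSE)
}

#' Classify many dyads
#'
#' Runs [ml_relationship()] over all within-population pairs (default) or
#' over every pair in the dataset. Within-population dyads use their own
#' sample's allele frequencies (standard convention); cross-population
#' dyads (and all dyads when `freq_scope = "pooled"`) use frequencies
#' pooled over the whole dataset.
#'
#' @param ds A `genotype_dataset`.
#' @param pairs `"within"` (default) or `"all"`.
#' @param freq_scope `"population"` (default) or `"pooled"`.
#' @param with_nulls Accommodate null alleles using per-cell EM estimates
#'   (computed via [estimate_null_all()] unless `null_estimates` given).
#' @param null_estimates Optional precomputed `null_estimates`.
#' @param categories,min_informative See [ml_relationship()].
#' @param estimate_k Estimate the ML k-vector and r (default TRUE; FALSE
#'   skips the simplex search and is faster when only the classification
#'   is needed).
#' @return Data frame, one row per dyad.
#' @export
dyad_relationships <- function(ds, pairs = c("within", "all"),
                               freq_scope = c("population", "pooled"),
                               with_nulls = FALSE, null_estimates = NULL,
                               categories = c("UR", "HS", "FS"),
                               min_informative = 5L, estimate_k = TRUE) {
  pairs <- match.arg(pairs)
  freq_scope <- match.arg(freq_scope)
  af <- allele_frequencies(ds)
  pooled <- pool_frequencies(af)
  if (with_nulls && is.null(null_estimates))
    null_estimates <- estimate_null_all(ds)
  null_of <- function(pp) {
    if (!with_nulls) return(NULL)
    sub <- null_estimates[null_estimates$population == pp, ]
    if (!nrow(sub)) {  # pooled scope: average EM estimates across samples
      agg <- tapply(null_estimates$r_em, null_estimates$locus, mean,
                    na.rm = TRUE)
      return(setNames(as.numeric(agg[ds$loci]), ds$loci))
    }
    setNames(sub$r_em[match(ds$loci, sub$locus)], ds$loci)
  }
  n <- length(ds$individuals)
  pr <- combn(n, 2L)
  keep <- rep(TRUE, ncol(pr))
  if (pairs == "within")
    keep <- ds$populations[pr[1L, ]] == ds$populations[pr[2L, ]]
  pr <- pr[, keep, drop = FALSE]
  rows <- vector("list", ncol(pr))
  for (cidx in seq_len(ncol(pr))) {
    i <- pr[1L, cidx]; j <- pr[2L, cidx]
    same <- ds$populations[i] == ds$populations[j]
    use_pop <- same && freq_scope == "population"
    fcell <- if (use_pop) af[[ds$populations[i]]] else pooled[[1L]]
    nf <- null_of(if (use_pop) ds$populations[i] else "__pooled__")
    rows[[cidx]] <- .classify_dyad2(ds, i, j, fcell, nf, categories,
                                    min_informative, estimate_k)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## classify with optional k estimation (shared core)
.classify_dyad2 <- function(ds, i, j, fcell, null_freqs, categories,
                            min_informative, estimate_k) {
  out <- .classify_dyad_core(ds, i, j, fcell, null_freqs, categories,
                             min_informative, estimate_k)
  out
}

.classify_dyad_core <- function(ds, i, j, fcell, null_freqs, categories,
                                min_informative, estimate_k) {
  if (estimate_k)
    return(.classify_dyad(ds, i, j, fcell, null_freqs, categories,
                          min_informative))
  ## classification-only fast path
  loci <- ds$loci
  coefs_list <- vector("list", length(loci))
  poly <- logical(length(loci))
  for (l in seq_along(loci)) {
    lc <- loci[l]
    ent <- fcell[[lc]]
    if (is.null(ent)) next
    pn <- if (!is.null(null_freqs)) unname(null_freqs[lc]) else ent$null
    if (is.na(pn)) pn <- 0
    p <- ent$p
    if (pn > 0 && abs(sum(p) + pn - 1) > 1e-6) p <- p * (1 - pn) / sum(p)
    g1 <- c(ds$allele1[i, lc], ds$allele2[i, lc])
    g2 <- c(ds$allele1[j, lc], ds$allele2[j, lc])
    coefs_list[[l]] <- dyad_locus_coefs(g1, g2, p, pn)
    poly[l] <- length(p) > 1L
  }
  used <- !vapply(coefs_list, is.null, logical(1))
  if (!any(used)) {
    return(data.frame(id1 = ds$individuals[i], id2 = ds$individuals[j],
                      pop1 = ds$populations[i], pop2 = ds$populations[j],
                      category = NA_character_, confidence = NA_real_,
                      k0 = NA_real_, k1 = NA_real_, k2 = NA_real_,
                      r = NA_real_, n_loci = 0L, n_informative = 0L,
                      unclassifiable = TRUE,
                      loglik_UR = NA_real_, loglik_HS = NA_real_,
                      loglik_FS = NA_real_, loglik_PO = NA_real_,
                      stringsAsFactors = FALSE))
  }
  coefs <- do.call(rbind, coefs_list[used])
  ll <- vapply(.CAT_PRIORITY, function(cat) {
    if (!cat %in% categories) return(NA_real_)
    lik <- coefs %*% .K_CANON[[cat]]
    lik[lik < 1e-300] <- 1e-300
    sum(log(lik))
  }, numeric(1))
  enabled <- .CAT_PRIORITY[.CAT_PRIORITY %in% categories]
  llv <- ll[enabled]
  best <- enabled[which(llv >= max(llv) - 1e-9)][1L]
  w <- exp(llv - max(llv))
  data.frame(id1 = ds$individuals[i], id2 = ds$individuals[j],
             pop1 = ds$populations[i], pop2 = ds$populations[j],
             category = best, confidence = unname(w[best] / sum(w)),
             k0 = NA_real_, k1 = NA_real_, k2 = NA_real_, r = NA_real_,
             n_loci = sum(used), n_informative = .informative(coefs_list, poly),
             unclassifiable = FALSE,
             loglik_UR = unname(ll["UR"]), loglik_HS = unname(ll["HS"]),
             loglik_FS = unname(ll["FS"]), loglik_PO = unname(ll["PO"]),
             stringsAsFactors = FALSE)
}

#' Within-sample half-sib and full-sib dyad frequencies
#'
#' Frequency of dyads classified HS (resp. FS) among all `n(n-1)/2` pairs
#' of each population sample, computed from the raw dataset and, when
#' `compare_nulls = TRUE`, also with null-allele accommodation — the
#' four-column layout used for with/without-correction comparisons.
#'
#' @param ds A `genotype_dataset`.
#' @param compare_nulls Compute both modes (default TRUE).
#' @param null_estimates Optional precomputed `null_estimates`.
#' @param ... Passed to [dyad_relationships()].
#' @return Data frame with columns `population, n, hs_nna, fs_nna` and,
#'   with `compare_nulls`, `hs_na, fs_na`.
#' @export
dyad_frequency_table <- function(ds, compare_nulls = TRUE,
                                 null_estimates = NULL, ...) {
  pops <- unique(ds$populations)
  sizes <- population_sizes(ds)
  count_mode <- function(with_nulls) {
    dy <- dyad_relationships(ds, pairs = "within", with_nulls = with_nulls,
                             null_estimates = null_estimates,
                             estimate_k = FALSE, ...)
    t(vapply(pops, function(pp) {
      sub <- dy[dy$pop1 == pp, ]
      denom <- pair_count(max(2L, sizes[[pp]]))
      c(hs = sum(sub$category == "HS", na.rm = TRUE) / denom,
        fs = sum(sub$category == "FS", na.rm = TRUE) / denom)
    }, numeric(2)))
  }
  raw <- count_mode(FALSE)
  out <- data.frame(population = pops, n = as.integer(sizes[pops]),
                    hs_nna = raw[, "hs"], fs_nna = raw[, "fs"],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (compare_nulls) {
    if (is.null(null_estimates)) null_estimates <- estimate_null_all(ds)
    cor <- count_mode(TRUE)
    out$hs_na <- cor[, "hs"]; out$fs_na <- cor[, "fs"]
  }
  out
}
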