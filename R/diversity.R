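#' Per-locus diversity summary
#'
#' For every (population, locus) cell: number of alleles, observed
#' heterozygosity (fraction of heterozygous non-blank genotypes), unbiased
#' expected heterozygosity `(2n/(2n-1)) (1 - sum p_i^2)` with `n` the typed
#' count, and (optionally) a Hardy-Weinberg exact-test p-value. Blank-only
#' cells are reported with `NA` entries (flagged absent).
#'
#' @param ds A `genotype_dataset`.
#' @param hwe `"mc"` (Markov-chain exact test, default), `"enumeration"`,
#'   or `"none"`.
#' @param steps,dememorization Markov-chain settings (defaults 1000 and
#'   10000).
#' @param seed Seed for the Markov chain.
#' @return Data frame with columns `population, locus, n_typed, n_blank,
#'   n_alleles, ho, he, hwe_p`.
#' @export
locus_summary <- function(ds, hwe = c("mc", "enumeration", "none"),
                          steps = 1000L, dememorization = 10000L, seed = 1L) {
  hwe <- match.arg(hwe)
  pops <- unique(ds$populations)
  rows <- list()
  for (pp in pops) for (lc in ds$loci) {
    gc <- genotype_counts(ds, pp, lc)
    if (gc$n == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        population = pp, locus = lc, n_typed = 0L, n_blank = gc$n_blank,
        n_alleles = NA_integer_, ho = NA_real_, he = NA_real_,
        hwe_p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    het <- sum(gc$counts) - sum(diag(gc$counts))
    ho <- het / gc$n
    p <- allele_freq_from_counts(gc)
    he <- (2 * gc$n / (2 * gc$n - 1)) * (1 - sum(p^2))
    pval <- switch(hwe,
      none = NA_real_,
      enumeration = hwe_exact_enumeration(gc$counts),
      mc = hwe_exact_mc(gc$counts, steps = steps,
                        dememorization = dememorization, seed = seed))
    rows[[length(rows) + 1L]] <- data.frame(
      population = pp, locus = lc, n_typed = gc$n, n_blank = gc$n_blank,
      n_alleles = length(gc$alleles), ho = ho, he = he, hwe_p = pval,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

allele_freq_from_counts <- function(gc) {
  ## row+col sums count each diagonal cell twice and each het cell once per
  ## constituent allele, i.e. exactly the gamete counts
  cnt <- rowSums(gc$counts) + colSums(gc$counts)
  setNames(cnt / (2 * gc$n), gc$alleles)
}

## normalize genotype-count input: accept the list from genotype_counts()
## or a square matrix of counts (any triangle); returns upper-triangle k x k
## integer matrix plus allele counts.
as_genotype_table <- function(x) {
  cnt <- if (is.list(x) && !is.null(x$counts)) x$counts else as.matrix(x)
  k <- nrow(cnt)
  up <- matrix(0L, k, k, dimnames = dimnames(cnt))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i <= j) up[i, j] <- up[i, j] + cnt[i, j]
    else up[j, i] <- up[j, i] + cnt[i, j]
  }
  m <- rowSums(up) + colSums(up)  # diagonal counted twice = 2 homozygote gametes
  list(counts = up, allele_counts = as.integer(m), n = sum(up))
}

## log conditional probability of a genotype table given allele counts:
## log[ n! 2^h prod(m_a!) / ((2n)! prod(n_gg!)) ]
log_table_prob <- function(up, allele_counts) {
  n <- sum(up)
  h <- sum(up) - sum(diag(up))
  lfactorial(n) + h * log(2) + sum(lfactorial(allele_counts)) -
    lfactorial(2 * n) - sum(lfactorial(up[upper.tri(up, diag = TRUE)]))
}

#' Hardy-Weinberg exact test by full enumeration
#'
#' Enumerates every genotype table compatible with the observed allele
#' counts; the conditional probability of a table is
#' `n! 2^h prod(m_a!) / ((2n)! prod(n_gg!))`. The p-value is the total
#' probability of tables no more probable than the observed one (Fisher
#' criterion, ties included). Feasible for small allele totals; serves as
#' the exact oracle for the Markov-chain test.
#'
#' @param counts Genotype counts: a square matrix (either triangle) or the
#'   list returned by the internal counter.
#' @return p-value in (0, 1]. Monomorphic data give 1 by convention.
#' @export
hwe_exact_enumeration <- function(counts) {
  gt <- as_genotype_table(counts)
  k <- nrow(gt$counts)
  if (k <= 1L) return(1)
  m <- gt$allele_counts
  n <- gt$n
  obs_lp <- log_table_prob(gt$counts, m)
  ## enumerate tables cell by cell in row-major upper-triangle order
  cells <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
  total <- 0; tail_p <- 0
  tab <- matrix(0L, k, k)
  recurse <- function(ci, rem) {
    if (ci > nrow(cells)) {
      if (any(rem != 0L)) return()
      lp <- log_table_prob(tab, m)
      pr <- exp(lp)
      total <<- total + pr
      if (lp <= obs_lp + 1e-9) tail_p <<- tail_p + pr
      return()
    }
    i <- cells[ci, 1L]; j <- cells[ci, 2L]
    cap <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (v in 0:cap) {
      tab[i, j] <<- v
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2L * v
      else { rem2[i] <- rem2[i] - v; rem2[j] <- rem2[j] - v }
      ## feasibility: allele k's remaining copies can only pair with
      ## remaining alleles; cheap prune: none negative
      if (all(rem2 >= 0L)) recurse(ci + 1L, rem2)
    }
    tab[i, j] <<- 0L
  }
  recurse(1L, m)
  if (total <= 0) return(1)
  min(1, tail_p / total)  # normalize guards rounding
}

#' Hardy-Weinberg exact test by Markov chain
#'
#' A random-transposition chain over the vector of 2n gametes: two allele
#' copies chosen uniformly are swapped between genotypes each step. The
#' chain's stationary distribution is uniform over gamete arrangements,
#' which induces exactly the conditional table distribution used by
#' [hwe_exact_enumeration()]. After the dememorization burn-in, the p-value
#' is the proportion of visited tables no more probable than the observed
#' one.
#'
#' @param counts Genotype counts (square matrix, either triangle).
#' @param steps Samples counted toward the p-value (default 1000).
#' @param dememorization Burn-in swap proposals (default 10000).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @param thin Swap proposals between recorded samples (default 1);
#'   thinning reduces chain autocorrelation so the Monte-Carlo standard
#'   error of the p-value approaches the independent-sample value.
#' @return p-value in (0, 1]. Monomorphic or single-table cases give 1.
#' @export
hwe_exact_mc <- function(counts, steps = 1000L, dememorization = 10000L,
                         seed = 1L, thin = 1L) {
  stopifnot(steps >= 1L)
  gt <- as_genotype_table(counts)
  k <- nrow(gt$counts)
  if (k <= 1L) return(1)
  m <- gt$allele_counts
  n <- gt$n
  if (n <= 1L) return(1)
  obs_lp <- log_table_prob(gt$counts, m)
  ## gamete vector: positions 1..2n, pair i occupies (2i-1, 2i)
  g <- integer(2L * n)
  pos <- 1L
  up <- gt$counts
  for (i in seq_len(k)) for (j in i:k) {
    cnt <- up[i, j]
    if (cnt > 0L) {
      idx <- seq.int(pos, length.out = 2L * cnt, by = 1L)
      g[idx] <- rep(c(i, j), cnt)
      pos <- pos + 2L * cnt
    }
  }
  tab <- up
  cur_lp <- obs_lp
  set.seed(as.integer(seed))
  hits <- 0L
  norm_pair <- function(a, b) if (a <= b) c(a, b) else c(b, a)
  total_steps <- dememorization + steps * thin
  for (s in seq_len(total_steps)) {
    pq <- sample.int(2L * n, 2L)
    p1 <- pq[1L]; p2 <- pq[2L]
    i1 <- (p1 + 1L) %/% 2L; i2 <- (p2 + 1L) %/% 2L
    if (i1 != i2 && g[p1] != g[p2]) {
      ## remove old genotypes, add swapped ones; update logP incrementally
      o1 <- norm_pair(g[2L * i1 - 1L], g[2L * i1])
      o2 <- norm_pair(g[2L * i2 - 1L], g[2L * i2])
      tmp <- g[p1]; g[p1] <- g[p2]; g[p2] <- tmp
      n1 <- norm_pair(g[2L * i1 - 1L], g[2L * i1])
      n2 <- norm_pair(g[2L * i2 - 1L], g[2L * i2])
      delta <- 0
      dec <- function(pr) {
        delta <<- delta + log(tab[pr[1L], pr[2L]]) -
          (if (pr[1L] != pr[2L]) log(2) else 0)
        tab[pr[1L], pr[2L]] <<- tab[pr[1L], pr[2L]] - 1L
      }
      inc <- function(pr) {
        tab[pr[1L], pr[2L]] <<- tab[pr[1L], pr[2L]] + 1L
        delta <<- delta - log(tab[pr[1L], pr[2L]]) +
          (if (pr[1L] != pr[2L]) log(2) else 0)
      }
      dec(o1); dec(o2); inc(n1); inc(n2)
      cur_lp <- cur_lp + delta
    }
    if (s > dememorization && (s - dememorization) %% thin == 0L &&
        cur_lp <= obs_lp + 1e-9) hits <- hits + 1L
  }
  hits / steps
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' Exact-style test of association between the genotypes at two loci within
#' one population. The statistic is the log-probability of the two-locus
#' genotypic contingency table under fixed margins (Fisher criterion); the
#' null distribution is realized by permuting one locus's genotypes among
#' the individuals typed at both loci. p-values use the add-one correction.
#'
#' @param ds A `genotype_dataset`.
#' @param locus_a,locus_b Locus names.
#' @param population Population label.
#' @param iterations Number of permutations (default 999).
#' @param seed Integer seed.
#' @return p-value in (0, 1]; 1 when either locus is monomorphic in the
#'   population or fewer than 2 individuals are typed at both.
#' @export
ld_genotypic_test <- function(ds, locus_a, locus_b, population,
                              iterations = 999L, seed = 1L) {
  idx <- which(ds$populations == population)
  ga <- paste(ds$allele1[idx, locus_a], ds$allele2[idx, locus_a])
  gb <- paste(ds$allele1[idx, locus_b], ds$allele2[idx, locus_b])
  ok <- !is.na(ds$allele1[idx, locus_a]) & !is.na(ds$allele1[idx, locus_b])
  ga <- factor(ga[ok]); gb <- factor(gb[ok])
  if (length(ga) < 2L || nlevels(droplevels(ga)) < 2L ||
      nlevels(droplevels(gb)) < 2L) return(1)
  log_ct_prob <- function(a, b) {
    tab <- table(a, b)
    sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
      lfactorial(sum(tab)) - sum(lfactorial(tab))
  }
  obs <- log_ct_prob(ga, gb)
  set.seed(as.integer(seed))
  hits <- 0L
  for (it in seq_len(iterations)) {
    if (log_ct_prob(ga, sample(gb)) <= obs + 1e-9) hits <- hits + 1L
  }
  (hits + 1) / (iterations + 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param k Number of tests (>= 1).
#' @return `alpha / k`.
#' @examples
#' bonferroni_threshold(0.05, 28)  # 0.00179 for 28 pairwise sample tests
#' @export
bonferroni_threshold <- function(alpha, k) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (k < 1) stop("k must be >= 1")
  alpha / k
}

#' Fisher's combination of per-population HWE p-values
#'
#' Global per-locus Hardy-Weinberg assessment across population samples:
#' -2 sum log p ~ chi^2 with 2k degrees of freedom.
#'
#' @param p Vector of p-values (NA dropped).
#' @return Combined p-value.
#' @export
fisher_combine_p <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  p <- pmax(p, 1e-300)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

## ---- Weir-Cockerham variance components -------------------------------

## per-locus WC (1984) components. Returns per-allele a, b, c vectors.
## r = 1 populations: a is NA (undefined); b, c still defined.
wc_components_locus <- function(ds, locus, pops, exclude_alleles = integer(0)) {
  r <- length(pops)
  ni <- numeric(r)
  stats_pop <- vector("list", r)
  alleles <- sort(unique(c(ds$allele1[ds$populations %in% pops, locus],
                           ds$allele2[ds$populations %in% pops, locus])))
  alleles <- alleles[!is.na(alleles) & !(alleles %in% exclude_alleles)]
  if (length(alleles) < 1L) return(NULL)
  for (ii in seq_len(r)) {
    idx <- which(ds$populations == pops[ii])
    g1 <- ds$allele1[idx, locus]; g2 <- ds$allele2[idx, locus]
    ## genotypes carrying an excluded allele class (the null sentinel) are
    ## dropped per locus: the EM re-labelling removed the expected
    ## visible/null excess, so the retained genotypes emulate a clean
    ## Hardy-Weinberg sample at the conditional visible frequencies
    typed <- !is.na(g1) & !(g1 %in% exclude_alleles) &
      !(g2 %in% exclude_alleles)
    g1 <- g1[typed]; g2 <- g2[typed]
    ni[ii] <- length(g1)
    pA <- vapply(alleles, function(a) (sum(g1 == a) + sum(g2 == a)), numeric(1)) /
      max(1, 2 * length(g1))
    hA <- vapply(alleles, function(a) sum((g1 == a) != (g2 == a)), numeric(1)) /
      max(1, length(g1))
    stats_pop[[ii]] <- list(p = pA, h = hA)
  }
  keep <- ni >= 1
  if (sum(keep) < 1L) return(NULL)
  ni <- ni[keep]; stats_pop <- stats_pop[keep]; r <- sum(keep)
  nbar <- mean(ni)
  if (nbar <= 1) return(NULL)
  nc <- if (r > 1) (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1) else NA_real_
  P <- do.call(rbind, lapply(stats_pop, `[[`, "p"))  # r x k
  H <- do.call(rbind, lapply(stats_pop, `[[`, "h"))
  pbar <- colSums(ni * P) / (r * nbar)
  hbar <- colSums(ni * H) / (r * nbar)
  s2 <- if (r > 1) colSums(ni * sweep(P, 2, pbar)^2) / ((r - 1) * nbar)
        else rep(0, length(pbar))
  frac <- if (r > 1) (r - 1) / r else 0
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - frac * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a <- if (r > 1) (nbar / nc) *
         (s2 - (1 / (nbar - 1)) *
            (pbar * (1 - pbar) - frac * s2 - hbar / 4))
       else rep(NA_real_, length(pbar))
  list(alleles = alleles, a = a, b = b, c = cc)
}

#' Weir-Cockerham inbreeding coefficient (f)
#'
#' Locus-by-locus and overall f from the 1984 variance components (within-
#' individual vs among-individual-within-population); the overall value is
#' the ratio of summed components across alleles and loci, not a mean of
#' per-locus estimates. Significance by randomizing alleles among
#' individuals within samples; a 95% CI for the overall value by
#' bootstrapping loci.
#'
#' @param ds A `genotype_dataset`.
#' @param pops Populations to include; default all.
#' @param randomizations Allele randomizations for the p-value (0 skips).
#' @param n_boot Locus bootstrap replicates for the CI (0 skips; needs
#'   >= 2 loci).
#' @param seed Integer seed.
#' @return List with `per_locus` (data frame `locus, f`; `NA` means not
#'   evaluated, e.g. no variation), `overall`, `ci`, `p`.
#' @export
fis_weir_cockerham <- function(ds, pops = unique(ds$populations),
                               randomizations = 0L, n_boot = 0L, seed = 1L) {
  comp <- lapply(ds$loci, function(lc) wc_components_locus(ds, lc, pops))
  names(comp) <- ds$loci
  per_locus <- vapply(comp, function(cp) {
    if (is.null(cp)) return(NA_real_)
    den <- sum(cp$b + cp$c)
    if (!is.finite(den) || den <= 0) return(NA_real_)
    1 - sum(cp$c) / den
  }, numeric(1))
  bsum <- sum(vapply(comp, function(cp) if (is.null(cp)) 0 else sum(cp$b), numeric(1)))
  csum <- sum(vapply(comp, function(cp) if (is.null(cp)) 0 else sum(cp$c), numeric(1)))
  overall <- if ((bsum + csum) > 0) 1 - csum / (bsum + csum) else NA_real_

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L && length(ds$loci) >= 2L) {
    set.seed(as.integer(seed) + 1L)
    bs <- replicate(n_boot, {
      pick <- sample(ds$loci, replace = TRUE)
      bb <- sum(vapply(comp[pick], function(cp) if (is.null(cp)) 0 else sum(cp$b), numeric(1)))
      cc <- sum(vapply(comp[pick], function(cp) if (is.null(cp)) 0 else sum(cp$c), numeric(1)))
      if ((bb + cc) > 0) 1 - cc / (bb + cc) else NA_real_
    })
    ci <- quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }

  pval <- NA_real_
  if (randomizations > 0L) {
    set.seed(as.integer(seed))
    hits <- 0L
    for (b in seq_len(randomizations)) {
      perm <- ds
      for (pp in pops) {
        idx <- which(ds$populations == pp)
        for (lc in ds$loci) {
          al <- c(ds$allele1[idx, lc], ds$allele2[idx, lc])
          typed <- !is.na(al)
          al[typed] <- sample(al[typed])
          half <- length(idx)
          a1 <- al[seq_len(half)]; a2 <- al[half + seq_len(half)]
          ## realign so half-calls can't appear: permute among typed slots only
          perm$allele1[idx, lc] <- pmin(a1, a2)
          perm$allele2[idx, lc] <- pmax(a1, a2)
        }
      }
      compb <- lapply(ds$loci, function(lc) wc_components_locus(perm, lc, pops))
      bb <- sum(vapply(compb, function(cp) if (is.null(cp)) 0 else sum(cp$b), numeric(1)))
      cc <- sum(vapply(compb, function(cp) if (is.null(cp)) 0 else sum(cp$c), numeric(1)))
      fb <- if ((bb + cc) > 0) 1 - cc / (bb + cc) else NA_real_
      if (!is.na(fb) && fb >= overall - 1e-12) hits <- hits + 1L
    }
    pval <- (hits + 1) / (randomizations + 1)
  }

  list(per_locus = data.frame(locus = ds$loci, f = unname(per_locus),
                              stringsAsFactors = FALSE),
       overall = overall, ci = ci, p = pval)
}
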