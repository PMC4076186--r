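#' Construct a co-dominant genotype dataset
#'
#' The central container of patchkin: diploid genotypes (unordered pairs of
#' positive-integer allele labels, e.g. fragment sizes in base pairs) for a
#' set of individuals typed at a common panel of loci and grouped into
#' population samples. A completely failed amplification (blank) is stored
#' as `NA` in both allele slots; half-called genotypes are invalid.
#'
#' @param individuals Character vector of unique individual identifiers.
#' @param populations Character vector (or factor) of population labels,
#'   one per individual.
#' @param loci Character vector of locus names.
#' @param allele1,allele2 Integer matrices (individuals x loci) of allele
#'   labels; `NA` in both marks a blank. Pairs are unordered and stored
#'   sorted so that `allele1 <= allele2`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(individuals, populations, loci, allele1, allele2) {
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  dimnames(allele1) <- dimnames(allele2) <- list(individuals, loci)
  ## normalize unordered pairs (sentinel sorts last, which is what we want)
  swap <- !is.na(allele1) & !is.na(allele2) & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }
  ds <- structure(
    list(individuals = as.character(individuals),
         populations = as.character(populations),
         loci        = as.character(loci),
         allele1     = allele1,
         allele2     = allele2),
    class = "genotype_dataset")
  validate_genotype_dataset(ds)
  ds
}

#' Validate a genotype dataset
#'
#' Checks the container invariants: unique individual ids, one population
#' per individual, positive-integer allele labels (plus the reserved null
#' sentinel), and no half-called genotypes.
#'
#' @param ds A `genotype_dataset`.
#' @return `ds`, invisibly; errors on violation.
#' @export
validate_genotype_dataset <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n <- length(ds$individuals)
  if (n < 1L) stop("dataset must contain at least one individual")
  if (anyDuplicated(ds$individuals))
    stop("duplicate individual ids: ",
         paste(unique(ds$individuals[duplicated(ds$individuals)]), collapse = ", "))
  if (length(ds$populations) != n)
    stop("populations must map every individual to exactly one label")
  if (any(is.na(ds$populations)) || any(ds$populations == ""))
    stop("every individual needs a non-empty population label")
  for (m in list(ds$allele1, ds$allele2)) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != length(ds$loci))
      stop("allele matrices must be individuals x loci")
  }
  half <- xor(is.na(ds$allele1), is.na(ds$allele2))
  if (any(half))
    stop("half-called genotypes are not allowed (individual ",
         ds$individuals[which(half, arr.ind = TRUE)[1L, 1L]], ")")
  vals <- c(ds$allele1[!is.na(ds$allele1)], ds$allele2[!is.na(ds$allele2)])
  bad <- vals < 1L & vals != .NULL_SENTINEL
  if (any(bad)) stop("allele labels must be positive integers")
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$individuals), "individuals,",
      length(x$loci), "loci,",
      length(unique(x$populations)), "population sample(s)\n")
  tab <- table(factor(x$populations, levels = unique(x$populations)))
  cat("  samples:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                          collapse = ", "), "\n")
  blanks <- sum(is.na(x$allele1))
  cat("  blanks:", blanks, sprintf("(%.1f%% of genotypes)\n",
      100 * blanks / (length(x$individuals) * length(x$loci))))
  invisible(x)
}

#' Population sample sizes
#' @param ds A `genotype_dataset`.
#' @return Named integer vector of sample sizes, in input order.
#' @export
population_sizes <- function(ds) {
  tab <- table(factor(ds$populations, levels = unique(ds$populations)))
  setNames(as.integer(tab), names(tab))
}

#' Subset a genotype dataset
#'
#' @param ds A `genotype_dataset`.
#' @param individuals,populations,loci Optional selectors; `NULL` keeps all.
#' @return A `genotype_dataset`.
#' @export
subset_genotypes <- function(ds, individuals = NULL, populations = NULL,
                             loci = NULL) {
  keep <- rep(TRUE, length(ds$individuals))
  if (!is.null(populations)) keep <- keep & ds$populations %in% populations
  if (!is.null(individuals)) keep <- keep & ds$individuals %in% individuals
  lkeep <- if (is.null(loci)) ds$loci else intersect(ds$loci, loci)
  genotype_dataset(ds$individuals[keep], ds$populations[keep], lkeep,
                   ds$allele1[keep, lkeep, drop = FALSE],
                   ds$allele2[keep, lkeep, drop = FALSE])
}

#' Number of unordered pairs among n individuals
#'
#' Denominator of the dyad-frequency tables: the number of distinct dyads
#' that can be formed within a sample of size `n`, i.e. n(n-1)/2.
#'
#' @param n Positive integer (vectorized).
#' @return Non-negative integer(s).
#' @examples
#' pair_count(52)  # 1326
#' @export
pair_count <- function(n) {
  if (any(n < 1) || any(n != round(n))) stop("n must be a positive integer")
  as.integer(n * (n - 1) / 2)
}

#' Visible-allele frequencies per population and locus
#'
#' Counts alleles over non-blank genotypes. Gametes carrying the reserved
#' null sentinel (produced by [adjust_genotypes()]) are tallied into the
#' `null` frequency class rather than as a visible allele, so visible
#' frequencies plus the null frequency always sum to one.
#'
#' @param ds A `genotype_dataset`.
#' @return An `allele_freq_table`: a nested list `[[population]][[locus]]`
#'   with elements `p` (named numeric, visible allele frequencies),
#'   `null` (frequency mass on the null class, 0 for uncorrected data) and
#'   `n_typed` (non-blank genotype count). Blank-only cells are `NULL`
#'   (flagged absent).
#' @export
allele_frequencies <- function(ds) {
  pops <- unique(ds$populations)
  out <- lapply(pops, function(pp) {
    idx <- which(ds$populations == pp)
    cell <- lapply(ds$loci, function(lc) {
      a <- c(ds$allele1[idx, lc], ds$allele2[idx, lc])
      a <- a[!is.na(a)]
      if (length(a) == 0L) return(NULL)
      nullmass <- mean(a == .NULL_SENTINEL)
      vis <- a[a != .NULL_SENTINEL]
      p <- if (length(vis)) table(vis) / length(a) else table(integer(0))
      list(p = setNames(as.numeric(p), names(p)),
           null = nullmass,
           n_typed = length(a) / 2L)
    })
    setNames(cell, ds$loci)
  })
  structure(setNames(out, pops), class = "allele_freq_table")
}

#' Pool allele frequencies across population samples
#'
#' Gamete-weighted pooling of per-population frequency entries, used when a
#' single frequency vector is needed for dyads spanning two samples.
#'
#' @param freqs An `allele_freq_table`.
#' @param populations Populations to pool; default all.
#' @return An `allele_freq_table` with one population named `"pooled"`.
#' @export
pool_frequencies <- function(freqs, populations = names(freqs)) {
  loci <- names(freqs[[1L]])
  cell <- lapply(loci, function(lc) {
    ent <- lapply(populations, function(pp) freqs[[pp]][[lc]])
    ent <- ent[!vapply(ent, is.null, logical(1))]
    if (!length(ent)) return(NULL)
    w <- vapply(ent, function(e) 2 * e$n_typed, numeric(1))
    alleles <- sort(unique(unlist(lapply(ent, function(e) names(e$p)))))
    p <- setNames(numeric(length(alleles)), alleles)
    nullmass <- 0
    for (i in seq_along(ent)) {
      p[names(ent[[i]]$p)] <- p[names(ent[[i]]$p)] + w[i] * ent[[i]]$p
      nullmass <- nullmass + w[i] * ent[[i]]$null
    }
    tot <- sum(w)
    list(p = p / tot, null = nullmass / tot, n_typed = as.integer(tot / 2))
  })
  structure(setNames(list(setNames(cell, loci)), "pooled"),
            class = "allele_freq_table")
}

## ---- GenePop ----------------------------------------------------------

#' Read a GenePop file
#'
#' Standard GenePop layout: a title line, one locus name per line (or a
#' single comma-separated line), `POP` separators, then one individual per
#' line as `id , g1 g2 ...` with each genotype coded in `2 * allele_digits`
#' characters. All-zero codes decode to blank; codes with exactly one zero
#' half (half-calls) are rejected.
#'
#' @param path_or_text Path to a file, or the file contents as a single
#'   string containing newlines.
#' @param allele_digits 2 or 3 (default) digits per allele.
#' @return A `genotype_dataset`; populations are named `pop1`, `pop2`, ...
#'   in file order, or by the id of their last individual when
#'   `pop_names = "last_id"`.
#' @param pop_names `"index"` (default) or `"last_id"`.
#' @export
read_genepop <- function(path_or_text, allele_digits = 3, pop_names = "index") {
  allele_digits <- match.arg(as.character(allele_digits), c("2", "3"))
  w <- as.integer(allele_digits)
  lines <- if (grepl("\n", path_or_text)) strsplit(path_or_text, "\n")[[1]]
           else readLines(path_or_text)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 2L) stop("GenePop parse error: file too short")
  body <- lines[-1L]
  is_pop <- toupper(trimws(body)) == "POP"
  if (!any(is_pop)) stop("GenePop parse error: no POP separator found")
  first_pop <- which(is_pop)[1L]
  loci_lines <- trimws(body[seq_len(first_pop - 1L)])
  loci_lines <- loci_lines[loci_lines != ""]
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  loci <- loci[loci != ""]
  if (!length(loci)) stop("GenePop parse error: no loci declared")

  ids <- character(0); pops <- character(0)
  a1 <- NULL; a2 <- NULL
  pop_i <- 0L
  pop_of_line <- integer(0)
  for (i in seq(first_pop, length(body))) {
    ln <- body[i]
    if (toupper(trimws(ln)) == "POP") { pop_i <- pop_i + 1L; next }
    if (trimws(ln) == "") next
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L)
      stop("GenePop parse error at line ", i + 1L, ": missing ',' separator")
    id <- trimws(parts[1L])
    gstr <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "[ \t]+")[[1]]
    gstr <- gstr[gstr != ""]
    if (length(gstr) != length(loci))
      stop("GenePop parse error at line ", i + 1L, ": expected ",
           length(loci), " genotypes, found ", length(gstr))
    if (any(nchar(gstr) != 2L * w))
      stop("GenePop parse error at line ", i + 1L,
           ": genotype codes must be ", 2L * w, " characters wide")
    g1 <- as.integer(substr(gstr, 1L, w))
    g2 <- as.integer(substr(gstr, w + 1L, 2L * w))
    half <- xor(g1 == 0L, g2 == 0L)
    if (any(half))
      stop("GenePop parse error at line ", i + 1L,
           ": half-missing genotype code")
    blank <- g1 == 0L & g2 == 0L
    g1[blank] <- NA_integer_; g2[blank] <- NA_integer_
    ids <- c(ids, id)
    pop_of_line <- c(pop_of_line, pop_i)
    a1 <- rbind(a1, g1); a2 <- rbind(a2, g2)
  }
  if (!length(ids)) stop("GenePop parse error: no individuals")
  if (anyDuplicated(ids))
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pop_lab <- if (identical(pop_names, "last_id")) {
    vapply(seq_len(max(pop_of_line)),
           function(k) ids[max(which(pop_of_line == k))], character(1))
  } else paste0("pop", seq_len(max(pop_of_line)))
  genotype_dataset(ids, pop_lab[pop_of_line], loci, a1, a2)
}

#' Write a GenePop file
#'
#' Inverse of [read_genepop()]: the round trip reproduces the dataset
#' exactly (individual order, population blocks, blanks as all-zero codes).
#'
#' @param ds A `genotype_dataset`.
#' @param path Optional output path; when `NULL` the text is returned.
#' @param allele_digits 2 or 3 (default); allele labels must fit.
#' @param title Title line content.
#' @return The GenePop text, invisibly when written to `path`.
#' @export
write_genepop <- function(ds, path = NULL, allele_digits = 3,
                          title = "patchkin export") {
  w <- as.integer(match.arg(as.character(allele_digits), c("2", "3")))
  mx <- suppressWarnings(max(c(ds$allele1, ds$allele2), na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^w)
    stop("allele label ", mx, " not representable with ", w, " digits")
  fmt <- function(a) ifelse(is.na(a), strrep("0", w), formatC(a, width = w, flag = "0"))
  out <- c(title, ds$loci)
  for (pp in unique(ds$populations)) {
    out <- c(out, "POP")
    for (i in which(ds$populations == pp)) {
      codes <- paste0(fmt(ds$allele1[i, ]), fmt(ds$allele2[i, ]))
      out <- c(out, paste0(ds$individuals[i], " , ", paste(codes, collapse = " ")))
    }
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(out, path)
  invisible(text)
}

## ---- long-form CSV ----------------------------------------------------

#' Read genotypes from long-form CSV
#'
#' Columns `individual,population,locus,allele1,allele2`; empty allele
#' fields mean a blank genotype. Individual and locus order follow first
#' appearance.
#'
#' @param path CSV path.
#' @return A `genotype_dataset`.
#' @export
read_genotype_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("CSV must have columns ", paste(need, collapse = ","))
  inds <- unique(df$individual)
  loci <- unique(df$locus)
  pop <- df$population[match(inds, df$individual)]
  a1 <- matrix(NA_integer_, length(inds), length(loci),
               dimnames = list(inds, loci))
  a2 <- a1
  i <- match(df$individual, inds)
  j <- match(df$locus, loci)
  v1 <- suppressWarnings(as.integer(df$allele1))
  v2 <- suppressWarnings(as.integer(df$allele2))
  a1[cbind(i, j)] <- v1
  a2[cbind(i, j)] <- v2
  genotype_dataset(inds, pop, loci, a1, a2)
}

#' Write genotypes to long-form CSV
#'
#' @param ds A `genotype_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(ds, path) {
  n <- length(ds$individuals); L <- length(ds$loci)
  df <- data.frame(
    individual = rep(ds$individuals, times = L),
    population = rep(ds$populations, times = L),
    locus      = rep(ds$loci, each = n),
    allele1    = as.vector(ds$allele1),
    allele2    = as.vector(ds$allele2),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

## internal: genotype count matrix for one population x locus cell.
## Returns a symmetric-storage list: alleles (labels), counts (k x k upper
## triangle matrix, genotype (i,j) i<=j stored at [i,j]), n (typed count),
## n_blank.
genotype_counts <- function(ds, population, locus) {
  idx <- which(ds$populations == population)
  g1 <- ds$allele1[idx, locus]; g2 <- ds$allele2[idx, locus]
  blank <- is.na(g1)
  g1 <- g1[!blank]; g2 <- g2[!blank]
  alleles <- sort(unique(c(g1, g2)))
  k <- length(alleles)
  cnt <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  if (k) {
    i <- match(pmin(g1, g2), alleles)
    j <- match(pmax(g1, g2), alleles)
    for (t in seq_along(i)) cnt[i[t], j[t]] <- cnt[i[t], j[t]] + 1L
  }
  list(alleles = alleles, counts = cnt, n = length(g1),
       n_blank = sum(blank))
}
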