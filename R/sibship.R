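#' Build the sibship edge set of a population
#'
#' One edge for every within-population dyad classified HS or FS whose
#' confidence (likelihood share of the winning category among the enabled
#' categories) is at least `min_confidence`.
#'
#' @param dyads Data frame from [dyad_relationships()].
#' @param population Population label.
#' @param min_confidence Default 0.95.
#' @return Data frame `from, to, label` (label HS or FS); possibly empty.
#' @export
build_sibship_graph <- function(dyads, population, min_confidence = 0.95) {
  sel <- dyads$pop1 == population & dyads$pop2 == population &
    !is.na(dyads$category) & dyads$category %in% c("HS", "FS") &
    !is.na(dyads$confidence) & dyads$confidence >= min_confidence
  data.frame(from = dyads$id1[sel], to = dyads$id2[sel],
             label = dyads$category[sel], stringsAsFactors = FALSE)
}

#' Extended sibship networks and nested full-sib families
#'
#' Networks are the connected components (>= 2 members) of the graph whose
#' edges are HS or FS dyads: individuals linked through chains of
#' intermediate half- or full-sibs belong to the same network even without
#' a shared parent. Full-sib families are the components (>= 2) of the
#' FS-only subgraph, each nested inside exactly one network. Components of
#' size 1 are reported as unrelated singletons.
#'
#' @param edges Edge data frame (`from, to, label`), e.g. from
#'   [build_sibship_graph()].
#' @param individuals Character vector of all individuals in the
#'   population (isolated ones become singletons).
#' @return A `sibship_partition`: list with `networks` (list of character
#'   vectors), `singletons`, `fs_families` (list of
#'   `list(members, network)`).
#' @export
extended_networks <- function(edges, individuals) {
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = individuals, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  member <- split(individuals, comp$membership[individuals])
  networks <- unname(member[vapply(member, length, integer(1)) >= 2L])
  networks <- lapply(networks, sort)
  singletons <- sort(unlist(member[vapply(member, length, integer(1)) == 1L],
                            use.names = FALSE))
  if (is.null(singletons)) singletons <- character(0)
  fs_edges <- edges[edges$label == "FS", , drop = FALSE]
  fs_families <- list()
  if (nrow(fs_edges)) {
    gf <- igraph::graph_from_data_frame(
      fs_edges[, c("from", "to"), drop = FALSE], directed = FALSE,
      vertices = data.frame(name = individuals, stringsAsFactors = FALSE))
    compf <- igraph::components(gf)
    memf <- split(individuals, compf$membership[individuals])
    memf <- memf[vapply(memf, length, integer(1)) >= 2L]
    fs_families <- lapply(unname(memf), function(mm) {
      net <- which(vapply(networks, function(nw) all(mm %in% nw), logical(1)))
      list(members = sort(mm), network = if (length(net)) net[1L] else NA_integer_)
    })
  }
  structure(list(networks = networks, singletons = singletons,
                 fs_families = fs_families),
            class = "sibship_partition")
}

#' Sibship partitions for every population
#'
#' @param ds A `genotype_dataset`.
#' @param dyads Optional precomputed within-pair dyad table.
#' @param min_confidence Edge confidence threshold (default 0.95).
#' @param ... Passed to [dyad_relationships()] when dyads are computed.
#' @return Named list of `sibship_partition`, one per population.
#' @export
sibship_partitions <- function(ds, dyads = NULL, min_confidence = 0.95, ...) {
  if (is.null(dyads))
    dyads <- dyad_relationships(ds, pairs = "within", estimate_k = FALSE, ...)
  pops <- unique(ds$populations)
  setNames(lapply(pops, function(pp) {
    extended_networks(build_sibship_graph(dyads, pp, min_confidence),
                      ds$individuals[ds$populations == pp])
  }), pops)
}

#' Text report of a sibship partition
#'
#' One population per call: network sizes and the nested FS families in
#' `k(m)` notation — e.g. `4(2)` means 4 full-sib families of 2 members
#' each; populations without any network report `no family structure`.
#'
#' @param partition A `sibship_partition`.
#' @param population Optional label to prefix.
#' @return Character scalar (the report line).
#' @export
network_report <- function(partition, population = NULL) {
  pre <- if (is.null(population)) "" else paste0(population, ": ")
  if (!length(partition$networks))
    return(paste0(pre, "no family structure"))
  sizes <- vapply(partition$networks, length, integer(1))
  nets <- paste0(length(sizes), " network(s) of size ",
                 paste(sort(sizes, decreasing = TRUE), collapse = ", "))
  fs <- ""
  if (length(partition$fs_families)) {
    fsz <- vapply(partition$fs_families, function(f) length(f$members),
                  integer(1))
    tab <- table(fsz)
    fs <- paste0("; FS families: ",
                 paste(sprintf("%d(%s)", as.integer(tab), names(tab)),
                       collapse = " "))
  }
  sing <- if (length(partition$singletons))
    paste0("; ", length(partition$singletons), " unrelated") else ""
  paste0(pre, nets, fs, sing)
}

#' @export
print.sibship_partition <- function(x, ...) {
  cat(network_report(x), "\n")
  invisible(x)
}
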