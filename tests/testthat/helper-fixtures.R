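# Shared fixtures and independent oracles, all built in code.

# tiny two-population dataset with a blank and a monomorphic locus
make_tiny_ds <- function() {
  genotype_dataset(
    individuals = c("a1", "a2", "a3", "b1", "b2"),
    populations = c("A", "A", "A", "B", "B"),
    loci = c("L1", "L2", "Lmono"),
    allele1 = rbind(c(1, 3, 7), c(1, NA, 7), c(2, 4, 7),
                    c(2, 3, 7), c(1, 3, 7)),
    allele2 = rbind(c(1, 4, 7), c(2, NA, 7), c(2, 4, 7),
                    c(2, 3, 7), c(2, 5, 7)))
}

# random valid dataset for round-trip property tests
random_dataset <- function(seed) {
  set.seed(seed)
  n_pop <- sample(1:3, 1)
  sizes <- sample(1:6, n_pop, replace = TRUE)
  n <- sum(sizes)
  L <- sample(1:4, 1)
  a1 <- matrix(sample(1:50, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample(1:50, n * L, replace = TRUE), n, L)
  blank <- matrix(runif(n * L) < 0.15, n, L)
  a1[blank] <- NA; a2[blank] <- NA
  genotype_dataset(paste0("ind", seq_len(n)),
                   rep(paste0("pop", seq_len(n_pop)), sizes),
                   paste0("loc", seq_len(L)), a1, a2)
}

# independent pedigree-enumeration oracle for dyad likelihoods: joint
# probability of two observed unordered genotypes under a relationship,
# by exhaustive enumeration of parental genotypes and gamete transmission
ped_enum_joint <- function(g1, g2, p, relationship) {
  alleles <- as.integer(names(p))
  keyg <- function(g) paste(sort(g), collapse = "/")
  k1 <- keyg(g1); k2 <- keyg(g2)
  gametes <- function(g) c(g[1], g[2])
  prob <- 0
  genos <- expand.grid(x = alleles, y = alleles)  # ordered parent gametes
  gp <- function(i) p[as.character(genos$x[i])] * p[as.character(genos$y[i])]
  if (relationship == "UR") {
    pg <- function(g) {
      f <- p[as.character(g)]
      if (g[1] == g[2]) f[1] * f[2] else 2 * f[1] * f[2]
    }
    return(unname(pg(sort(g1)) * pg(sort(g2))))
  }
  if (relationship == "PO") {
    ## g1 parent, g2 child: child = random allele of parent + random gamete
    for (i in seq_len(nrow(genos))) {
      par <- c(genos$x[i], genos$y[i])
      if (keyg(par) != k1) next
      ppar <- gp(i)
      for (tr in 1:2) for (a in alleles) {
        child <- c(par[tr], a)
        if (keyg(child) == k2)
          prob <- prob + ppar * 0.5 * p[as.character(a)]
      }
    }
    return(unname(prob))
  }
  ## sib relationships: enumerate parents
  for (i in seq_len(nrow(genos))) for (j in seq_len(nrow(genos))) {
    m <- c(genos$x[i], genos$y[i]); f <- c(genos$x[j], genos$y[j])
    pmf <- gp(i) * gp(j)
    if (relationship == "FS") {
      for (t1 in 1:2) for (t2 in 1:2) for (t3 in 1:2) for (t4 in 1:2) {
        c1 <- c(m[t1], f[t2]); c2 <- c(m[t3], f[t4])
        if (keyg(c1) == k1 && keyg(c2) == k2)
          prob <- prob + pmf * (1 / 16)
      }
    } else if (relationship == "HS") {
      ## shared parent m; f and a third parent g for the second child
      for (l in seq_len(nrow(genos))) {
        g <- c(genos$x[l], genos$y[l])
        pall <- pmf * gp(l)
        for (t1 in 1:2) for (t2 in 1:2) for (t3 in 1:2) for (t4 in 1:2) {
          c1 <- c(m[t1], f[t2]); c2 <- c(m[t3], g[t4])
          if (keyg(c1) == k1 && keyg(c2) == k2)
            prob <- prob + pall * (1 / 16)
        }
      }
    }
  }
  unname(prob)
}

# brute-force connected components via transitive closure (oracle for the
# igraph-based implementation)
closure_components <- function(nodes, edges) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  diag(adj) <- TRUE
  for (r in seq_len(nrow(edges))) {
    adj[edges$from[r], edges$to[r]] <- TRUE
    adj[edges$to[r], edges$from[r]] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comps <- unique(apply(adj, 1, function(row) paste(sort(nodes[row]),
                                                    collapse = ",")))
  lapply(strsplit(comps, ","), identity)
}

# unrelated multi-population null dataset for calibration tests
null_calibration_ds <- function(seed, n_pops = 3, n = 6, L = 8, k = 4) {
  cfg <- sim_config(n_pops = n_pops, pop_sizes = n, n_loci = L,
                    alleles_per_locus = k, seed = seed)
  fr <- derive_population_frequencies(sample_base_frequencies(cfg),
                                      n_pops, 0, seed)
  simulate_pedigree_sample(fr, cfg)$dataset
}
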