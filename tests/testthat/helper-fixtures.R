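# Shared fixtures and independent oracles, all built in code.

# Three-taxon reference tree: d(A,B) = 2, d(A,C) = d(B,C) = 4.
abc_tree <- function() {
  tf <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tf)
  read_newick(tf)
}

tree_from_text <- function(text) {
  tf <- tempfile(fileext = ".nwk")
  writeLines(text, tf)
  read_newick(tf)
}

otu <- function(..., samples = NULL, taxa = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  storage.mode(m) <- "integer"
  rownames(m) <- if (is.null(samples)) paste0("s", seq_len(nrow(m))) else samples
  colnames(m) <- if (is.null(taxa)) paste0("t", seq_len(ncol(m))) else taxa
  m
}

# Brute-force double-loop oracle for the abundance-weighted betaMNTD,
# written independently of the package's kernel: explicit loops over
# individuals' taxa and explicit nearest-neighbour scans.
bmntd_oracle <- function(table, tree) {
  d <- ape::cophenetic.phylo(tree)
  ns <- nrow(table)
  out <- matrix(0, ns, ns, dimnames = list(rownames(table), rownames(table)))
  for (k in seq_len(ns)) {
    for (m in seq_len(ns)) {
      if (m <= k) next
      xk <- table[k, ]; xm <- table[m, ]
      fk <- xk / sum(xk); fm <- xm / sum(xm)
      tk <- colnames(table)[xk > 0]; tm <- colnames(table)[xm > 0]
      s1 <- 0
      for (i in tk) {
        best <- Inf
        for (j in tm) if (d[i, j] < best) best <- d[i, j]
        s1 <- s1 + fk[i] * best
      }
      s2 <- 0
      for (j in tm) {
        best <- Inf
        for (i in tk) if (d[j, i] < best) best <- d[j, i]
        s2 <- s2 + fm[j] * best
      }
      out[k, m] <- out[m, k] <- 0.5 * (s1 + s2)
    }
  }
  out
}

# Random small community + tree instances for oracle equivalence.
random_instance <- function(seed, max_taxa = 8, max_samples = 5) {
  set.seed(seed)
  nt <- sample(3:max_taxa, 1)
  ns <- sample(2:max_samples, 1)
  tree <- ape::rphylo(nt, 1, 0)
  tree$tip.label <- paste0("x", seq_len(nt))
  m <- matrix(rpois(ns * nt, 3), ns, nt,
              dimnames = list(paste0("s", seq_len(ns)), tree$tip.label))
  # ensure no empty sample and at least one taxon per sample
  for (s in seq_len(ns)) if (sum(m[s, ]) == 0) m[s, sample(nt, 1)] <- 1L
  storage.mode(m) <- "integer"
  list(table = m, tree = tree)
}

# Tiny graphs with hand-enumerable topology.
triangle_graph <- function() {
  igraph::graph_from_literal(A - B, B - C, C - A)
}
path_graph4 <- function() {
  igraph::graph_from_literal(A - B, B - C, C - D)
}
star_graph4 <- function() {
  igraph::graph_from_literal(C - L1, C - L2, C - L3, C - L4)
}
three_cliques <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  igraph::V(g)$name <- paste0("n", seq_len(15))
  g
}
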