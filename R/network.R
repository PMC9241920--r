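#' Build a co-occurrence network from a correlation table
#'
#' Retains an edge iff `|estimate| > r_min` and (strictly) `p < p_max`
#' and, when `q_max` is given, `q < q_max`. All inequalities are strict:
#' an estimate of exactly `r_min` is excluded. Nodes appear only when they
#' carry at least one retained edge (isolated taxa are dropped).
#'
#' @param corr A [correlation_table()] data frame (`id_a`, `id_b`,
#'   `estimate`, `p`, optionally `q`).
#' @param r_min Strict lower bound on `|estimate|`; default 0.5.
#' @param p_max Strict upper bound on `p`; default 0.05. `NULL` skips the
#'   p filter.
#' @param q_max Strict upper bound on FDR-adjusted `q`; default `NULL`
#'   (unused).
#' @param taxonomy Optional named vector of lineage strings attached as a
#'   node attribute.
#' @return An undirected simple [igraph::graph] with edge attributes
#'   `weight` (the estimate), `sign`, `p`, and `q` when present.
#' @export
build_network <- function(corr, r_min = 0.5, p_max = 0.05, q_max = NULL,
                          taxonomy = NULL) {
  keep <- abs(corr$estimate) > r_min
  if (!is.null(p_max)) keep <- keep & corr$p < p_max
  if (!is.null(q_max)) keep <- keep & corr$q < q_max
  edges <- corr[which(keep), , drop = FALSE]
  if (nrow(edges) == 0)
    return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$id_a, to = edges$id_b,
               weight = edges$estimate,
               sign = ifelse(edges$estimate > 0, "positive", "negative"),
               p = edges$p,
               q = if ("q" %in% names(edges)) edges$q else NA_real_),
    directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = "first")
  if (!is.null(taxonomy)) {
    igraph::V(g)$taxonomy <-
      unname(taxonomy[igraph::V(g)$name])
  }
  g
}

#' Network topology statistics
#'
#' Standard unweighted descriptors: node and edge counts, average degree,
#' average clustering coefficient (mean local clustering over nodes of
#' degree >= 2), global transitivity, average shortest-path length and
#' diameter on the largest connected component, the fraction of positive
#' edges, plus per-node degree, (unnormalized shortest-path) betweenness
#' and local clustering.
#'
#' @param net An undirected igraph network.
#' @return List with `network` (one-row data frame) and `nodes` (per-node
#'   data frame).
#' @export
topology_stats <- function(net) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  if (n == 0) {
    return(list(network = data.frame(
      n_nodes = 0, n_edges = 0, average_degree = NA_real_,
      clustering_coefficient = NA_real_, global_transitivity = NA_real_,
      average_path_length = NA_real_, diameter = NA_real_,
      positive_edge_fraction = NA_real_),
      nodes = data.frame()))
  }
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, weights = NA,
                             normalized = FALSE)
  loc <- igraph::transitivity(net, type = "local", isolates = "NaN")
  comp <- igraph::components(net)
  lcc <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  pos_frac <- if ("sign" %in% igraph::edge_attr_names(net) && m > 0)
    mean(igraph::E(net)$sign == "positive") else NA_real_
  network <- data.frame(
    n_nodes = n, n_edges = m,
    average_degree = mean(deg),
    clustering_coefficient = if (all(is.nan(loc))) 0
                             else mean(loc, na.rm = TRUE),
    global_transitivity = igraph::transitivity(net, type = "global"),
    average_path_length = igraph::mean_distance(lcc, directed = FALSE,
                                                weights = NA),
    diameter = igraph::diameter(lcc, directed = FALSE,
                                unconnected = FALSE, weights = NA),
    positive_edge_fraction = pos_frac)
  nodes <- data.frame(node = igraph::V(net)$name, degree = deg,
                      betweenness = btw, clustering = loc,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(network = network, nodes = nodes)
}

#' Power-law fit of the degree distribution
#'
#' Least-squares linear fit of `log(frequency)` on `log(degree)` over the
#' nonzero-frequency positive-degree bins; the returned R-squared is the
#' usual scale-free-ness descriptor for co-occurrence networks.
#'
#' @param net An igraph network with at least 3 distinct positive degree
#'   values.
#' @return The fit's R-squared (single number).
#' @export
fit_powerlaw_r2 <- function(net) {
  deg <- igraph::degree(net)
  tab <- table(deg[deg > 0])
  if (length(tab) < 3)
    stop("need at least 3 distinct positive degree values")
  x <- log(as.numeric(names(tab)))
  y <- log(as.numeric(tab))
  summary(lm(y ~ x))$r.squared
}

#' Louvain module detection
#'
#' Greedy modularity maximization (local moves plus graph aggregation,
#' iterated to a fixed point) on the unweighted simple graph. Modules are
#' renamed `M1..Mk` in decreasing size order.
#'
#' @param net Nonempty igraph network.
#' @param resolution Louvain resolution parameter (1 = plain modularity).
#' @param seed Integer seed (tie-breaking in the local-move phase).
#' @param weighted If `TRUE`, `|weight|` edge weights are used; default
#'   unweighted.
#' @return `data.frame` with `node` and `module`; the partition modularity
#'   is in `attr(, "modularity")` and module sizes in `attr(, "sizes")`.
#' @export
louvain_modules <- function(net, resolution = 1, seed = NULL,
                            weighted = FALSE) {
  if (igraph::vcount(net) == 0) stop("empty network")
  w <- if (weighted && "weight" %in% igraph::edge_attr_names(net))
    abs(igraph::E(net)$weight) else NA
  cl <- with_seed(seed,
    igraph::cluster_louvain(net, weights = w, resolution = resolution))
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(paste0("M", seq_along(sizes)), names(sizes))
  out <- data.frame(node = igraph::V(net)$name,
                    module = unname(relabel[as.character(memb)]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "modularity") <- igraph::modularity(net, memb,
    weights = if (identical(w, NA) || all(is.na(w))) NULL else w)
  attr(out, "sizes") <- setNames(as.integer(sizes), relabel)
  out
}

#' Erdos-Renyi random-graph ensemble comparison
#'
#' Generates `n_random` G(n, m) graphs (uniform over graphs with exactly
#' the real network's node and edge counts) and summarizes their
#' clustering, average path length and Louvain modularity, yielding
#' z-scores locating the real network against its random expectation.
#'
#' @param net The real igraph network.
#' @param n_random Ensemble size; default 1000.
#' @param seed Integer seed.
#' @return List with `ensemble` (per-graph data frame of
#'   `global_transitivity`, `average_path_length`, `modularity`) and
#'   `z` (named z-scores of the real network's values).
#' @export
er_ensemble <- function(net, n_random = 1000, seed = NULL) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  if (m > n * (n - 1) / 2) stop("more edges than a simple graph allows")
  stats_one <- function(g) {
    comp <- igraph::components(g)
    lcc <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize)))
    cl <- igraph::cluster_louvain(g)
    c(global_transitivity = igraph::transitivity(g, type = "global"),
      average_path_length = igraph::mean_distance(lcc, directed = FALSE,
                                                weights = NA),
      modularity = igraph::modularity(g, igraph::membership(cl)))
  }
  ens <- with_seed(seed, {
    t(vapply(seq_len(n_random), function(i)
      stats_one(igraph::sample_gnm(n, m)), numeric(3)))
  })
  ens <- as.data.frame(ens)
  real <- stats_one(net)
  z <- (real - colMeans(ens, na.rm = TRUE)) /
    apply(ens, 2, sd, na.rm = TRUE)
  list(ensemble = ens, real = real, z = z)
}

#' Identify keystone taxa
#'
#' Keystones are highly connected but locally embedded nodes: degree
#' strictly above `degree_min` and unnormalized betweenness centrality
#' strictly below `betweenness_max`.
#'
#' @param net An igraph network.
#' @param degree_min Strict lower degree bound; default 100.
#' @param betweenness_max Strict upper betweenness bound; default 5000.
#' @return Character vector of keystone node names.
#' @export
identify_keystones <- function(net, degree_min = 100,
                               betweenness_max = 5000) {
  if (igraph::vcount(net) == 0) return(character())
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, weights = NA,
                             normalized = FALSE)
  names(deg)[deg > degree_min & btw < betweenness_max]
}

#' Per-sample subnetworks of a meta-community network
#'
#' For each sample, the induced subgraph on the taxa it actually contains
#' (nonzero count), with the per-subnetwork descriptors commonly regressed
#' on environmental drivers: mean degree, mean betweenness, mean local
#' clustering ("transitivity"), and global transitivity.
#'
#' @param net Meta-community igraph network (nodes must be taxa of
#'   `table`).
#' @param table Samples x taxa count matrix.
#' @return `data.frame`, one row per sample: `sample`, `n_nodes`,
#'   `n_edges`, `mean_degree`, `mean_betweenness`, `mean_clustering`,
#'   `global_transitivity`.
#' @export
sample_subnetworks <- function(net, table) {
  table <- as_otu_matrix(table)
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% colnames(table)))
    stop("network contains nodes absent from the OTU table")
  out <- lapply(rownames(table), function(s) {
    present <- colnames(table)[table[s, ] > 0]
    sub <- igraph::induced_subgraph(net, intersect(nodes, present))
    nv <- igraph::vcount(sub)
    deg <- igraph::degree(sub)
    loc <- igraph::transitivity(sub, type = "local", isolates = "NaN")
    data.frame(
      sample = s, n_nodes = nv, n_edges = igraph::ecount(sub),
      mean_degree = if (nv) mean(deg) else NA_real_,
      mean_betweenness = if (nv)
        mean(igraph::betweenness(sub, directed = FALSE,
                                 weights = NA)) else NA_real_,
      mean_clustering = if (nv == 0 || all(is.nan(loc))) 0
                        else mean(loc, na.rm = TRUE),
      global_transitivity = igraph::transitivity(sub, type = "global"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spearman association network
#'
#' Rank correlations (midrank ties) between every cross pair of columns
#' of two sample-aligned tables — taxa vs environmental variables, or
#' taxa of two domains — with Benjamini-Hochberg FDR over all tested
#' pairs; edges pass `|rho| > rho_min` and `q < q_max` (both strict).
#' Constant columns (undefined rank correlation) are skipped with a
#' warning.
#'
#' @param table_a Samples x features numeric matrix/data frame.
#' @param table_b Second table, same samples in the same order.
#' @param rho_min Strict lower bound on `|rho|`; default 0.6.
#' @param q_max Strict upper bound on `q`; default 0.01.
#' @return List with `table` (all tested pairs: `id_a`, `id_b`,
#'   `estimate`, `p`, `q`) and `network` (the retained igraph graph).
#' @export
spearman_network <- function(table_a, table_b, rho_min = 0.6, q_max = 0.01) {
  a <- as.matrix(table_a)
  b <- as.matrix(table_b)
  if (nrow(a) != nrow(b) ||
      (!is.null(rownames(a)) && !is.null(rownames(b)) &&
       !identical(rownames(a), rownames(b))))
    stop("tables must share identically ordered samples")
  const_a <- apply(a, 2, function(x) length(unique(x)) < 2)
  const_b <- apply(b, 2, function(x) length(unique(x)) < 2)
  if (any(const_a) || any(const_b))
    warning("skipping constant column(s): ",
            paste(c(colnames(a)[const_a], colnames(b)[const_b]),
                  collapse = ", "))
  a <- a[, !const_a, drop = FALSE]
  b <- b[, !const_b, drop = FALSE]
  rho <- cor(a, b, method = "spearman")
  n <- nrow(a)
  # t approximation for the rank correlation's null distribution
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- data.frame(
    id_a = rep(colnames(a), times = ncol(b)),
    id_b = rep(colnames(b), each = ncol(a)),
    estimate = as.vector(rho), p = as.vector(p),
    stringsAsFactors = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  net <- build_network(out, r_min = rho_min, p_max = NULL, q_max = q_max)
  list(table = out, network = net)
}

#' Bipartite incidence matrix from cross-domain associations
#'
#' Converts a retained cross-domain correlation table into binary and
#' count incidence matrices: rows are one node set (e.g. microeukaryote
#' taxa), columns the other (prokaryote taxa), a cell is 1 iff at least
#' one retained association links the pair.
#'
#' @param corr Correlation table whose `id_a`/`id_b` span two disjoint
#'   node sets.
#' @param set_a,set_b Character vectors defining the two sets (rows,
#'   columns).
#' @return List with `incidence` (0/1 matrix) and `counts` (association
#'   counts).
#' @export
bipartite_incidence <- function(corr, set_a, set_b) {
  if (length(intersect(set_a, set_b)))
    stop("node sets overlap: not bipartite")
  counts <- matrix(0L, length(set_a), length(set_b),
                   dimnames = list(set_a, set_b))
  for (k in seq_len(nrow(corr))) {
    ia <- corr$id_a[k]; ib <- corr$id_b[k]
    if (ia %in% set_a && ib %in% set_b) {
      counts[ia, ib] <- counts[ia, ib] + 1L
    } else if (ia %in% set_b && ib %in% set_a) {
      counts[ib, ia] <- counts[ib, ia] + 1L
    } else {
      stop("pair (", ia, ", ", ib, ") does not span the two sets")
    }
  }
  list(incidence = (counts > 0) + 0L, counts = counts)
}
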