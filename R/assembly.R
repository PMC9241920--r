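#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` over taxa, the
#' abundance-based taxonomic beta-diversity used throughout the pipeline.
#'
#' @param table Samples x taxa count matrix (no all-zero sample).
#' @return Symmetric samples x samples matrix in `[0, 1]`, zero diagonal.
#' @export
bray_curtis <- function(table) {
  table <- as_otu_matrix(table)
  if (any(rowSums(table) == 0))
    stop("all-zero sample: '", rownames(table)[rowSums(table) == 0][1L], "'")
  as.matrix(vegan::vegdist(table, method = "bray"))
}

# Patristic distances among `taxa`, in that order; errors on tips missing
# from the tree.
patristic <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxon missing from tree: '", missing[1L], "'")
  if (length(tree$tip.label) == 1L)
    return(matrix(0, 1, 1, dimnames = list(taxa, taxa)))
  ape::cophenetic.phylo(tree)[taxa, taxa, drop = FALSE]
}

#' Abundance-weighted beta mean-nearest-taxon distance
#'
#' For a sample pair (k, m), the mean over individuals of the patristic
#' distance from each taxon to its nearest neighbour in the opposite
#' community, weighted by relative abundance and averaged over the two
#' directions:
#' `0.5 * (sum_i f_ik min_j d(i, j) + sum_j f_jm min_i d(j, i))`,
#' sums running over taxa present in the focal sample. Measures
#' phylogenetic turnover between communities.
#'
#' @param table Samples x taxa count matrix; every taxon with a nonzero
#'   count must be a tip of `tree`.
#' @param tree A `"phylo"` tree with branch lengths.
#' @return Symmetric non-negative samples x samples matrix.
#' @export
beta_mntd <- function(table, tree) {
  table <- as_otu_matrix(table)
  used <- colnames(table)[colSums(table) > 0]
  d <- patristic(tree, used)
  m <- table[, used, drop = FALSE]
  relab <- m / rowSums(m)
  out <- .bmntd_cpp(relab, d)
  dimnames(out) <- list(rownames(table), rownames(table))
  out
}

#' Beta nearest-taxon index (standardized betaMNTD)
#'
#' Standardized effect size of [beta_mntd()] against a phylogenetic null
#' in which tip labels are shuffled uniformly across the whole tree
#' (abundances untouched), recomputing betaMNTD each time:
#' `betaNTI = (obs - mean(null)) / sd(null)`. Values beyond +2 indicate
#' more phylogenetic turnover than expected (heterogeneous selection),
#' below -2 less than expected (homogeneous selection).
#'
#' The null randomizes taxon placement over the *entire* tree — including
#' tips never observed in the table, which represent the regional pool —
#' so phylogenetic clustering of the observed taxa is measured against
#' the whole pool, not only against itself.
#'
#' @inheritParams beta_mntd
#' @param reps Null replicates (>= 2; default 999).
#' @param seed Integer seed; same seed, same inputs give a bit-identical
#'   matrix.
#' @return Symmetric matrix of betaNTI values. Pairs whose null standard
#'   deviation is zero are degenerate: they are set to `NA` and flagged in
#'   the logical `attr(, "degenerate")` matrix, with a warning.
#' @export
beta_nti <- function(table, tree, reps = 999, seed = NULL) {
  if (reps < 2) stop("`reps` must be >= 2")
  table <- as_otu_matrix(table)
  used <- colnames(table)[colSums(table) > 0]
  missing <- setdiff(used, tree$tip.label)
  if (length(missing)) stop("taxon missing from tree: '", missing[1L], "'")
  d_full <- ape::cophenetic.phylo(tree)
  idx <- match(used, tree$tip.label)
  d <- d_full[idx, idx, drop = FALSE]
  m <- table[, used, drop = FALSE]
  relab <- m / rowSums(m)
  obs <- .bmntd_cpp(relab, d)

  ntip <- length(tree$tip.label)
  s1 <- matrix(0, nrow(obs), ncol(obs))
  s2 <- matrix(0, nrow(obs), ncol(obs))
  with_seed(seed, {
    for (r in seq_len(reps)) {
      pos <- sample.int(ntip)[seq_along(idx)]
      nul <- .bmntd_cpp(relab, d_full[pos, pos, drop = FALSE])
      s1 <- s1 + nul
      s2 <- s2 + nul * nul
    }
  })
  mu <- s1 / reps
  sdv <- sqrt(pmax(s2 / reps - mu * mu, 0) * reps / (reps - 1))
  bnti <- (obs - mu) / sdv
  degen <- sdv < 1e-12
  diag(degen) <- FALSE
  diag(bnti) <- 0
  if (any(degen)) {
    bnti[degen] <- NA_real_
    warning(sum(degen[upper.tri(degen)]),
            " pair(s) have zero null variance (degenerate betaNTI)")
  }
  dimnames(bnti) <- list(rownames(table), rownames(table))
  attr(bnti, "degenerate") <- degen
  attr(bnti, "reps") <- reps
  bnti
}

# One Raup-Crick null community: preserve the sample's richness and total
# abundance; draw identities without replacement with probability
# proportional to occupancy, then allocate the remaining individuals with
# probability proportional to mean relative abundance (or uniformly).
rc_null_sample <- function(richness, total, occ, mean_relab, weighted) {
  nt <- length(occ)
  ids <- sample.int(nt, richness, prob = occ)
  x <- integer(nt)
  x[ids] <- 1L
  rest <- total - richness
  if (rest > 0) {
    pr <- if (weighted) mean_relab[ids] else rep(1, richness)
    if (sum(pr) <= 0) pr <- rep(1, richness)
    x[ids] <- x[ids] + as.integer(rmultinom(1L, rest, pr))
  }
  x
}

#' Raup-Crick metric on Bray-Curtis distances
#'
#' Compares each pair's observed Bray-Curtis dissimilarity against a
#' probabilistic-assembly null that rebuilds both communities preserving
#' their observed richness and total abundance: taxon identities are drawn
#' without replacement with probability proportional to occupancy (the
#' fraction of samples where the taxon occurs), and remaining individuals
#' are allocated with probability proportional to mean relative abundance
#' across samples. `RC = 2 * [(#null < obs) + 0.5 (#null = obs)]/reps - 1`,
#' in `[-1, 1]`: near +1, communities are more dissimilar than the
#' stochastic expectation (dispersal limitation); near -1, less
#' (homogenizing dispersal).
#'
#' @inheritParams beta_nti
#' @param weighted If `TRUE` (default) the abundance allocation uses mean
#'   relative abundances; `FALSE` allocates uniformly over drawn taxa.
#' @return Symmetric samples x samples matrix of Raup-Crick values.
#' @export
raup_crick <- function(table, reps = 999, seed = NULL, weighted = TRUE) {
  if (reps < 2) stop("`reps` must be >= 2")
  table <- as_otu_matrix(table)
  if (any(rowSums(table > 0) == 0))
    stop("sample with zero richness: '",
         rownames(table)[rowSums(table > 0) == 0][1L], "'")
  ns <- nrow(table)
  occ <- colMeans(table > 0)
  relab <- table / rowSums(table)
  mean_relab <- colMeans(relab)
  richness <- rowSums(table > 0)
  totals <- rowSums(table)

  bc_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)
  out <- matrix(0, ns, ns, dimnames = list(rownames(table), rownames(table)))
  with_seed(seed, {
    for (i in seq_len(ns - 1L)) {
      for (j in (i + 1L):ns) {
        obs <- bc_pair(table[i, ], table[j, ])
        below <- ties <- 0L
        for (r in seq_len(reps)) {
          ni <- rc_null_sample(richness[i], totals[i], occ, mean_relab, weighted)
          nj <- rc_null_sample(richness[j], totals[j], occ, mean_relab, weighted)
          nbc <- bc_pair(ni, nj)
          if (nbc < obs - 1e-12) below <- below + 1L
          else if (abs(nbc - obs) <= 1e-12) ties <- ties + 1L
        }
        out[i, j] <- out[j, i] <- 2 * ((below + 0.5 * ties) / reps) - 1
      }
    }
  })
  attr(out, "reps") <- reps
  out
}

#' Classify pairwise comparisons into five assembly processes
#'
#' Applies the two-stage decision rule: `betaNTI > +2` is heterogeneous
#' selection and `betaNTI < -2` homogeneous selection; among the remaining
#' pairs (`|betaNTI| < 2`), `RC > +0.95` indicates dispersal limitation,
#' `RC < -0.95` homogenizing dispersal, and `|RC| < 0.95` drift
#' (undominated processes) acting alone.
#'
#' @param bnti,rc Aligned matrices from [beta_nti()] and [raup_crick()].
#' @return `data.frame` with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `bnti`, `rc`, `process`. Degenerate (NA) betaNTI pairs are
#'   labelled `"undefined"` with a warning.
#' @export
classify_pairs <- function(bnti, rc) {
  if (!identical(dim(bnti), dim(rc)) ||
      !identical(rownames(bnti), rownames(rc)))
    stop("betaNTI and RC matrices are not aligned")
  ids <- rownames(bnti)
  ut <- which(upper.tri(bnti), arr.ind = TRUE)
  b <- bnti[ut]
  r <- rc[ut]
  process <- ifelse(is.na(b), "undefined",
             ifelse(b > 2, "heterogeneous_selection",
             ifelse(b < -2, "homogeneous_selection",
             ifelse(r > 0.95, "dispersal_limitation",
             ifelse(r < -0.95, "homogenizing_dispersal", "drift")))))
  if (any(process == "undefined"))
    warning(sum(process == "undefined"),
            " degenerate pair(s) labelled 'undefined'")
  data.frame(sample_a = ids[ut[, 1L]], sample_b = ids[ut[, 2L]],
             bnti = b, rc = r, process = process,
             stringsAsFactors = FALSE)
}

#' Summarize process fractions per group
#'
#' Tallies, within each group (e.g. season), the fraction of pairwise
#' comparisons assigned to each of the five assembly processes. Only pairs
#' whose two samples share a group are counted; `"undefined"` pairs are
#' excluded from the denominators with a warning.
#'
#' @param labels Output of [classify_pairs()].
#' @param grouping Named character vector mapping sample id to group.
#' @return `data.frame` with one row per group: the five process fractions
#'   (summing to 1) and `n_pairs`.
#' @export
summarize_processes <- function(labels, grouping) {
  processes <- c("heterogeneous_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal", "drift")
  ga <- grouping[labels$sample_a]
  gb <- grouping[labels$sample_b]
  if (anyNA(ga) || anyNA(gb)) stop("grouping missing for some samples")
  within <- labels[ga == gb, , drop = FALSE]
  within$group <- grouping[within$sample_a]
  groups <- unique(grouping)
  small <- names(table(grouping))[table(grouping) < 2]
  if (length(small))
    stop("group with fewer than 2 samples: '", small[1L], "'")
  if (any(within$process == "undefined")) {
    warning("excluding 'undefined' pairs from process fractions")
    within <- within[within$process != "undefined", , drop = FALSE]
  }
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- within[within$group == g, , drop = FALSE]
    n <- nrow(sub)
    fr <- if (n) as.vector(table(factor(sub$process, levels = processes))) / n
          else rep(NA_real_, 5L)
    df <- as.data.frame(as.list(setNames(fr, processes)))
    df$n_pairs <- n
    df
  }))
  rownames(out) <- groups
  cbind(group = groups, out)
}

#' Full assembly-process analysis
#'
#' Convenience wrapper: betaNTI and Raup-Crick nulls, per-pair
#' classification, and per-group process fractions in one call.
#'
#' @inheritParams beta_nti
#' @param grouping Named character vector (sample id -> group); if `NULL`,
#'   all samples form one group `"all"`.
#' @param rc_weighted Passed to [raup_crick()].
#' @return List with `bnti`, `rc`, `pairs`, `summary`.
#' @export
assembly_processes <- function(table, tree, grouping = NULL, reps = 999,
                               seed = NULL, rc_weighted = TRUE) {
  table <- as_otu_matrix(table)
  if (is.null(grouping))
    grouping <- setNames(rep("all", nrow(table)), rownames(table))
  bnti <- beta_nti(table, tree, reps = reps, seed = sub_seed(seed, 11L))
  rc <- raup_crick(table, reps = reps, seed = sub_seed(seed, 12L),
                   weighted = rc_weighted)
  pairs <- classify_pairs(bnti, rc)
  list(bnti = bnti, rc = rc, pairs = pairs,
       summary = summarize_processes(pairs, grouping))
}
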