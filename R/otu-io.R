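#' Read an OTU abundance table
#'
#' Parses a delimited samples-by-taxa (or taxa-by-samples) count table into
#' the package's canonical form: an integer matrix with samples as rows and
#' taxa as columns, both axes named. This is the universal community object
#' every downstream function consumes.
#'
#' @param path Path to a tab- or comma-separated file. The first column
#'   holds one identifier axis, the header row the other.
#' @param orientation `"taxa_rows"` (the common OTU-table dialect: taxa down
#'   the rows, samples across the columns) or `"samples_rows"`. The result is
#'   always samples x taxa.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return Integer matrix, samples x taxa, with `dimnames`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_otu_table(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("t1", "t2", "t3"))), tf)
#' read_otu_table(tf)
#' @export
read_otu_table <- function(path, orientation = c("taxa_rows", "samples_rows"),
                           sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","

  nf <- count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged table: line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1L])
  }

  df <- read.table(path, sep = sep, header = TRUE, row.names = NULL,
                   check.names = FALSE, colClasses = "character",
                   comment.char = "")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row identifier: ", ids[duplicated(ids)][1L])
  cn <- colnames(df)[-1L]
  if (anyDuplicated(cn))
    stop("duplicate column identifier: ", cn[duplicated(cn)][1L])

  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(m), nrow(m), ncol(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric count at line ", bad[1L] + 1L, " ('",
         m[bad[1L], bad[2L]], "')")
  }
  if (any(num < 0)) stop("negative counts are not allowed")
  storage.mode(num) <- "integer"
  dimnames(num) <- list(ids, cn)
  if (orientation == "taxa_rows") num <- t(num)
  num
}

#' Write an OTU table
#'
#' @param table Samples x taxa count matrix.
#' @param path Output path.
#' @param orientation Dialect to emit (see [read_otu_table()]).
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path,
                            orientation = c("taxa_rows", "samples_rows"),
                            sep = "\t") {
  orientation <- match.arg(orientation)
  table <- as_otu_matrix(table)
  m <- if (orientation == "taxa_rows") t(table) else table
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  colnames(df)[1L] <- if (orientation == "taxa_rows") "taxon_id" else "sample_id"
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Validate/coerce a samples x taxa count matrix.
as_otu_matrix <- function(table) {
  m <- as.matrix(table)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("OTU table must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(m))) stop("duplicate taxon ids")
  if (!is.numeric(m) || anyNA(m)) stop("counts must be numeric and non-missing")
  if (any(m < 0)) stop("counts must be non-negative")
  m
}

#' Rarefy samples to a fixed sequencing depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) so every retained sample sums exactly to `depth`,
#' removing depth-driven differences in richness and dissimilarity before
#' community comparison.
#'
#' @param table Samples x taxa count matrix.
#' @param depth Target reads per sample (positive integer).
#' @param seed Integer seed; subsampling is reproducible given the seed.
#' @param drop_below If `TRUE`, samples with fewer than `depth` reads are
#'   dropped; if `FALSE` (default) such samples raise an error.
#' @return Rarefied samples x taxa integer matrix.
#' @export
rarefy <- function(table, depth, seed, drop_below = FALSE) {
  table <- as_otu_matrix(table)
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0)
    stop("`depth` must be a positive integer")
  depth <- as.integer(depth)
  totals <- rowSums(table)
  if (any(totals < depth)) {
    if (drop_below) {
      table <- table[totals >= depth, , drop = FALSE]
    } else {
      stop("sample '", rownames(table)[which(totals < depth)[1L]],
           "' has fewer than ", depth, " reads; use drop_below = TRUE")
    }
  }
  with_seed(seed, {
    out <- table
    for (s in seq_len(nrow(table))) {
      x <- table[s, ]
      if (sum(x) == depth) next
      reads <- rep.int(seq_along(x), x)
      keep <- sample(reads, depth)
      out[s, ] <- tabulate(keep, nbins = length(x))
    }
    out
  })
}

#' Filter taxa by total abundance
#'
#' Keeps taxa whose summed count across all samples is strictly greater
#' than `min_total` (default 10 reads), the usual pre-filter before
#' co-occurrence inference. The sample set is unchanged.
#'
#' @param table Samples x taxa count matrix.
#' @param min_total Strict lower bound on a taxon's total count.
#' @return Filtered matrix (possibly with zero columns).
#' @export
filter_prevalence <- function(table, min_total = 10) {
  table <- as_otu_matrix(table)
  table[, colSums(table) > min_total, drop = FALSE]
}

#' Read a rooted Newick phylogeny
#'
#' @param path Newick file.
#' @param missing_lengths `"error"` (default) rejects trees lacking branch
#'   lengths; `"zero"` substitutes zero-length branches.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_newick <- function(path, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("failed to parse Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("failed to parse Newick file: ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (missing_lengths == "error")
      stop("tree has missing branch lengths")
    if (is.null(tree$edge.length))
      tree$edge.length <- numeric(nrow(tree$edge))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Read a sample metadata / environment table
#'
#' @param path CSV with a `sample_id` first column; remaining columns are
#'   environmental variables (numeric) and grouping labels such as `site`
#'   and `season` (character).
#' @return `data.frame` with row names set to sample ids.
#' @export
read_env_table <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate sample ids in environment table")
  rownames(df) <- ids
  df[, -1L, drop = FALSE]
}

#' Write / read a network with attributes
#'
#' Serializes an [igraph::graph] co-occurrence network, carrying node
#' attributes (taxonomy, module, degree, betweenness, keystone flag) and
#' edge attributes (estimate, sign, p, q) so the file can be re-read or
#' opened in external viewers.
#'
#' @param network An igraph object with unique node `name`s.
#' @param path Output path.
#' @param dialect `"gml"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(network, path, dialect = c("gml", "graphml")) {
  dialect <- match.arg(dialect)
  if (anyDuplicated(igraph::V(network)$name)) stop("duplicate node ids")
  igraph::write_graph(network, path, format = dialect)
  invisible(path)
}

#' @rdname write_graph_file
#' @export
read_graph_file <- function(path, dialect = c("gml", "graphml")) {
  dialect <- match.arg(dialect)
  g <- igraph::read_graph(path, format = dialect)
  # GML readers surface the node label as `label`; restore `name`
  if (!("name" %in% igraph::vertex_attr_names(g)) &&
      "label" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$name <- igraph::V(g)$label
  g
}
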