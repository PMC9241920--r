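#' Euclidean environmental distance matrix
#'
#' Pairwise Euclidean distance between samples over the numeric
#' environmental variables, optionally z-scoring each variable first so
#' that factors measured in different units contribute comparably.
#'
#' @param env Environment data frame / matrix (samples in rows); only
#'   numeric columns are used.
#' @param standardize Z-score each variable across the included samples
#'   first (default `TRUE`). Zero-variance variables are dropped with a
#'   warning.
#' @param exclude Variable names to leave out (e.g. a factor known to
#'   covary with another).
#' @param impute Replace missing values by the variable mean
#'   (default `FALSE`: missing values are an error).
#' @return Symmetric samples x samples distance matrix.
#' @export
euclidean_matrix <- function(env, standardize = TRUE, exclude = NULL,
                             impute = FALSE) {
  num <- as.data.frame(env)[, setdiff(colnames(env), exclude), drop = FALSE]
  num <- num[, vapply(num, is.numeric, logical(1)), drop = FALSE]
  if (ncol(num) == 0) stop("no numeric environmental variables")
  m <- as.matrix(num)
  if (anyNA(m)) {
    if (!impute) stop("missing environmental values (set impute = TRUE)")
    for (j in seq_len(ncol(m)))
      m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
  }
  if (standardize) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance variable(s): ",
              paste(colnames(m)[sds == 0], collapse = ", "))
      m <- m[, sds > 0, drop = FALSE]
    }
    if (ncol(m) > 0) m <- scale(m)
  }
  if (ncol(m) == 0) {
    # every variable constant: all samples environmentally identical
    d <- matrix(0, nrow(env), nrow(env))
    dimnames(d) <- list(rownames(env), rownames(env))
    return(d)
  }
  d <- as.matrix(dist(m))
  dimnames(d) <- list(rownames(env), rownames(env))
  d
}

#' Environmental heterogeneity index
#'
#' Per group (typically per season): the mean pairwise Euclidean distance
#' between samples' environmental vectors, the distance matrix being
#' computed within each group. High values mean sites experience
#' divergent conditions; 0 means all sites are environmentally identical.
#'
#' When `standardize = TRUE`, variables are z-scored across *all* samples
#' before the within-group distances are taken, so groups whose sites
#' spread more widely along the (shared) environmental axes score higher.
#' Standardizing within each group instead would make every group's index
#' scale-free and erase exactly the between-group differences the index
#' exists to measure.
#'
#' @inheritParams euclidean_matrix
#' @param grouping Named character vector mapping sample id to group;
#'   every group needs >= 2 samples.
#' @return `data.frame` with `group`, `heterogeneity` (H >= 0) and `n`.
#' @export
heterogeneity_index <- function(env, grouping, standardize = TRUE,
                                exclude = NULL) {
  if (is.null(rownames(env))) stop("`env` needs sample ids as row names")
  if (!all(rownames(env) %in% names(grouping)))
    stop("grouping missing for some samples")
  d_all <- euclidean_matrix(env, standardize = standardize,
                            exclude = exclude)
  groups <- unique(grouping[rownames(env)])
  out <- lapply(groups, function(g) {
    ids <- rownames(env)[grouping[rownames(env)] == g]
    if (length(ids) < 2) stop("group '", g, "' has fewer than 2 samples")
    d <- d_all[ids, ids, drop = FALSE]
    data.frame(group = g, heterogeneity = mean(d[upper.tri(d)]),
               n = length(ids), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the corresponding off-diagonal entries, with
#' significance from joint row/column permutations of the second matrix:
#' `p = (1 + #{perm r >= obs r}) / (n_perm + 1)`.
#'
#' @param d1,d2 Square symmetric matrices with identical ids in the same
#'   order.
#' @param n_perm Permutations (>= 99; default 999).
#' @param seed Integer seed.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("`n_perm` must be >= 99")
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dim(d1), dim(d2)))
    stop("distance matrices differ in dimension")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("distance matrices have mismatched ids")
  v1 <- d1[lower.tri(d1)]; v2 <- d2[lower.tri(d2)]
  if (sd(v1) == 0 || sd(v2) == 0) stop("constant distance vector")
  fit <- with_seed(seed,
    vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                  method = "pearson", permutations = n_perm))
  list(r = unname(fit$statistic), p = fit$signif, n_perm = n_perm)
}

#' Distance-distance regression
#'
#' Ordinary least squares of one distance matrix's upper triangle on
#' another's — the descriptive slope/R-squared fits used for
#' beta-diversity vs environmental-distance relationships. Pairwise
#' distances are dependent observations, so inference should come from
#' [mantel_test()], not from this fit.
#'
#' @param dx,dy Aligned square symmetric matrices (predictor, response).
#' @return List with `slope`, `intercept`, `r_squared`, `n_pairs`.
#' @export
distance_regression <- function(dx, dy) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  if (!identical(dim(dx), dim(dy))) stop("matrices differ in dimension")
  x <- dx[upper.tri(dx)]; y <- dy[upper.tri(dy)]
  if (length(x) < 3) stop("fewer than 3 pairs")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = summary(fit)$r.squared, n_pairs = length(x))
}
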