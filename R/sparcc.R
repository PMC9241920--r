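#' SparCC compositional correlations
#'
#' Estimates correlations between the latent absolute abundances
#' underlying compositional count data. Per estimation iteration, taxon
#' fractions are resampled from a Dirichlet posterior with a unit prior
#' (`counts + 1`), the log-ratio variance matrix
#' `t_ij = var(log(x_i / x_j))` is formed, and basis variances `w_i` are
#' obtained from the linear approximation that most pairs are
#' uncorrelated, giving `r_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))`
#' clipped to `[-1, 1]`. The most strongly correlated pair above
#' `exclusion_threshold` is then iteratively removed from the system and
#' the basis re-solved, weakening the sparsity assumption where it fails.
#' The reported estimate is the entrywise median over estimation
#' iterations.
#'
#' @param table Samples x taxa count matrix with at least 4 taxa.
#' @param n_iter Estimation (resampling) iterations; default 20.
#' @param n_exclude Maximum strong-pair exclusion rounds per iteration;
#'   default 10.
#' @param exclusion_threshold Absolute correlation above which a pair is
#'   eligible for exclusion; default 0.1.
#' @param seed Integer seed (drives the Dirichlet resampling).
#' @param zero_handling `"dirichlet"` (default) resamples fractions from
#'   the posterior, handling zeros without a fixed offset;
#'   `"pseudocount"` uses the deterministic `(counts + 1)` fractions.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sparcc <- function(table, n_iter = 20, n_exclude = 10,
                   exclusion_threshold = 0.1, seed = NULL,
                   zero_handling = c("dirichlet", "pseudocount")) {
  zero_handling <- match.arg(zero_handling)
  table <- as_otu_matrix(table)
  p <- ncol(table)
  if (p < 4) stop("SparCC needs at least 4 taxa")
  if (zero_handling == "pseudocount") n_iter <- 1L
  with_seed(seed, {
    est <- array(NA_real_, c(p, p, n_iter))
    for (k in seq_len(n_iter)) {
      f <- draw_fractions(table, zero_handling)
      est[, , k] <- sparcc_once(log(f), n_exclude, exclusion_threshold)
    }
    r <- apply(est, c(1, 2), median)
    r <- (r + t(r)) / 2
    diag(r) <- 1
    dimnames(r) <- list(colnames(table), colnames(table))
    r
  })
}

# Fractions per sample: Dirichlet(counts + 1) draw, or the posterior-mean
# pseudocount fractions.
draw_fractions <- function(table, zero_handling) {
  a <- table + 1
  if (zero_handling == "dirichlet") {
    g <- matrix(rgamma(length(a), shape = a), nrow(a), ncol(a))
    g / rowSums(g)
  } else {
    a / rowSums(a)
  }
}

# One SparCC basis solve with iterative strong-pair exclusion.
# `logf` is the samples x taxa matrix of log fractions.
sparcc_once <- function(logf, n_exclude, threshold) {
  p <- ncol(logf)
  C <- cov(logf)
  v <- diag(C)
  T_ <- outer(v, v, "+") - 2 * C   # variation matrix var(log(x_i/x_j))
  diag(T_) <- 0

  M <- matrix(1, p, p)
  diag(M) <- p - 1
  excluded <- matrix(FALSE, p, p)
  compute_r <- function() {
    t_i <- rowSums(T_ * !excluded)
    w <- solve(M, t_i)
    w <- pmax(w, 1e-10)
    r <- (outer(w, w, "+") - T_) / (2 * sqrt(outer(w, w)))
    pmin(pmax(r, -1), 1)
  }
  r <- compute_r()
  for (it in seq_len(n_exclude)) {
    a <- abs(r)
    diag(a) <- 0
    a[excluded] <- 0
    mx <- max(a)
    if (mx <= threshold) break
    ij <- which(a == mx, arr.ind = TRUE)[1L, ]
    i <- ij[1L]; j <- ij[2L]
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1
    M[j, i] <- M[j, i] - 1
    # a component excluded from nearly every pair leaves the system
    # ill-posed; stop excluding when any diagonal hits 3
    if (M[i, i] < 3 || M[j, j] < 3) break
    r <- compute_r()
  }
  r
}

#' SparCC bootstrap significance
#'
#' Two-sided pseudo p-values for [sparcc()] estimates: each bootstrap
#' permutes every taxon's counts across samples independently (destroying
#' all true associations while preserving marginal distributions) and
#' recomputes the correlation matrix;
#' `p = (#{|r_boot| >= |r_obs|} + 1) / (n_boot + 1)`.
#'
#' @inheritParams sparcc
#' @param n_boot Bootstrap datasets (>= 20; default 100).
#' @return List with `r` (observed matrix), `p` (p-value matrix), and
#'   `table`, a [correlation_table()] data frame with BH-adjusted `q`.
#' @export
sparcc_significance <- function(table, n_boot = 100, n_iter = 20,
                                n_exclude = 10, exclusion_threshold = 0.1,
                                seed = NULL) {
  if (n_boot < 20) stop("`n_boot` must be >= 20")
  table <- as_otu_matrix(table)
  r_obs <- sparcc(table, n_iter, n_exclude, exclusion_threshold,
                  seed = sub_seed(seed, 1L))
  n <- nrow(table)
  exceed <- matrix(0L, ncol(table), ncol(table))
  with_seed(sub_seed(seed, 2L), {
    for (b in seq_len(n_boot)) {
      perm <- apply(table, 2, function(x) x[sample.int(n)])
      rownames(perm) <- rownames(table)
      r_b <- sparcc(perm, n_iter, n_exclude, exclusion_threshold, seed = NULL)
      exceed <- exceed + (abs(r_b) >= abs(r_obs))
    }
  })
  p <- (exceed + 1) / (n_boot + 1)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(r_obs)
  list(r = r_obs, p = p, table = correlation_table(r_obs, p))
}

#' Long-form correlation table
#'
#' Flattens symmetric estimate/p-value matrices to one record per
#' unordered pair, with Benjamini-Hochberg FDR-adjusted `q` over all
#' tested pairs.
#'
#' @param r,p Symmetric matrices with shared dimnames.
#' @return `data.frame` with `id_a`, `id_b`, `estimate`, `p`, `q`.
#' @export
correlation_table <- function(r, p) {
  stopifnot(identical(dim(r), dim(p)))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(id_a = rownames(r)[ut[, 1L]],
                    id_b = colnames(r)[ut[, 2L]],
                    estimate = r[ut], p = p[ut],
                    stringsAsFactors = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  out
}
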