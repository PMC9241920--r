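#' Simulate a birth-death phylogeny
#'
#' Ultrametric tree for a regional species pool, the backbone for
#' phylogenetically conserved environmental optima and for the
#' phylogenetic null models downstream.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate,death_rate Speciation and extinction rates;
#'   `birth_rate > death_rate >= 0`.
#' @param seed Integer seed.
#' @return A rooted, ultrametric `"phylo"` tree with tips `otu1..otuN`.
#' @export
simulate_phylogeny <- function(n_taxa, birth_rate = 1, death_rate = 0, seed = NULL) {
  if (n_taxa < 2) stop("`n_taxa` must be >= 2")
  if (!(birth_rate > death_rate && death_rate >= 0))
    stop("require birth_rate > death_rate >= 0")
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth_rate, death_rate))
  tree$tip.label <- paste0("otu", seq_len(n_taxa))
  tree
}

# Rescale a tree so its maximum root-to-tip depth is `height`.
scale_tree_height <- function(tree, height = 1) {
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (height / h)
  tree
}

#' Evolve environmental optima along a phylogeny
#'
#' Brownian-motion trait evolution: each tip's optimum is the root value
#' plus independent zero-mean increments with variance
#' `brownian_rate * branch_length` along its root path. This is what makes
#' niche positions phylogenetically conserved, and hence makes betaNTI
#' sensitive to environmental filtering.
#'
#' With `eb_decay > 0` the process follows the early-burst (ACDC) variant:
#' the instantaneous rate declines exponentially with time since the root,
#' `rate(t) = brownian_rate * exp(-eb_decay * t)`, so an edge running from
#' depth t0 to t1 contributes variance
#' `brownian_rate * (exp(-eb_decay * t0) - exp(-eb_decay * t1)) / eb_decay`.
#' Niche differences then concentrate on deep splits — clades hold distinct
#' optima while close relatives are near-identical, the classic
#' adaptive-radiation form of niche conservatism.
#'
#' @param tree A `"phylo"` tree.
#' @param brownian_rate Variance accumulated per unit branch length at the
#'   root (>= 0).
#' @param root_value Ancestral optimum.
#' @param eb_decay Early-burst decay rate (>= 0); 0 is plain Brownian
#'   motion.
#' @param seed Integer seed.
#' @return Named numeric vector of optima, one per tip.
#' @export
evolve_optima <- function(tree, brownian_rate, root_value = 0,
                          eb_decay = 0, seed = NULL) {
  if (brownian_rate < 0) stop("`brownian_rate` must be >= 0")
  if (eb_decay < 0) stop("`eb_decay` must be >= 0")
  with_seed(seed, {
    n <- length(tree$tip.label)
    depth <- ape::node.depth.edgelength(tree)
    val <- numeric(n + tree$Nnode)
    val[n + 1L] <- root_value
    edges <- reorder(tree, "postorder")$edge
    # preorder: visit parents before children
    for (k in rev(seq_len(nrow(edges)))) {
      par <- edges[k, 1L]; child <- edges[k, 2L]
      v <- if (eb_decay > 0)
        brownian_rate * (exp(-eb_decay * depth[par]) -
                         exp(-eb_decay * depth[child])) / eb_decay
      else brownian_rate * (depth[child] - depth[par])
      val[child] <- val[par] + rnorm(1L, 0, sqrt(v))
    }
    setNames(val[seq_len(n)], tree$tip.label)
  })
}

#' Generate site-by-season environment tables
#'
#' One sample per site x season. Within each season, site values of the
#' dominant axis ("temperature") are drawn around the season mean with a
#' season-specific spread, so seasons differ in environmental
#' heterogeneity. Optional auxiliary variables are correlated with the
#' main axis plus noise, mimicking covarying water-chemistry measurements.
#'
#' @param n_sites Sites per season.
#' @param n_seasons Number of seasons; 4 gives winter/spring/summer/autumn
#'   labels, otherwise `season1..`.
#' @param season_means Numeric vector (recycled) of per-season means of the
#'   environmental axis.
#' @param season_spreads Numeric vector (recycled) of per-season standard
#'   deviations across sites; 0 makes all sites identical.
#' @param n_aux Number of auxiliary correlated variables.
#' @param aux_weight Loading of auxiliary variables on the main axis (the
#'   remainder is independent noise).
#' @param seed Integer seed.
#' @return `data.frame` with row names = sample ids and columns `site`,
#'   `season`, `temperature`, and `aux1..`.
#' @export
generate_environments <- function(n_sites, n_seasons = 4,
                                  season_means = 0, season_spreads = 1,
                                  n_aux = 0, aux_weight = 0.7, seed = NULL) {
  if (any(season_spreads < 0)) stop("spreads must be >= 0")
  seasons <- if (n_seasons == 4) c("winter", "spring", "summer", "autumn")
             else paste0("season", seq_len(n_seasons))
  means <- rep_len(season_means, n_seasons)
  spreads <- rep_len(season_spreads, n_seasons)
  with_seed(seed, {
    rows <- lapply(seq_len(n_seasons), function(s) {
      temp <- rnorm(n_sites, means[s], spreads[s])
      df <- data.frame(site = paste0("site", seq_len(n_sites)),
                       season = seasons[s], temperature = temp,
                       stringsAsFactors = FALSE)
      if (n_aux > 0) {
        z <- if (spreads[s] > 0) (temp - means[s]) / spreads[s] else rep(0, n_sites)
        for (a in seq_len(n_aux)) {
          df[[paste0("aux", a)]] <- aux_weight * z * spreads[s] +
            sqrt(1 - aux_weight^2) * rnorm(n_sites, sd = max(spreads[s], 1e-8))
        }
      }
      rownames(df) <- paste0(seasons[s], "_", df$site)
      df
    })
    do.call(rbind, rows)
  })
}

#' Assemble local communities under filtering and drift
#'
#' For every sample in `env`, a local community of `community_size`
#' individuals is drawn from the regional pool with weight proportional to
#' `pool_abundance * exp(-(optimum - E)^2 / (2 * filter_width^2))` — a
#' Gaussian niche kernel around the sample's environment `E` — and then
#' subjected to `drift_generations` generations of zero-sum Moran drift
#' (one generation = `community_size` single birth-death replacements).
#' `filter_width = Inf` disables selection entirely; `drift_generations = 0`
#' gives pure environmental filtering.
#'
#' @param tree Regional-pool phylogeny (tips = taxa).
#' @param optima Named per-taxon environmental optima covering the tips.
#' @param env Environment table with a `temperature` column and sample ids
#'   as row names (see [generate_environments()]).
#' @param community_size Individuals per local community (J).
#' @param filter_width Niche-filter width w > 0; smaller is stronger
#'   filtering.
#' @param drift_generations Generations of neutral drift G >= 0.
#' @param pool_abundance Regional-pool relative abundances (named, or
#'   unnamed in tip order). Default: a lognormal species-abundance
#'   distribution (`sdlog = 1.2`) drawn once per call.
#' @param lottery_concentration Site-level dispersal-lottery strength:
#'   when finite, each site's sampling weights are drawn from a
#'   Dirichlet distribution centred on the filtered pool weights with
#'   this concentration (Dirichlet-multinomial sampling). Small values
#'   mean few colonists found each community, so sites dominated by
#'   different members of the eligible pool; `Inf` (default) disables
#'   the lottery (plain multinomial sampling).
#' @param seed Integer seed.
#' @return A `driftnet_sim` list: `otu` (samples x taxa counts), `tree`,
#'   `env`, `optima`, `pool`, and the generating parameters.
#' @export
assemble_metacommunity <- function(tree, optima, env, community_size = 1000,
                                   filter_width = Inf, drift_generations = 0,
                                   pool_abundance = NULL,
                                   lottery_concentration = Inf, seed = NULL) {
  if (filter_width <= 0) stop("`filter_width` must be > 0")
  if (lottery_concentration <= 0) stop("`lottery_concentration` must be > 0")
  if (drift_generations < 0) stop("`drift_generations` must be >= 0")
  taxa <- tree$tip.label
  if (!all(taxa %in% names(optima)))
    stop("optima missing for some tree tips")
  optima <- optima[taxa]
  if (!("temperature" %in% colnames(env)))
    stop("`env` must contain a `temperature` column")

  with_seed(seed, {
    pool <- if (is.null(pool_abundance)) {
      p <- rlnorm(length(taxa), meanlog = 0, sdlog = 1.2)
      p / sum(p)
    } else {
      p <- if (!is.null(names(pool_abundance))) pool_abundance[taxa] else pool_abundance
      if (length(p) != length(taxa) || anyNA(p) || any(p < 0))
        stop("invalid `pool_abundance`")
      p / sum(p)
    }
    otu <- matrix(0L, nrow(env), length(taxa),
                  dimnames = list(rownames(env), taxa))
    for (s in seq_len(nrow(env))) {
      E <- env$temperature[s]
      lw <- log(pool)
      if (is.finite(filter_width))
        lw <- lw - (optima - E)^2 / (2 * filter_width^2)
      w <- exp(lw - max(lw))
      if (!any(w > 0)) stop("empty community: all filtering weights are zero")
      if (is.finite(lottery_concentration)) {
        alpha <- lottery_concentration * w / sum(w)
        w <- rgamma(length(alpha), shape = alpha)
        if (!any(w > 0)) w <- exp(lw - max(lw))
      }
      counts <- as.integer(rmultinom(1L, community_size, w))
      if (drift_generations > 0)
        counts <- .moran_drift_cpp(counts,
                                   drift_generations * community_size)
      otu[s, ] <- counts
    }
    structure(list(otu = otu, tree = tree, env = env, optima = optima,
                   pool = setNames(pool, taxa),
                   params = list(community_size = community_size,
                                 filter_width = filter_width,
                                 drift_generations = drift_generations)),
              class = "driftnet_sim")
  })
}

#' Simulate a metacommunity under a named assembly regime
#'
#' Convenience front end bundling phylogeny simulation, Brownian optima,
#' environment generation and community assembly into the three canonical
#' regimes used for validating the process classifier:
#'
#' * `"heterogeneous_selection"` — strong filtering (w = 1 vs a tip-optima
#'   SD of ~3) across divergent site environments (spread 3), no drift;
#' * `"homogeneous_selection"` — the same strong filter but identical
#'   environments at every site;
#' * `"drift"` — no filtering (w = Inf), identical environments, and
#'   prolonged neutral drift.
#'
#' Regional-pool optima are evolved under the early-burst model
#' (`eb_decay = 6`), giving clade-structured niches. The heterogeneous
#' regime spreads site environments widely (SD 3) around the pool's
#' median optimum so different sites select different clades. The
#' homogeneous regime places every site at the centre of the pool's
#' tightest 40-taxon niche cluster with a filter just wide enough to
#' cover it, and uses small local communities (J = 50) so that
#' multinomial sampling turns over membership *within* the selected
#' clade — different members, same lineage — which is the homogeneous
#' selection signature. The drift regime removes the filter and runs
#' sustained neutral drift (two complete community turnovers) instead;
#' much longer drift drives divergence beyond the stochastic null
#' envelope and increasingly reads as dispersal limitation.
#'
#' @param regime One of the three regime names.
#' @param n_taxa Regional pool size.
#' @param n_sites Local communities (one sample each).
#' @param seed Integer master seed (stages use derived sub-seeds).
#' @return A `driftnet_sim` with `$true_regime` set.
#' @export
simulate_regime <- function(regime = c("heterogeneous_selection",
                                       "homogeneous_selection", "drift"),
                            n_taxa = 150, n_sites = 15, seed = 1) {
  regime <- match.arg(regime)
  tree <- scale_tree_height(
    simulate_phylogeny(n_taxa, seed = sub_seed(seed, 1L)))
  optima <- evolve_optima(tree, brownian_rate = 9, eb_decay = 6,
                          seed = sub_seed(seed, 2L))
  # regime settings: niche width w, drift generations G, community size J,
  # pool-abundance skew, and spread of site environments
  if (regime == "homogeneous_selection") {
    # centre of the tightest 40-taxon cluster of optima, filter sized to it
    k <- min(40L, n_taxa - 1L)
    o <- sort(optima)
    widths <- o[k:n_taxa] - o[seq_len(n_taxa - k + 1L)]
    i <- which.min(widths)
    centre <- (o[i] + o[i + k - 1L]) / 2
    cfg <- list(w = max(widths[i] / 2, 0.1), G = 0, J = 50,
                sdlog = 0.3, spread = 0, centre = centre)
  } else if (regime == "heterogeneous_selection") {
    cfg <- list(w = 1, G = 0, J = 1000, sdlog = 1.2, spread = 3,
                centre = median(optima))
  } else {
    cfg <- list(w = Inf, G = 2, J = 500, sdlog = 1.2, spread = 0,
                centre = median(optima))
  }
  env <- generate_environments(n_sites, n_seasons = 1,
                               season_means = cfg$centre,
                               season_spreads = cfg$spread,
                               seed = sub_seed(seed, 3L))
  pool <- with_seed(sub_seed(seed, 5L), {
    p <- rlnorm(n_taxa, 0, cfg$sdlog)
    p / sum(p)
  })
  sim <- assemble_metacommunity(tree, optima, env,
                                community_size = cfg$J,
                                filter_width = cfg$w,
                                drift_generations = cfg$G,
                                pool_abundance = pool,
                                seed = sub_seed(seed, 4L))
  sim$true_regime <- regime
  sim
}

#' Simulate a full seasonal survey
#'
#' A multi-season, multi-site dataset for end-to-end pipeline runs:
#' seasons differ in environmental heterogeneity (high-spread "winter",
#' low-spread "summer"), with filtering strength fixed, so cold seasons
#' are selection-dominated and warm seasons drift towards stochasticity.
#'
#' @param n_taxa,n_sites Pool and site counts.
#' @param season_means,season_spreads Per-season environment axis
#'   parameters (defaults: means 2/8/16/10, spreads 3/1.5/0.3/1.5 for
#'   winter/spring/summer/autumn).
#' @param filter_width,drift_generations,community_size Assembly settings
#'   applied to every sample.
#' @param n_aux Auxiliary environment variables (for heterogeneity
#'   indices over several covarying factors).
#' @param seed Master seed.
#' @return A `driftnet_sim` (with multi-season `env`).
#' @export
simulate_survey <- function(n_taxa = 150, n_sites = 13,
                            season_means = c(2, 8, 16, 10),
                            season_spreads = c(3, 1.5, 0.3, 1.5),
                            filter_width = 2, drift_generations = 2,
                            community_size = 1000, n_aux = 3, seed = 1) {
  tree <- scale_tree_height(
    simulate_phylogeny(n_taxa, seed = sub_seed(seed, 1L)))
  optima <- evolve_optima(tree, brownian_rate = 25, root_value = 9,
                          seed = sub_seed(seed, 2L))
  env <- generate_environments(n_sites, n_seasons = 4,
                               season_means = season_means,
                               season_spreads = season_spreads,
                               n_aux = n_aux, seed = sub_seed(seed, 3L))
  assemble_metacommunity(tree, optima, env, community_size = community_size,
                         filter_width = filter_width,
                         drift_generations = drift_generations,
                         seed = sub_seed(seed, 4L))
}

#' Simulate compositional count data with known basis correlations
#'
#' Absolute ("basis") abundances are log-normal: each taxon's
#' log-abundance is drawn per sample with its own mean and a common
#' log-scale standard deviation; selected taxon pairs get a bivariate
#' normal log-correlation. Samples are then closed to fractions and
#' counted by multinomial sequencing at a fixed depth — the regime SparCC
#' is designed for, where naive correlations on proportions are distorted
#' by closure.
#'
#' @param n_taxa,n_samples Dimensions.
#' @param depth Reads per sample.
#' @param cor_pairs Data frame with columns `a`, `b`, `rho`: basis
#'   log-correlations to impose on disjoint taxon pairs.
#' @param meanlog_sd Spread of per-taxon mean log-abundances.
#' @param sdlog Common per-sample log-scale SD.
#' @param seed Integer seed.
#' @return List with `counts` (samples x taxa), `fractions`, and `basis`
#'   (the latent log-abundance matrix).
#' @export
simulate_compositional <- function(n_taxa, n_samples, depth = 20000,
                                   cor_pairs = NULL, meanlog_sd = 1,
                                   sdlog = 0.7, seed = NULL) {
  with_seed(seed, {
    mu <- rnorm(n_taxa, 0, meanlog_sd)
    z <- matrix(rnorm(n_samples * n_taxa), n_samples, n_taxa)
    if (!is.null(cor_pairs)) {
      for (k in seq_len(nrow(cor_pairs))) {
        a <- cor_pairs$a[k]; b <- cor_pairs$b[k]; rho <- cor_pairs$rho[k]
        z[, b] <- rho * z[, a] + sqrt(1 - rho^2) * z[, b]
      }
    }
    logabund <- sweep(z * sdlog, 2, mu, "+")
    frac <- exp(logabund)
    frac <- frac / rowSums(frac)
    counts <- t(apply(frac, 1, function(p) rmultinom(1, depth, p)))
    dimnames(counts) <- list(paste0("s", seq_len(n_samples)),
                             paste0("t", seq_len(n_taxa)))
    list(counts = counts, fractions = frac, basis = logabund)
  })
}
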