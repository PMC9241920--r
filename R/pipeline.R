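# Tabular output with `# key=value` header comments so runs diff cleanly.
write_tsv_commented <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(paste0("# ", k, "=", meta[[k]]), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Either
#' `simulate = TRUE` (synthetic survey via [simulate_survey()], arguments
#' in `sim`) or the three input paths must be given.
#'
#' @param simulate Generate the dataset instead of reading it.
#' @param sim Named list of [simulate_survey()] arguments.
#' @param table_path,tree_path,env_path Input files (OTU TSV, Newick,
#'   CSV) when `simulate = FALSE`.
#' @param grouping_column Environment column defining groups (default
#'   `"season"`).
#' @param rarefy_depth Reads per sample for rarefaction; `NULL` skips.
#' @param min_total Prevalence filter applied before network inference.
#' @param reps Null-model replicates for betaNTI / Raup-Crick.
#' @param n_boot SparCC bootstraps.
#' @param r_min,p_max SparCC network retention thresholds.
#' @param n_perm Mantel permutations.
#' @param standardize Standardize environment variables.
#' @param exclude_vars Environment variables excluded from heterogeneity
#'   and Mantel distances.
#' @param seed Master seed; every stochastic stage derives its own
#'   sub-seed, all recorded in the run manifest.
#' @return A validated `driftnet_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, sim = list(),
                            table_path = NULL, tree_path = NULL,
                            env_path = NULL, grouping_column = "season",
                            rarefy_depth = NULL, min_total = 10,
                            reps = 199, n_boot = 50, r_min = 0.5,
                            p_max = 0.05, n_perm = 999,
                            standardize = TRUE, exclude_vars = NULL,
                            seed = 1) {
  if (!simulate) {
    paths <- list(table = table_path, tree = tree_path, env = env_path)
    for (nm in names(paths))
      if (is.null(paths[[nm]]) || !file.exists(paths[[nm]]))
        stop("config error: missing ", nm, " input file when simulate = FALSE")
  }
  structure(as.list(environment()), class = "driftnet_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> assembly null models -> per-group
#' co-occurrence networks -> environmental statistics, writing
#' plain-text results and a JSON manifest (parameters, seeds, file
#' hashes) to `out_dir`. Rerunning with the same configuration reproduces
#' byte-identical tabular outputs.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "driftnet_config")) stop("config error: not a pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  data <- run_stage("input", {
    if (config$simulate) {
      sim <- do.call(simulate_survey,
                     c(config$sim, list(seed = sub_seed(seed, 1L))))
      list(otu = sim$otu, tree = sim$tree, env = sim$env)
    } else {
      list(otu = read_otu_table(config$table_path),
           tree = read_newick(config$tree_path),
           env = read_env_table(config$env_path))
    }
  })
  otu <- data$otu
  env <- data$env
  grouping <- setNames(as.character(env[[config$grouping_column]]),
                       rownames(env))
  if (!is.null(config$rarefy_depth))
    otu <- run_stage("rarefy",
      rarefy(otu, config$rarefy_depth, seed = sub_seed(seed, 2L),
             drop_below = TRUE))

  run_stage("assembly", {
    res <- assembly_processes(otu, data$tree, grouping = grouping,
                              reps = config$reps, seed = sub_seed(seed, 3L))
    meta <- list(stage = "assembly", reps = config$reps,
                 seed = sub_seed(seed, 3L))
    write_tsv_commented(matrix_to_long(res$bnti, "bnti"),
                        file.path(out_dir, "bnti.tsv"), meta)
    write_tsv_commented(matrix_to_long(res$rc, "rc"),
                        file.path(out_dir, "rc.tsv"), meta)
    write_tsv_commented(res$pairs, file.path(out_dir, "labels.tsv"), meta)
    write_tsv_commented(res$summary,
                        file.path(out_dir, "process_summary.tsv"), meta)
  })

  run_stage("network", {
    filt <- filter_prevalence(otu, config$min_total)
    stats_rows <- list()
    for (g in unique(grouping)) {
      ids <- names(grouping)[grouping == g]
      sub <- filt[ids, colSums(filt[ids, , drop = FALSE]) > 0, drop = FALSE]
      sig <- sparcc_significance(sub, n_boot = config$n_boot,
                                 seed = sub_seed(seed, 4L))
      net <- build_network(sig$table, r_min = config$r_min,
                           p_max = config$p_max)
      if (igraph::vcount(net) > 0)
        write_graph_file(net, file.path(out_dir, paste0("network_", g, ".gml")))
      ts <- topology_stats(net)
      row <- cbind(group = g, ts$network)
      row$modularity <- if (igraph::vcount(net) > 1)
        attr(louvain_modules(net, seed = sub_seed(seed, 5L)),
             "modularity") else NA_real_
      row$n_keystones <- length(identify_keystones(net))
      stats_rows[[g]] <- row
    }
    write_tsv_commented(do.call(rbind, stats_rows),
                        file.path(out_dir, "network_stats.tsv"),
                        list(stage = "network", r_min = config$r_min,
                             p_max = config$p_max, n_boot = config$n_boot))
  })

  run_stage("envstats", {
    het <- heterogeneity_index(env, grouping,
                               standardize = config$standardize,
                               exclude = config$exclude_vars)
    write_tsv_commented(het, file.path(out_dir, "heterogeneity.tsv"),
                        list(stage = "envstats",
                             standardize = config$standardize))
    bc <- bray_curtis(otu)
    ed <- euclidean_matrix(env, standardize = config$standardize,
                           exclude = config$exclude_vars)
    mt <- mantel_test(ed, bc, n_perm = config$n_perm,
                      seed = sub_seed(seed, 6L))
    write_tsv_commented(
      data.frame(comparison = "bray_curtis_vs_environment",
                 r = mt$r, p = mt$p, n_perm = mt$n_perm),
      file.path(out_dir, "mantel.tsv"), list(stage = "envstats"))
  })

  run_stage("manifest", {
    outputs <- list.files(out_dir, full.names = TRUE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("driftnet")),
      seed = seed,
      stage_seeds = setNames(lapply(1:6, function(i) sub_seed(seed, i)),
                             c("input", "rarefy", "assembly", "network",
                               "modules", "mantel")),
      parameters = config[setdiff(names(config), c("sim"))],
      outputs = as.list(tools::md5sum(outputs)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  })
  invisible(out_dir)
}

# Long form (sample_a, sample_b, value) of a symmetric matrix's upper
# triangle, for diff-friendly TSV output.
matrix_to_long <- function(m, value_name) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  out <- data.frame(sample_a = rownames(m)[ut[, 1L]],
                    sample_b = colnames(m)[ut[, 2L]],
                    value = m[ut], stringsAsFactors = FALSE)
  names(out)[3L] <- value_name
  out
}
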