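write_tsv_with_manifest <- function(df, path, checksum_note) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", checksum_note), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run a configured experiment
#'
#' Dispatches a [load_config()] configuration to the appropriate module,
#' aggregates multi-seed runs, writes TSV outputs plus a JSON run manifest
#' (full parameter echo, seeds, package version, timestamp, per-output
#' checksums) into `out_dir`, and returns the summary invisibly. Module
#' flags (unresolved trajectories, non-converged lattice runs) are
#' surfaced in the manifest.
#'
#' @param config A `"cp_config"` object.
#' @param out_dir Output directory (created if missing).
#' @return The experiment summary (list), invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "cp_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  game <- config$game
  seeds <- config$seeds
  flags <- character(0)
  files <- character(0)
  summary <- list()

  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_with_manifest(df, path,
                            paste("condpunish", packageVersion("condpunish")))
    files <<- c(files, path)
  }

  if (config$experiment == "trajectory") {
    state0 <- unlist(config_field(config, "settings", "state0",
                                  c(0.25, 0.25, 0.25, 0.25)))
    tr <- integrate_replicator(state0, game,
      t_max = config_field(config, "integration", "t_max", 1e4),
      rtol = config_field(config, "integration", "rtol", 1e-8),
      atol = config_field(config, "integration", "atol", 1e-10))
    emit(data.frame(t = tr$times, tr$states), "trajectory.tsv")
    if (tr$terminal_class == "UNRESOLVED") flags <- c(flags, "UNRESOLVED")
    summary <- list(terminal_class = tr$terminal_class,
                    final_state = as.list(tr$states[nrow(tr$states), ]))
  } else if (config$experiment %in% c("basin", "face_basin")) {
    n_samples <- config_field(config, "settings", "n_samples", 10000)
    face <- unlist(config_field(config, "settings", "strategies",
                                if (config$experiment == "face_basin")
                                  c("C", "D", "P") else strategies()))
    res <- lapply(seeds, function(sd)
      basin_fraction(game, n_samples = n_samples, seed = sd,
                     strategies_used = face))
    coop <- vapply(res, `[[`, numeric(1), "cooperative_fraction")
    unres <- vapply(res, `[[`, numeric(1), "unresolved")
    if (any(unres > 0))
      flags <- c(flags, sprintf("%d unresolved trajectories", sum(unres)))
    emit(data.frame(seed = seeds, cooperative_fraction = coop,
                    defection_fraction = vapply(res, `[[`, numeric(1),
                                                "defection_fraction"),
                    unresolved = unres, n_samples = n_samples),
         "basin.tsv")
    summary <- list(cooperative_fraction = mean(coop),
                    defection_fraction = mean(vapply(res, `[[`, numeric(1),
                                                     "defection_fraction")),
                    unresolved = sum(unres),
                    n_samples = n_samples * length(seeds), seeds = seeds)
  } else if (config$experiment == "fixation") {
    N <- config_field(config, "evo", "N", 100)
    s <- config_field(config, "evo", "s", 2)
    pairs <- expand.grid(resident = strategies(), mutant = strategies(),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$resident != pairs$mutant, ]
    pairs$rho <- mapply(function(i, j)
      fixation_probability(i, j, game, N, s), pairs$resident, pairs$mutant)
    emit(pairs, "fixation.tsv")
    summary <- list(N = N, s = s, fixation = pairs)
  } else if (config$experiment == "stationary") {
    N <- config_field(config, "evo", "N", 100)
    s <- config_field(config, "evo", "s", 2)
    ch <- embedded_markov_chain(game, N, s)
    emit(as.data.frame(ch$transition_matrix), "transition_matrix.tsv")
    emit(data.frame(state = names(ch$stationary),
                    probability = as.numeric(ch$stationary)),
         "stationary.tsv")
    summary <- list(N = N, s = s,
                    stationary = as.list(ch$stationary))
  } else if (config$experiment == "simulate_wm") {
    N <- config_field(config, "evo", "N", 100)
    init <- unlist(config_field(config, "settings", "initial_counts",
                                rep(N %/% 4, 4)))
    runs <- lapply(seeds, function(sd) {
      ev <- evo_params(s = config_field(config, "evo", "s", 2),
                       mu = config_field(config, "evo", "mu", 1e-3),
                       n_steps = config_field(config, "evo", "n_steps", 2e5),
                       seed = sd)
      simulate_wellmixed(game, ev, init)
    })
    for (k in seq_along(runs))
      emit(runs[[k]], sprintf("wellmixed_seed%d.tsv", seeds[k]))
    fr <- t(vapply(runs, function(r)
      colMeans(r[, c("X", "Y", "Z", "W")]) / N, numeric(4)))
    summary <- list(mean_frequencies = as.list(colMeans(fr)),
                    sd_frequencies = as.list(apply(fr, 2, stats::sd)),
                    seeds = seeds)
  } else {  # equilibrium_freqs
    L <- config_field(config, "lattice", "L", 100)
    n_mcs <- config_field(config, "lattice", "n_mcs", 2e4)
    s <- config_field(config, "lattice", "s", 2)
    strategy_set <- unlist(config_field(config, "lattice", "strategy_set",
                                        strategies()))
    runs <- lapply(seeds, function(sd)
      run_mcs(NULL, game, s = s, n_mcs = n_mcs, seed = sd, L = L,
              strategy_set = strategy_set))
    for (k in seq_along(runs))
      emit(runs[[k]]$frequencies, sprintf("lattice_seed%d.tsv", seeds[k]))
    eq <- withCallingHandlers(
      equilibrium_frequencies(runs),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    summary <- list(mean = as.list(eq$mean), sd = as.list(eq$sd),
                    converged = eq$converged, seeds = seeds, L = L,
                    n_mcs = n_mcs)
  }

  manifest <- list(
    package = "condpunish",
    version = as.character(packageVersion("condpunish")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    game = unclass(game),
    dynamics = config$dynamics,
    experiment = config$experiment,
    seeds = seeds,
    flags = flags,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    summary = summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(flags) > 0)
    warning("experiment completed with flags: ",
            paste(flags, collapse = "; "))
  invisible(summary)
}
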