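#' Load a run configuration
#'
#' Reads a YAML configuration with sections `game` (the [game_params()]
#' fields), `dynamics` (`"replicator"`, `"finite_wm"` or `"lattice"`),
#' `experiment` (`"trajectory"`, `"basin"`, `"face_basin"`, `"fixation"`,
#' `"stationary"`, `"simulate_wm"` or `"equilibrium_freqs"`), an optional
#' `evo`/`integration`/`lattice` section with the regime-specific
#' settings, and `seeds` (explicit integer vector; no silent entropy).
#' All game-parameter invariants are enforced at load time and violations
#' name the broken constraint.
#'
#' @param path Path to the YAML file.
#' @return A validated list of class `"cp_config"`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (sec in c("game", "dynamics", "experiment"))
    if (is.null(raw[[sec]])) stop("config is missing the '", sec, "' section")
  game <- do.call(game_params, raw$game)
  dynamics <- match.arg(raw$dynamics, c("replicator", "finite_wm", "lattice"))
  experiment <- match.arg(raw$experiment,
                          c("trajectory", "basin", "face_basin", "fixation",
                            "stationary", "simulate_wm", "equilibrium_freqs"))
  seeds <- raw$seeds
  if (is.null(seeds)) stop("config must list explicit seeds")
  seeds <- as.integer(seeds)
  ok <- switch(experiment,
    trajectory = , basin = , face_basin = dynamics == "replicator",
    fixation = , stationary = , simulate_wm = dynamics == "finite_wm",
    equilibrium_freqs = dynamics == "lattice")
  if (!ok)
    stop("experiment '", experiment, "' does not belong to dynamics '",
         dynamics, "'")
  structure(list(game = game, dynamics = dynamics, experiment = experiment,
                 evo = raw$evo, integration = raw$integration,
                 lattice = raw$lattice, settings = raw$settings,
                 seeds = seeds),
            class = "cp_config")
}

config_field <- function(config, section, name, default) {
  v <- config[[section]][[name]]
  if (is.null(v)) default else v
}
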