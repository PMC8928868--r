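#' Experiment configuration
#'
#' A `scenario_config` bundles a full model parameter set with an
#' experiment name and experiment-specific settings. Configurations are
#' plain YAML on disk: the nine model-parameter keys (`alpha`, `beta`,
#' `delta`, `mu`, `tau`, `sigma`, `rho`, `T`, `t_l`) at the top level plus
#' an `experiment` key and an optional `settings` block. Omitted model
#' parameters take the package defaults ([model_params()]); `tau` may be
#' omitted for the `ess` experiment, where it is the solved-for quantity.
#'
#' @param experiment One of `"simulate"`, `"bifurcation"`,
#'   `"phase_diagram"`, `"ess"`, `"invade"`, `"evolve"`.
#' @param params A [model_params()] object.
#' @param settings Named list of experiment-specific settings.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(experiment, params = model_params(),
                            settings = list()) {
  experiments <- c("simulate", "bifurcation", "phase_diagram", "ess",
                   "invade", "evolve")
  if (!is.character(experiment) || length(experiment) != 1L ||
      !experiment %in% experiments) {
    stop("'experiment' must be one of: ", paste(experiments, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(inherits(params, "model_params"), is.list(settings))
  structure(list(experiment = experiment, params = params,
                 settings = settings), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$experiment, "\n")
  print(x$params)
  if (length(x$settings)) {
    cat("  settings:", paste(names(x$settings), collapse = ", "), "\n")
  }
  invisible(x)
}

.param_keys <- c("alpha", "beta", "delta", "mu", "tau", "sigma", "rho",
                 "T", "t_l")

#' Read a scenario configuration from YAML
#'
#' Reads and fully validates a configuration file. Unknown top-level keys
#' are an error (naming the key); missing model parameters are filled with
#' the package defaults; the phenological invariant `t_l <= T` and
#' positivity of all rates are enforced before any computation starts.
#' An empty file yields the default parameter set and the `simulate`
#' experiment.
#'
#' @param path Path to a YAML file.
#' @return A [scenario_config()].
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("tau: 3.1\nexperiment: simulate", f)
#' load_config(f)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c(.param_keys, "experiment", "settings")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  experiment <- raw$experiment %||% "simulate"
  defaults <- unclass(model_params())
  vals <- defaults
  for (k in intersect(names(raw), .param_keys)) {
    v <- raw[[k]]
    if (!is.numeric(v) || length(v) != 1L) {
      stop("config key '", k, "' must be a single number", call. = FALSE)
    }
    vals[[k]] <- as.numeric(v)
  }
  if (experiment == "ess" && !"tau" %in% names(raw)) {
    vals$tau <- defaults$tau   # placeholder; ess solves for tau
  }
  params <- tryCatch(do.call(model_params, vals), error = function(e) {
    stop("invalid configuration: ", conditionMessage(e), call. = FALSE)
  })
  scenario_config(experiment, params,
                  settings = raw$settings %||% list())
}

#' Write a scenario configuration to YAML
#'
#' @param config A [scenario_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  out <- c(unclass(config$params),
           list(experiment = config$experiment))
  if (length(config$settings)) out$settings <- config$settings
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Built-in reference scenarios
#'
#' Named, version-controlled configurations for the package's headline
#' experiments in the short-season, synchronous-emergence environment
#' (`T = 4`, `t_l = 1`): the bifurcation scan over the virulence trait,
#' the quasiperiodic reference run at `tau = 2.8`, the phenological phase
#' diagram, the cycle-phase invasion experiment (resident `tau = 2.8`,
#' mutant `tau = 2.81`), and the paired adaptive-walk experiments with and
#' without host demographic feedback.
#'
#' @return A named list of [scenario_config()] objects.
#' @examples
#' names(reference_scenarios())
#' @export
reference_scenarios <- function() {
  base <- model_params()  # tau = 2.8, T = 4, t_l = 1 reference environment
  list(
    fig2_bifurcation = scenario_config(
      "bifurcation", base,
      settings = list(tau_min = 2.5, tau_max = 3.5, tau_step = 0.01,
                      burn_in = 800, window = 100)),
    fig2_cycling_run = scenario_config(
      "simulate", base,
      settings = list(n_seasons = 900, burn_in = 800, window = 100)),
    fig3_phase = scenario_config(
      "phase_diagram", base,
      settings = list(T_grid = c(3, 4, 5, 6, 8), t_l_grid = c(0.5, 1, 2, 3))),
    fig4_invasion = scenario_config(
      "invade", base,
      settings = list(resident_tau = 2.8, mutant_tau = 2.81,
                      intro_seasons = 12, burn_in = 800)),
    fig5_cycling_evolution = scenario_config(
      "evolve", base,
      settings = list(n_replicates = 12, seed = 1, offset = 0.5,
                      mutant_interval_seasons = 1000,
                      first_mutant_season = 100, mutation_sd = 0.1,
                      extinction_threshold = 1, constant_cohort = FALSE)),
    fig5_stable_evolution = scenario_config(
      "evolve", base,
      settings = list(n_replicates = 12, seed = 1, offset = 0.5,
                      mutant_interval_seasons = 1000,
                      first_mutant_season = 100, mutation_sd = 0.1,
                      extinction_threshold = 1, constant_cohort = TRUE))
  )
}

#' Run a configured experiment
#'
#' Dispatches a [scenario_config()] to the corresponding analysis function
#' and (optionally) writes tidy CSV results plus the fully resolved
#' configuration to an output directory, so every run is reproducible from
#' its own provenance files.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed for stochastic experiments.
#' @param out_dir Optional output directory; created if missing. Results
#'   are written as `results.csv` with the resolved configuration in
#'   `config.resolved.yaml`.
#' @return The experiment's result tibble, invisibly when `out_dir` is
#'   given.
#' @export
run_scenario <- function(config, seed = 1, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  p <- config$params
  s <- config$settings
  num <- function(key, default) as.numeric(s[[key]] %||% default)
  res <- switch(
    config$experiment,
    simulate = {
      n <- num("n_seasons", 900)
      ser <- iterate_seasons(p, n = n)
      cls <- classify_dynamics(ser, burn_in = num("burn_in", 800),
                               window = num("window", 100))
      dplyr::mutate(tibble::as_tibble(ser), label = cls$label)
    },
    bifurcation = {
      grid <- seq(num("tau_min", 2.5), num("tau_max", 3.5),
                  by = num("tau_step", 0.01))
      bifurcation_scan(p, grid, burn_in = num("burn_in", 800),
                       window = num("window", 100))
    },
    phase_diagram = {
      phase_boundary(as.numeric(s$T_grid %||% c(3, 4, 5, 6, 8)),
                     as.numeric(s$t_l_grid %||% c(0.5, 1, 2, 3)), p)
    },
    ess = {
      tibble::tibble(T = p$T, t_l = p$t_l, tau_star = ess_tau(p))
    },
    invade = {
      phase_dependent_invasion(
        p, resident_tau = num("resident_tau", 2.8),
        mutant_tau = num("mutant_tau", 2.81),
        intro_seasons = seq_len(num("intro_seasons", 12)),
        burn_in = num("burn_in", 800))
    },
    evolve = {
      n_rep <- num("n_replicates", 12)
      seed <- as.integer(s$seed %||% seed)  # config seed takes precedence
      walk_ensemble(
        p, seed = seed,
        n_below = ceiling(n_rep / 2), n_above = floor(n_rep / 2),
        offset = num("offset", 0.5),
        constant_cohort = isTRUE(s$constant_cohort),
        first_mutant_season = num("first_mutant_season", 100),
        mutant_interval = num("mutant_interval_seasons", 1000),
        mutation_sd = num("mutation_sd", 0.1),
        extinction_threshold = num("extinction_threshold", 1),
        max_events = num("max_events", 80))
    },
    stop("unknown experiment: ", config$experiment, call. = FALSE)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    resolved <- config
    resolved$settings$seed <- seed
    resolved$settings$package_version <-
      as.character(utils::packageVersion("phenocycle"))
    write_config(resolved, file.path(out_dir, "config.resolved.yaml"))
    utils::write.csv(as.data.frame(res), file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    if (inherits(res, "walk_ensemble")) {
      # one row per mutant event across replicates
      utils::write.csv(as.data.frame(tidy(res)),
                       file.path(out_dir, "events.csv"), row.names = FALSE)
    }
    return(invisible(res))
  }
  res
}

#' Export a seasonal trajectory as tidy CSV
#'
#' Writes a [within_season()] trajectory (or several, bound with a
#' `season` column) in long format with columns `season`, `t`, `s`, `v1`,
#' `v2`.
#'
#' @param trajectory A `season_trajectory` tibble.
#' @param path Output CSV path.
#' @param season Season index to record in the `season` column.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(trajectory, path, season = 0L) {
  df <- dplyr::mutate(tibble::as_tibble(trajectory), season = season,
                      .before = 1)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
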