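#' Preset experiment configurations
#'
#' Ready-made configurations for the standard figure-style experiments:
#' * `fig5A`: bias versus relative target angle (discrete 20-angle targets).
#' * `fig5B`: peak bias versus the ITI ladder.
#' * `fig5C`: peak bias versus the delay ladder.
#' * `fig6A`: response spread under independent uniform targets.
#' * `fig6B`: response spread under locally correlated targets (mu = 0).
#' * `fig6C`: response spread under skewed correlated targets (mu = 90).
#' * `fig7`: delay-period variance time courses with and without STF.
#'
#' @param name preset name.
#' @param fast if `TRUE` (default) use the fast profile (dx = 0.72 deg,
#'   dt = 0.5 ms) for network runs; otherwise printed resolution
#'   (dx = 0.18 deg, dt = 0.1 ms).
#' @param n_trials number of trials for trial-based presets.
#' @return an experiment config list for [run_experiment()].
#' @export
experiment_preset <- function(name = c("fig5A", "fig5B", "fig5C",
                                       "fig6A", "fig6B", "fig6C", "fig7"),
                              fast = TRUE, n_trials = NULL) {
  name <- match.arg(name)
  dx <- if (fast) 0.72 else 0.18
  dt <- if (fast) 0.5 else 0.1
  base <- list(preset = name, dx = dx, dt = dt, n_trials = n_trials)
  switch(name,
    fig5A = c(base, list(model = "reduced", sampler = "uniform_pmf_20",
                         delay = 2000, iti = 1500,
                         n_trials = n_trials %||% 2000)),
    fig5B = c(base, list(model = "reduced", sampler = "uniform_pmf_20",
                         delay = 2000, iti = "iti_ladder",
                         n_trials = n_trials %||% 4000)),
    fig5C = c(base, list(model = "reduced", sampler = "uniform_pmf_20",
                         delay = "delay_ladder", iti = 1500,
                         n_trials = n_trials %||% 4000)),
    fig6A = c(base, list(model = "network", sampler = "uniform_density",
                         delay = 2000, iti = 1500,
                         n_trials = n_trials %||% 800)),
    fig6B = c(base, list(model = "network", sampler = "correlated_mu0",
                         delay = 2000, iti = 1500,
                         n_trials = n_trials %||% 800)),
    fig6C = c(base, list(model = "network", sampler = "correlated_mu90",
                         delay = 2000, iti = 1500,
                         n_trials = n_trials %||% 800)),
    fig7  = c(base, list(model = "network", n_paths = 500, duration = 5000))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_sampler <- function(s) {
  switch(s,
    uniform_density = target_sampler("uniform_density"),
    uniform_pmf_20 = target_sampler("uniform_pmf_20"),
    correlated_mu0 = target_sampler("correlated", mu = 0),
    correlated_mu90 = target_sampler("correlated", mu = 90),
    stop("unknown sampler: ", s, call. = FALSE))
}

#' Run a configured experiment
#'
#' Executes a preset (or hand-built) configuration and writes result CSVs
#' plus a JSON manifest recording the fully resolved configuration and seed,
#' so outputs are reproducible byte-for-byte under a fixed seed.
#'
#' @param config a config list from [experiment_preset()].
#' @param seed integer seed.
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing files and just return results.
#' @return invisibly, a list of result objects (trial results and summaries,
#'   depending on the preset).
#' @export
run_experiment <- function(config, seed = 1, out_dir = NULL) {
  stopifnot(is.list(config), !is.null(config$preset))
  params <- field_params(dx = config$dx)
  out <- list(config = config, seed = seed)
  if (identical(config$model, "network") && config$preset != "fig7") {
    sched <- build_schedule(config$n_trials, delay = config$delay,
                            iti = config$iti,
                            sampler = resolve_sampler(config$sampler),
                            seed = seed)
    res <- run_trials(sched, params, seed = seed + 1L, dt = config$dt)
    out$results <- res
    out$response_sd <- response_sd(res)
    out$bias_curve <- bias_by_relative_angle(res)
  } else if (identical(config$model, "reduced")) {
    sched <- build_schedule(config$n_trials, delay = config$delay,
                            iti = config$iti,
                            sampler = resolve_sampler(config$sampler),
                            seed = seed)
    rp <- reduced_params_from_field(params, dt = max(config$dt, 0.1))
    res <- simulate_reduced(sched, rp, seed = seed + 1L)
    out$results <- res
    out$bias_curve <- bias_by_relative_angle(res)
    if (config$preset == "fig5B") out$peak_bias <- peak_bias_vs(res, "T_I_ms")
    if (config$preset == "fig5C") out$peak_bias <- peak_bias_vs(res, "T_D_ms")
  } else if (config$preset == "fig7") {
    stf <- delay_ensemble(params, config$n_paths, config$duration,
                          seed = seed, dt = config$dt)
    static_params <- field_params(dx = config$dx, beta = 0)
    static <- delay_ensemble(static_params, config$n_paths, config$duration,
                             seed = seed, dt = config$dt)
    out$stf_course <- variance_course(stf)
    out$static_course <- variance_course(static)
  } else {
    stop("unknown model in config", call. = FALSE)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$results))
      write_results_csv(out$results, file.path(out_dir, "trial_results.csv"))
    if (!is.null(out$bias_curve))
      utils::write.csv(out$bias_curve, file.path(out_dir, "bias_curve.csv"),
                       row.names = FALSE)
    if (!is.null(out$peak_bias))
      utils::write.csv(out$peak_bias, file.path(out_dir, "peak_bias.csv"),
                       row.names = FALSE)
    manifest <- list(config = config, seed = seed,
                     package_version = as.character(utils::packageVersion("serialwm")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}

#' Generate small deterministic fixture datasets
#'
#' Tiny bundled datasets used by the test suite: a 5-trial schedule at
#' printed defaults, an 8-target history from the 20-angle uniform pmf, or
#' 20 one-second Brownian trajectories.
#'
#' @param kind one of `"schedules"`, `"histories"`, `"trajectories"`.
#' @param seed integer seed.
#' @return the fixture object (data.frame or numeric vector).
#' @export
make_fixtures <- function(kind = c("schedules", "histories", "trajectories"),
                          seed = 0) {
  kind <- match.arg(kind)
  switch(kind,
    schedules = build_schedule(5, delay = 2000, iti = 1500,
                               sampler = target_sampler("uniform_pmf_20"),
                               seed = seed),
    histories = sample_targets(target_sampler("uniform_pmf_20"), 8, seed = seed),
    trajectories = {
      set.seed(seed)
      U <- potential_field(angle_grid(200), rep(0, 200))
      cfg <- particle_config(sigma_theta = 1, dt = 1)
      lapply(1:20, function(i) simulate_particle(U, cfg, 0, 1000))
    })
}
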