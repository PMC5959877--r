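#' Target sequence sampler
#'
#' Generative laws for target angles across trials:
#' * `uniform_pmf_20`: uniform over the 20 discrete angles
#'   \{-180, -162, ..., 162\} deg (18 deg spacing), used for bias-curve
#'   protocols.
#' * `uniform_density`: uniform density on `[-180, 180)` deg, independent
#'   trials.
#' * `correlated`: first target uniform; each subsequent target drawn from
#'   the conditional mixture
#'   (1 - mix_eps) N_v exp(conc * cos(theta_n - theta_{n+1} - mu)) +
#'   mix_eps / 360,
#'   a von Mises component centered on the previous target (shifted by -mu)
#'   plus a uniform floor. Positive `mu` skews the next target clockwise of
#'   the previous one.
#'
#' The mixture weight here (`mix_eps`) is a property of the task generator
#' and is distinct from the observer's assumed change rate `eps` in the
#' inference module, although both default to the same symbol in the
#' underlying theory.
#'
#' @param mode one of `"uniform_pmf_20"`, `"uniform_density"`, `"correlated"`.
#' @param mix_eps uniform mixture weight for correlated mode (default 0.5).
#' @param conc von Mises concentration (default 25).
#' @param mu offset of the conditional mode, degrees (default 0; 90 gives
#'   the skewed protocol).
#' @return object of class `target_sampler`.
#' @export
target_sampler <- function(mode = c("uniform_density", "uniform_pmf_20", "correlated"),
                           mix_eps = 0.5, conc = 25, mu = 0) {
  mode <- match.arg(mode)
  if (mix_eps < 0 || mix_eps > 1) stop("`mix_eps` must be in [0, 1]", call. = FALSE)
  if (conc < 0) stop("`conc` must be >= 0", call. = FALSE)
  structure(list(mode = mode, mix_eps = mix_eps, conc = conc, mu = mu),
            class = "target_sampler")
}

## conditional density of theta_{n+1} given theta_n on a fine grid (deg)
correlated_conditional <- function(sampler, theta_prev, grid) {
  grid <- check_grid(grid)
  dx <- grid_spacing(grid)
  lv <- sampler$conc * cos(deg2rad(theta_prev - as.numeric(grid) - sampler$mu))
  v <- exp(lv - max(lv))
  v <- v / (sum(v) * dx)                       # von Mises part, normalized
  (1 - sampler$mix_eps) * v + sampler$mix_eps / 360
}

#' Draw a target history from a sampler
#'
#' @param sampler a [target_sampler()].
#' @param n_trials number of targets to draw (>= 1).
#' @param seed integer seed.
#' @param grid_n grid resolution for inverse-CDF sampling in correlated mode.
#' @return numeric vector of target angles in `[-180, 180)` degrees.
#' @export
#' @examples
#' sample_targets(target_sampler("uniform_pmf_20"), 5, seed = 1)
sample_targets <- function(sampler, n_trials, seed = 1, grid_n = 3600) {
  stopifnot(inherits(sampler, "target_sampler"))
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  set.seed(seed)
  if (sampler$mode == "uniform_pmf_20") {
    support <- seq(-180, 162, by = 18)
    return(sample(support, n_trials, replace = TRUE))
  }
  if (sampler$mode == "uniform_density") {
    return(stats::runif(n_trials, -180, 180))
  }
  ## correlated: inverse-CDF on a fine grid for each conditional draw
  grid <- angle_grid(grid_n)
  dx <- grid_spacing(grid)
  out <- numeric(n_trials)
  out[1] <- stats::runif(1, -180, 180)
  for (i in seq_len(n_trials - 1)) {
    dens <- correlated_conditional(sampler, out[i], grid)
    cdf <- cumsum(dens) * dx
    u <- stats::runif(1) * cdf[length(cdf)]
    j <- findInterval(u, cdf) + 1L
    j <- min(j, length(grid))
    out[i + 1] <- as.numeric(grid)[j] + stats::runif(1, 0, dx)  # jitter within bin
  }
  wrap_deg(out)
}

resolve_duration_spec <- function(spec, n, what) {
  if (is.numeric(spec) && length(spec) %in% c(1L, n)) {
    out <- rep_len(spec, n)
  } else if (identical(spec, "iti_ladder")) {
    out <- sample(seq(1000, 5000, by = 200), n, replace = TRUE)
  } else if (identical(spec, "delay_ladder")) {
    out <- sample(seq(0, 5000, by = 200), n, replace = TRUE)
  } else {
    stop("invalid ", what, " specification", call. = FALSE)
  }
  if (any(out < 0)) stop(what, " durations must be >= 0", call. = FALSE)
  out
}

#' Build a delayed-response trial schedule
#'
#' Per-trial timing and targets for the sequential task: each trial consists
#' of a cue period (T_C = 150 ms), a delay (T_D), a post-response
#' inactivation period (T_A = 500 ms), and an intertrial interval (T_I)
#' before the next cue. Delay and ITI can be fixed values, per-trial vectors,
#' or the discrete uniform ladders used in the protocol sweeps:
#' `"iti_ladder"` draws T_I from \{1000, 1200, ..., 5000\} ms and
#' `"delay_ladder"` draws T_D from \{0, 200, ..., 5000\} ms.
#'
#' @param n_trials number of trials.
#' @param delay delay specification: numeric (scalar or per-trial) in ms, or
#'   `"delay_ladder"`.
#' @param iti intertrial-interval specification: numeric in ms, or
#'   `"iti_ladder"`.
#' @param sampler a [target_sampler()], or a numeric vector of target angles
#'   to use directly.
#' @param seed integer seed (drives both duration ladders and targets).
#' @param T_C cue duration, ms (default 150).
#' @param T_A inactivation duration, ms (default 500).
#' @param I_0,I_1,I_R stimulus amplitudes: cue peak, cue sharpness, and
#'   inactivation strength (defaults 1, 1, 2).
#' @return a `trial_schedule` data.frame with columns `trial`, `t_start_ms`,
#'   `T_C_ms`, `T_D_ms`, `T_A_ms`, `T_I_ms`, `theta_deg`; stimulus
#'   amplitudes stored as attributes `I_0`, `I_1`, `I_R`.
#' @export
#' @examples
#' s <- build_schedule(3, delay = 2000, iti = 1500,
#'                     sampler = c(45, 0, -90))
#' diff(s$t_start_ms)  # 4150 ms per trial block
build_schedule <- function(n_trials, delay = 2000, iti = 1500,
                           sampler = target_sampler("uniform_density"),
                           seed = 1, T_C = 150, T_A = 500,
                           I_0 = 1, I_1 = 1, I_R = 2) {
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  if (T_C < 0 || T_A < 0) stop("durations must be >= 0", call. = FALSE)
  set.seed(seed)
  T_D <- resolve_duration_spec(delay, n_trials, "delay")
  T_I <- resolve_duration_spec(iti, n_trials, "iti")
  if (is.numeric(sampler)) {
    theta <- wrap_deg(rep_len(sampler, n_trials))
  } else {
    theta <- sample_targets(sampler, n_trials, seed = seed + 1L)
  }
  block <- T_C + T_D + T_A + T_I
  t_start <- c(0, cumsum(block))[seq_len(n_trials)]
  out <- data.frame(trial = seq_len(n_trials), t_start_ms = t_start,
                    T_C_ms = T_C, T_D_ms = T_D, T_A_ms = T_A, T_I_ms = T_I,
                    theta_deg = theta)
  attr(out, "I_0") <- I_0
  attr(out, "I_1") <- I_1
  attr(out, "I_R") <- I_R
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Stimulus field at a given time
#'
#' The piecewise spatiotemporal drive I(x, t): a tuned cue
#' I_0 exp[I_1 (cos(x - theta_n) - 1)] during the cue period of each trial
#' (peak I_0 at the target), zero during the delay, the global inactivating
#' input -I_R for T_A ms after the delay, and zero through the intertrial
#' interval.
#'
#' @param schedule a [build_schedule()] trial schedule.
#' @param t time in ms (>= 0).
#' @param grid an [angle_grid()].
#' @return numeric stimulus field over `grid`.
#' @export
stimulus_field <- function(schedule, t, grid) {
  stopifnot(inherits(schedule, "trial_schedule"))
  grid <- check_grid(grid)
  if (t < 0) stop("`t` must be >= 0", call. = FALSE)
  x <- as.numeric(grid)
  for (i in seq_len(nrow(schedule))) {
    t0 <- schedule$t_start_ms[i]
    tc <- t0 + schedule$T_C_ms[i]
    td <- tc + schedule$T_D_ms[i]
    ta <- td + schedule$T_A_ms[i]
    t1 <- ta + schedule$T_I_ms[i]
    if (t >= t0 && t < tc) {
      I0 <- attr(schedule, "I_0"); I1 <- attr(schedule, "I_1")
      return(I0 * exp(I1 * (cos(deg2rad(ang_diff_deg(x, schedule$theta_deg[i]))) - 1)))
    }
    if (t >= tc && t < td) return(rep(0, length(x)))
    if (t >= td && t < ta) return(rep(-attr(schedule, "I_R"), length(x)))
    if (t >= ta && t < t1) return(rep(0, length(x)))
  }
  rep(0, length(x))
}

#' Write a trial schedule to CSV
#'
#' @param x a `trial_schedule`.
#' @param path output file path.
#' @export
write_schedule_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
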