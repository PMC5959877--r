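#' Bias conditioned on the previous-to-current target angle
#'
#' Bins trials by the relative angle theta_n - theta_{n+1} (previous minus
#' current target, wrapped) and reports the mean and sd of the response bias
#' r - theta in each bin. Trials without a previous target (the first) and
#' invalid trials are excluded; empty bins are reported with count 0.
#'
#' @param results a `trial_results` data.frame (from [run_trials()] or
#'   [simulate_reduced()]).
#' @param bin_width bin width in degrees (default 18, matching the 20-angle
#'   discrete target set).
#' @return a `bias_curve` data.frame with columns `rel_angle_deg` (bin
#'   center), `mean_bias_deg`, `sd_bias_deg`, `n`.
#' @export
bias_by_relative_angle <- function(results, bin_width = 18) {
  stopifnot(is.data.frame(results))
  ok <- results$valid & !is.na(results$prev_theta_deg) & !is.na(results$bias_deg)
  r <- results[ok, , drop = FALSE]
  rel <- ang_diff_deg(r$prev_theta_deg, r$theta_deg)
  edges <- seq(-180, 180, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  ## biases live on (-180, 180]; shift -180 to 180 side convention for binning
  rel[rel == -180] <- 180
  idx <- findInterval(rel, edges, rightmost.closed = TRUE, left.open = TRUE)
  idx[idx < 1] <- 1
  mean_b <- sd_b <- rep(NA_real_, length(centers))
  n_b <- integer(length(centers))
  for (k in seq_along(centers)) {
    b <- r$bias_deg[idx == k]
    n_b[k] <- length(b)
    if (length(b) >= 1) mean_b[k] <- mean(b)
    if (length(b) >= 2) sd_b[k] <- stats::sd(b)
  }
  structure(data.frame(rel_angle_deg = centers, mean_bias_deg = mean_b,
                       sd_bias_deg = sd_b, n = n_b),
            class = c("bias_curve", "data.frame"))
}

#' Peak bias stratified by intertrial interval or delay
#'
#' For each value of the stratifying key (`T_I_ms` or `T_D_ms`), computes the
#' bias curve over relative angle and reports the maximum absolute mean bias.
#' Strata with fewer than `min_n` usable trials are flagged, not dropped.
#'
#' @param results a `trial_results` data.frame.
#' @param key `"T_I_ms"` or `"T_D_ms"`.
#' @param bin_width bin width passed to [bias_by_relative_angle()].
#' @param min_n minimum trials per stratum before flagging (default 20).
#' @return data.frame with columns `key_ms`, `peak_bias_deg`, `n`, `flagged`.
#' @export
peak_bias_vs <- function(results, key = c("T_I_ms", "T_D_ms"),
                         bin_width = 18, min_n = 20) {
  key <- match.arg(key)
  vals <- sort(unique(results[[key]]))
  out <- data.frame(key_ms = vals, peak_bias_deg = NA_real_,
                    n = 0L, flagged = FALSE)
  for (i in seq_along(vals)) {
    r <- results[results[[key]] == vals[i], , drop = FALSE]
    bc <- bias_by_relative_angle(r, bin_width = bin_width)
    out$n[i] <- sum(bc$n)
    out$flagged[i] <- out$n[i] < min_n
    if (any(bc$n > 0)) out$peak_bias_deg[i] <- max(abs(bc$mean_bias_deg), na.rm = TRUE)
  }
  out
}

#' Standard deviation of the response distribution
#'
#' Sample sd of the wrapped response bias r - theta across valid trials, with
#' the circular sd reported alongside. For the small biases typical here the
#' two agree closely; the linear-on-wrapped value is the headline sigma.
#'
#' @param results a `trial_results` data.frame.
#' @return list with elements `sd_deg` (linear sd of wrapped bias),
#'   `circular_sd_deg`, `mean_bias_deg` and `n`.
#' @export
response_sd <- function(results) {
  b <- results$bias_deg[results$valid & !is.na(results$bias_deg)]
  if (length(b) < 2) stop("need at least 2 valid trials", call. = FALSE)
  br <- deg2rad(b)
  R <- sqrt(mean(cos(br))^2 + mean(sin(br))^2)
  list(sd_deg = stats::sd(b),
       circular_sd_deg = rad2deg(sqrt(-2 * log(R))),
       mean_bias_deg = mean(b),
       n = length(b))
}

#' Ensemble variance time course with two-phase summary
#'
#' Across-path variance of unwrapped bump displacement as a function of time
#' since delay onset, with a two-phase diffusion summary: the early slope is
#' a least-squares fit over the first `early_ms` of the delay, the late slope
#' over the final half, and their ratio quantifies the slowdown produced by
#' facilitation (ratio near 1 for static synapses, well below 1 with STF).
#'
#' @param ens a [delay_ensemble()], or a list with `times_ms` and a
#'   paths-by-times `displacement_deg` matrix.
#' @param early_ms length of the early fitting window, ms (default 500).
#' @return object of class `variance_course`: list with `times_ms`,
#'   `variance_deg2`, `n_paths`, `early_slope`, `late_slope`, `slope_ratio`,
#'   `r_squared` (of a global linear fit through the origin), and
#'   `small_ensemble` warning flag for fewer than 50 paths.
#' @export
variance_course <- function(ens, early_ms = 500) {
  m <- ens$displacement_deg
  times <- ens$times_ms
  stopifnot(is.matrix(m), length(times) == ncol(m))
  n_paths <- nrow(m)
  if (n_paths < 50)
    warning("ensemble smaller than 50 paths; variance estimates are noisy")
  v <- apply(m, 2, stats::var)
  fit_slope <- function(sel) {
    if (sum(sel) < 2) return(NA_real_)
    stats::coef(stats::lm(v[sel] ~ times[sel]))[2]
  }
  early <- times <= early_ms & times > 0
  late <- times >= max(times) / 2
  ## global linear fit quality (R^2), for diagnosing pure diffusion
  fit <- stats::lm(v ~ times)
  structure(list(times_ms = times, variance_deg2 = v, n_paths = n_paths,
                 early_slope = unname(fit_slope(early)),
                 late_slope = unname(fit_slope(late)),
                 slope_ratio = unname(fit_slope(late) / fit_slope(early)),
                 r_squared = summary(fit)$r.squared,
                 small_ensemble = n_paths < 50),
            class = "variance_course")
}

#' @export
print.variance_course <- function(x, ...) {
  cat(sprintf(paste0("variance course: %d paths, %.0f-%.0f ms; early slope %.4g,",
                     " late slope %.4g (ratio %.3f), linear R^2 %.4f\n"),
              x$n_paths, min(x$times_ms), max(x$times_ms),
              x$early_slope, x$late_slope, x$slope_ratio, x$r_squared))
  invisible(x)
}

#' Write trial results to CSV
#'
#' @param x a `trial_results` data.frame.
#' @param path output file path.
#' @export
write_results_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
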