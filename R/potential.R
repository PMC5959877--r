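#' Potential field over the angle circle
#'
#' A potential U(theta) on a periodic grid, whose negative gradient drifts
#' the remembered angle. Only dU/dtheta and the associated Boltzmann density
#' are meaningful; U is defined up to an additive constant. Units are
#' deg^2/time, consistent with a noise amplitude sigma_theta in deg/sqrt(time).
#'
#' @param grid an [angle_grid()].
#' @param values potential values over `grid`.
#' @param chi optional normalization bookkeeping constant from
#'   [potential_from_predictive()].
#' @return object of class `potential_field`.
#' @export
potential_field <- function(grid, values, chi = NA_real_) {
  grid <- check_grid(grid)
  if (length(values) != length(grid) || any(!is.finite(values)))
    stop("`values` must be finite and match the grid", call. = FALSE)
  structure(list(grid = grid, values = as.numeric(values), chi = chi),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("potential field on %d-point grid; range [%.4g, %.4g], argmin %.2f deg\n",
              length(x$grid), min(x$values), max(x$values),
              x$grid[which.min(x$values)]))
  invisible(x)
}

#' Potential whose stationary density is a given predictive distribution
#'
#' Inverts the stationary Fokker-Planck (Boltzmann) relation:
#' U(theta) = (sigma_theta^2 / 2) * log(chi / L(theta)), with chi the
#' normalization constant of the density. [stationary_density()] applied to
#' the result recovers the input distribution exactly.
#'
#' @param dist a strictly positive [predictive_dist()].
#' @param sigma_theta noise amplitude of the angle dynamics (deg/sqrt(time)),
#'   > 0.
#' @return a [potential_field()] with `chi` recorded.
#' @export
potential_from_predictive <- function(dist, sigma_theta) {
  stopifnot(inherits(dist, "predictive_dist"))
  if (sigma_theta <= 0) stop("`sigma_theta` must be > 0", call. = FALSE)
  if (any(dist$density <= 0))
    stop("degenerate distribution: density has zeros, log-potential undefined",
         call. = FALSE)
  chi <- max(dist$density)
  U <- sigma_theta^2 / 2 * log(chi / dist$density)
  potential_field(dist$grid, U, chi = chi)
}

#' Stationary density of drift-diffusion on a potential
#'
#' Boltzmann form of the stationary Fokker-Planck solution on the circle:
#' p(theta) proportional to exp(-2 U(theta) / sigma_theta^2), normalized on
#' the grid.
#'
#' @param U a [potential_field()].
#' @param sigma_theta noise amplitude (deg/sqrt(time)), > 0.
#' @return a [predictive_dist()].
#' @export
stationary_density <- function(U, sigma_theta) {
  stopifnot(inherits(U, "potential_field"))
  if (sigma_theta <= 0)
    stop("degenerate: sigma_theta must be > 0 (zero noise gives a delta)",
         call. = FALSE)
  e <- -2 * U$values / sigma_theta^2
  predictive_dist(U$grid, exp(e - max(e)))
}

## Periodic centered-difference gradient of U on its grid (per degree).
potential_gradient_grid <- function(U) {
  v <- U$values
  n <- length(v)
  dx <- grid_spacing(U$grid)
  (v[c(2:n, 1)] - v[c(n, 1:(n - 1))]) / (2 * dx)
}

## Linear-interpolated gradient lookup at arbitrary wrapped angles (deg).
interp_gradient <- function(U, theta) {
  g <- potential_gradient_grid(U)
  n <- length(g)
  dx <- grid_spacing(U$grid)
  pos <- (wrap_deg(theta) + 180) / dx
  i0 <- floor(pos)
  frac <- pos - i0
  i0 <- (i0 %% n) + 1
  i1 <- (i0 %% n) + 1
  g[i0] * (1 - frac) + g[i1] * frac
}

#' Particle simulation configuration
#'
#' @param sigma_theta noise amplitude (deg/sqrt(time unit)), >= 0.
#' @param dt Euler-Maruyama step, in the same time unit as `sigma_theta^2`
#'   (default 0.1, i.e. 0.1 ms when time is in ms).
#' @param seed optional integer seed.
#' @return object of class `particle_config`.
#' @export
particle_config <- function(sigma_theta, dt = 0.1, seed = NULL) {
  if (sigma_theta < 0) stop("`sigma_theta` must be >= 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  structure(list(sigma_theta = sigma_theta, dt = dt, seed = seed),
            class = "particle_config")
}

#' Simulate the remembered angle as a particle on a potential
#'
#' Euler-Maruyama integration of
#' d theta = -U'(theta) dt + sigma_theta d xi on the circle. The gradient is
#' a centered periodic finite difference on the potential's grid with linear
#' interpolation between nodes. Both the wrapped angle and the unwrapped
#' cumulative displacement are returned, so variance-versus-time analyses are
#' well defined over long runs.
#'
#' @param U a [potential_field()].
#' @param config a [particle_config()].
#' @param theta0 initial angle (degrees).
#' @param duration total simulated time (same unit as `config$dt`).
#' @return data.frame of class `angle_trajectory` with columns `time`,
#'   `angle_deg` (wrapped) and `displacement_deg` (unwrapped).
#' @export
simulate_particle <- function(U, config, theta0, duration) {
  stopifnot(inherits(U, "potential_field"), inherits(config, "particle_config"))
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  nsteps <- ceiling(duration / config$dt)
  dt <- config$dt
  sq <- config$sigma_theta * sqrt(dt)
  g <- potential_gradient_grid(U)
  n <- length(g)
  dx <- grid_spacing(U$grid)
  th <- wrap_deg(theta0)
  disp <- 0
  out_t <- numeric(nsteps + 1)
  out_a <- numeric(nsteps + 1)
  out_d <- numeric(nsteps + 1)
  out_a[1] <- th
  noise <- if (sq > 0) stats::rnorm(nsteps, 0, sq) else numeric(nsteps)
  for (i in seq_len(nsteps)) {
    pos <- (th + 180) / dx
    i0 <- floor(pos)
    frac <- pos - i0
    j0 <- (i0 %% n) + 1
    j1 <- (j0 %% n) + 1
    drift <- -(g[j0] * (1 - frac) + g[j1] * frac) * dt
    step <- drift + if (sq > 0) noise[i] else 0
    th <- wrap_deg(th + step)
    disp <- disp + step
    out_t[i + 1] <- i * dt
    out_a[i + 1] <- th
    out_d[i + 1] <- disp
  }
  structure(data.frame(time = out_t, angle_deg = out_a, displacement_deg = out_d),
            class = c("angle_trajectory", "data.frame"))
}

#' Vectorized ensemble of particles on a potential
#'
#' Runs `n_paths` independent Euler-Maruyama particles in parallel and
#' records wrapped positions at thinned sample times after a burn-in. Used
#' for comparing long-run occupancy with [stationary_density()].
#'
#' @inheritParams simulate_particle
#' @param n_paths number of particles.
#' @param burn_in burn-in time discarded before recording.
#' @param record_every interval between recorded samples.
#' @return matrix (`n_paths` x number of sample times) of wrapped angles.
#' @export
particle_ensemble <- function(U, config, theta0, duration, n_paths,
                              burn_in = 0, record_every = config$dt) {
  stopifnot(inherits(U, "potential_field"), inherits(config, "particle_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dt <- config$dt
  sq <- config$sigma_theta * sqrt(dt)
  g <- potential_gradient_grid(U)
  n <- length(g)
  dx <- grid_spacing(U$grid)
  th <- rep(wrap_deg(theta0), length.out = n_paths)
  nsteps <- ceiling((burn_in + duration) / dt)
  thin <- max(1L, round(record_every / dt))
  burn_steps <- ceiling(burn_in / dt)
  keep <- which(seq_len(nsteps) > burn_steps & (seq_len(nsteps) %% thin == 0L))
  out <- matrix(NA_real_, n_paths, length(keep))
  k <- 1L
  for (i in seq_len(nsteps)) {
    pos <- (th + 180) / dx
    i0 <- floor(pos)
    frac <- pos - i0
    j0 <- (i0 %% n) + 1
    j1 <- (j0 %% n) + 1
    drift <- -(g[j0] * (1 - frac) + g[j1] * frac) * dt
    th <- wrap_deg(th + drift + stats::rnorm(n_paths, 0, sq))
    if (k <= length(keep) && i == keep[k]) {
      out[, k] <- th
      k <- k + 1L
    }
  }
  out
}

#' Write an angle trajectory to CSV
#'
#' @param x an `angle_trajectory` from [simulate_particle()].
#' @param path output file path.
#' @export
write_trajectory_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
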