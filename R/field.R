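#' Parameters of the ring neural field with short-term facilitation
#'
#' The network describes normalized synaptic activity u(x,t) and a
#' facilitation variable q(x,t) for neurons labeled by preferred angle x on
#' the ring. Activity obeys
#'   du = [-u + w * ((1+q) F(u)) + I] dt / tau_u + dW,
#'   tau dq/dt = -q + beta F(u) (q_plus - q),
#' with distance-dependent coupling w given by a cosine series, firing-rate
#' nonlinearity F (sigmoid, or Heaviside in the high-gain limit), stimulus
#' drive I(x,t), and spatially correlated noise dW with covariance
#' sigma_W^2 cos(x - y) dt in tau_u-scaled time (the increment enters u with
#' variance sigma_W^2 dt/tau_u when t is in ms); at sigma_W = 0.005 this
#' puts delay-period response spread in the few-percent range observed over
#' 1-10 s delays. Angles are degrees at the interface; the integrator works
#' in radians internally.
#'
#' @param tau_u excitatory synaptic time constant, ms (default 10).
#' @param tau facilitation time constant, ms (default 1000).
#' @param beta facilitation onset rate (default 0.01).
#' @param q_plus maximal facilitation increase (default 2).
#' @param gamma sigmoid gain (default 20).
#' @param kappa firing threshold, in (0, 1) (default 0.1).
#' @param sigma_W noise amplitude (default 0.005).
#' @param weight_harmonics cosine-series coupling amplitudes alpha_n for
#'   harmonics n = 1, 2, ...; default a single cosine, `c(1)`.
#' @param dx spatial grid spacing in degrees; must divide 360 into an even
#'   number of points. Default 0.18 (2000 points); the "fast" profile uses
#'   0.72 (500 points).
#' @param firing_rate_mode `"sigmoid"` or `"heaviside"`.
#' @return object of class `field_params`.
#' @export
field_params <- function(tau_u = 10, tau = 1000, beta = 0.01, q_plus = 2,
                         gamma = 20, kappa = 0.1, sigma_W = 0.005,
                         weight_harmonics = 1, dx = 0.18,
                         firing_rate_mode = c("sigmoid", "heaviside")) {
  firing_rate_mode <- match.arg(firing_rate_mode)
  if (!(tau > tau_u && tau_u > 0)) stop("need tau > tau_u > 0", call. = FALSE)
  if (beta < 0 || q_plus < 0) stop("beta and q_plus must be >= 0", call. = FALSE)
  if (kappa <= 0 || kappa >= 1) stop("kappa must be in (0, 1)", call. = FALSE)
  nx <- 360 / dx
  if (abs(nx - round(nx)) > 1e-9 || round(nx) %% 2 != 0)
    stop("dx must divide 360 into an even number of grid points", call. = FALSE)
  if (sigma_W < 0) stop("sigma_W must be >= 0", call. = FALSE)
  structure(list(tau_u = tau_u, tau = tau, beta = beta, q_plus = q_plus,
                 gamma = gamma, kappa = kappa, sigma_W = sigma_W,
                 weight_harmonics = as.numeric(weight_harmonics),
                 dx = dx, nx = as.integer(round(nx)),
                 firing_rate_mode = firing_rate_mode),
            class = "field_params")
}

#' @export
print.field_params <- function(x, ...) {
  cat(sprintf(paste0("ring field params: tau_u=%g ms, tau=%g ms, beta=%g, q+=%g, ",
                     "gamma=%g, kappa=%g, sigma_W=%g, dx=%g deg (%d pts), F=%s\n"),
              x$tau_u, x$tau, x$beta, x$q_plus, x$gamma, x$kappa, x$sigma_W,
              x$dx, x$nx, x$firing_rate_mode))
  invisible(x)
}

## radian grid associated with field params (periodic, [-pi, pi))
field_grid_rad <- function(params) {
  nx <- params$nx
  seq(-pi, pi - 2 * pi / nx, length.out = nx)
}

#' Spatial grid of a field model, in degrees
#' @param params a [field_params()].
#' @return an [angle_grid()] with `params$nx` points.
#' @export
field_grid <- function(params) angle_grid(params$nx)

## firing-rate nonlinearity
firing_rate <- function(u, params) {
  if (params$firing_rate_mode == "heaviside") {
    as.numeric(u > params$kappa)
  } else {
    1 / (1 + exp(-params$gamma * (u - params$kappa)))
  }
}

## periodic convolution with the cosine-series coupling kernel, by harmonic
## projection: w*g = sum_n alpha_n [cos(nx) <cos(ny), g> + sin(nx) <sin(ny), g>].
## Exact for any finite cosine series; a constant field maps to zero
## (mean-free coupling).
field_convolve <- function(g, params) {
  x <- field_grid_rad(params)
  dxr <- 2 * pi / params$nx
  out <- numeric(params$nx)
  for (n in seq_along(params$weight_harmonics)) {
    a <- params$weight_harmonics[n]
    if (a == 0) next
    cn <- cos(n * x); sn <- sin(n * x)
    out <- out + a * (cn * sum(cn * g) + sn * sum(sn * g)) * dxr
  }
  out
}

#' Stationary bump profile of the noiseless field
#'
#' Solves the implicit equation U(x) = integral w(x-y) F(U(y)) dy for a
#' stationary localized bump (facilitation and noise off). In Heaviside mode
#' with single-cosine coupling the solution is closed form:
#' U(x) = 2 sin(a) cos(x) with half-width a solving sin(2a) = kappa; the
#' stable wide branch a = (pi - asin(kappa))/2 is returned. In sigmoid mode
#' the profile is found by fixed-point iteration seeded with the Heaviside
#' solution.
#'
#' @param params a [field_params()].
#' @return object of class `bump_profile` with elements `grid` (degrees),
#'   `u` (profile), `half_width_rad`, `half_width_deg`, `amplitude`, `mode`,
#'   and `null_vector` (`"delta_pair"` in Heaviside mode; the gridded
#'   F'(U) U' in sigmoid mode).
#' @export
stationary_bump <- function(params) {
  stopifnot(inherits(params, "field_params"))
  if (length(params$weight_harmonics) != 1 || params$weight_harmonics[1] <= 0)
    stop("stationary bump requires single-cosine coupling with positive amplitude",
         call. = FALSE)
  alpha <- params$weight_harmonics[1]
  kappa <- params$kappa
  if (kappa >= alpha) stop("no bump: threshold kappa too large for coupling", call. = FALSE)
  a <- (pi - asin(kappa / alpha)) / 2   # stable wide branch of sin(2a) = kappa/alpha
  x <- field_grid_rad(params)
  u_h <- 2 * alpha * sin(a) * cos(x)
  if (params$firing_rate_mode == "heaviside") {
    u <- u_h
    nv <- "delta_pair"
  } else {
    ## with a single-cosine kernel the sigmoid bump is exactly A cos(x);
    ## solve the scalar self-consistency A = int cos(y) F(A cos y) dy for the
    ## largest (stable) root, seeded by the Heaviside amplitude
    dxr <- 2 * pi / params$nx
    h <- function(A) sum(cos(x) * firing_rate(A * cos(x), params)) * dxr * alpha
    As <- seq(0.02, max(3, 1.5 * 2 * alpha), by = 0.01)
    gap <- vapply(As, h, 1) - As
    sgn <- sign(gap)
    flips <- which(sgn[-length(sgn)] > 0 & sgn[-1] <= 0)
    if (length(flips) == 0)
      stop("no bump: no suprathreshold self-consistent amplitude", call. = FALSE)
    iroot <- flips[length(flips)]
    A <- stats::uniroot(function(A) h(A) - A, c(As[iroot], As[iroot + 1]),
                        tol = 1e-14)$root
    u <- A * cos(x)
    if (max(u) < kappa) stop("no bump: amplitude below threshold", call. = FALSE)
    du <- c(u[-1], u[1]) - c(u[length(u)], u[-length(u)])
    du <- du / (2 * 2 * pi / params$nx)
    Fp <- params$gamma * firing_rate(u, params) * (1 - firing_rate(u, params))
    nv <- Fp * du
    ## half-width from threshold crossings of the (even, centered) profile
    a <- crossing_halfwidth(u, x, kappa)
  }
  structure(list(grid = angle_grid(params$nx), u = u,
                 half_width_rad = a, half_width_deg = a * 180 / pi,
                 amplitude = max(u), mode = params$firing_rate_mode,
                 null_vector = nv),
            class = "bump_profile")
}

## half-width at threshold kappa from linear interpolation of the profile
crossing_halfwidth <- function(u, x, kappa) {
  above <- u > kappa
  if (!any(above)) return(NA_real_)
  idx <- which(above)
  ## profile is centered at 0; rightmost crossing between last above-threshold
  ## point and its neighbor
  i <- max(idx)
  if (i == length(u)) return(pi)
  x0 <- x[i]; x1 <- x[i + 1]
  u0 <- u[i]; u1 <- u[i + 1]
  x0 + (kappa - u0) * (x1 - x0) / (u1 - u0)
}

#' @export
print.bump_profile <- function(x, ...) {
  cat(sprintf("stationary bump (%s): amplitude %.4f, half-width %.2f deg\n",
              x$mode, x$amplitude, x$half_width_deg))
  invisible(x)
}

#' Stationary facilitation profile under a clamped bump
#'
#' With the bump held in place, the facilitation variable relaxes to the
#' plateau Q(x) = beta q_plus / (1 + beta) over the bump's suprathreshold
#' interval (-a, a), and zero outside (Heaviside mode).
#'
#' @param params a [field_params()].
#' @param bump a [stationary_bump()] profile.
#' @return numeric facilitation profile over the field grid.
#' @export
stationary_stf <- function(params, bump) {
  stopifnot(inherits(params, "field_params"), inherits(bump, "bump_profile"))
  x <- field_grid_rad(params)
  plateau <- params$beta * params$q_plus / (1 + params$beta)
  ifelse(abs(x) < bump$half_width_rad, plateau, 0)
}

#' Spatially correlated noise increment
#'
#' One increment of the field noise dW over a time step: built from two
#' independent standard normal draws xi1, xi2 as
#' sigma_W (cos(x) xi1 + sin(x) xi2) sqrt(dt), which has mean zero and
#' spatial covariance sigma_W^2 cos(x - y) dt, white in time.
#'
#' @param params a [field_params()] (supplies `sigma_W` and the grid).
#' @param dt time step (ms), > 0.
#' @return numeric increment over the field grid.
#' @export
noise_increment <- function(params, dt) {
  stopifnot(inherits(params, "field_params"))
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  x <- field_grid_rad(params)
  xi <- stats::rnorm(2)
  params$sigma_W * (cos(x) * xi[1] + sin(x) * xi[2]) * sqrt(dt)
}

#' One Euler-Maruyama step of the field equations
#'
#' Reference (pure R) implementation of a single update of (u, q):
#' an Euler-Maruyama step for u and an explicit Euler step for q. Used for
#' property checks; long simulations go through the compiled trial runner
#' [run_trials()], which this step is validated against.
#'
#' @param state list with numeric fields `u` and `q` over the field grid.
#' @param params a [field_params()].
#' @param stimulus numeric stimulus field I(x, t) over the grid (or a single
#'   number, recycled).
#' @param dt time step (ms).
#' @param noise noise increment dW over the grid (e.g. from
#'   [noise_increment()]), entering u scaled by 1/sqrt(tau_u) per the
#'   tau_u-nondimensional time convention; default zero.
#' @return updated state list with fields `u`, `q`.
#' @export
field_step <- function(state, params, stimulus = 0, dt = 0.1, noise = 0) {
  stopifnot(inherits(params, "field_params"))
  u <- state$u; q <- state$q
  r <- firing_rate(u, params)
  conv <- field_convolve((1 + q) * r, params)
  u_new <- u + dt / params$tau_u * (-u + conv + stimulus) +
    noise / sqrt(params$tau_u)
  q_new <- q + dt / params$tau * (-q + params$beta * r * (params$q_plus - q))
  ## q stays in [0, q_plus] up to numerical overshoot
  over <- q_new > params$q_plus + 1e-12 | q_new < -1e-12
  if (any(over)) q_new <- pmin(pmax(q_new, 0), params$q_plus)
  if (any(!is.finite(u_new)) || any(!is.finite(q_new)))
    stop("numerical blow-up in field_step: non-finite state", call. = FALSE)
  list(u = u_new, q = q_new)
}

#' Bump center readout
#'
#' Position of the activity bump as the argmax of u over the grid; `NA` if
#' no point exceeds the firing threshold. If the maximum is attained at
#' several nodes, the circular centroid of the argmax set is returned.
#'
#' @param u numeric activity field over `grid`.
#' @param grid an [angle_grid()] matching `u`.
#' @param kappa firing threshold below which no bump is reported.
#' @return center angle in degrees, or `NA_real_`.
#' @export
bump_center <- function(u, grid, kappa = 0.1) {
  grid <- check_grid(grid)
  m <- max(u)
  if (!is.finite(m) || m < kappa) return(NA_real_)
  idx <- which(u >= m - 1e-12)
  if (length(idx) == 1) return(as.numeric(grid)[idx])
  ang <- deg2rad(as.numeric(grid)[idx])
  rad2deg(atan2(mean(sin(ang)), mean(cos(ang))))
}

#' Run a sequence of delayed-response trials in the full network
#'
#' Simulates the stochastic field equations through an entire trial schedule
#' (compiled integrator): a 2 s noise-driven burn-in (ended by one
#' inactivation period) precedes trial 1; each trial presents the tuned cue
#' for T_C ms, evolves freely through the delay T_D, reads out the response
#' as the bump position at delay end, and then applies the global
#' inactivating input -I_R from the response until the next cue (T_A + T_I),
#' so the network is quiescent between trials and facilitation alone carries
#' the trial history. Facilitation is never reset; its persistence across
#' the intertrial interval is the mechanism under study.
#'
#' @param schedule a [build_schedule()] trial schedule.
#' @param params a [field_params()].
#' @param seed integer seed (R RNG).
#' @param dt integration step, ms (default 0.1; the fast profile uses 0.5).
#' @param record_every optional interval (ms) at which to record the bump
#'   center during each delay; recorded trajectories are attached as
#'   attribute `"trajectories"` (list of data.frames).
#' @return a `trial_results` data.frame with columns `trial`, `theta_deg`,
#'   `response_deg`, `bias_deg`, `prev_theta_deg`, `T_D_ms`, `T_I_ms`,
#'   `valid`. Trials where the bump had collapsed at readout are flagged
#'   `valid = FALSE` (response `NA`), not dropped.
#' @export
run_trials <- function(schedule, params, seed = 1, dt = 0.1,
                       record_every = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"), inherits(params, "field_params"))
  set.seed(seed)
  rec <- if (is.null(record_every)) 0 else record_every
  res <- nf_run_trials(
    deg2rad(schedule$theta_deg), schedule$T_C_ms, schedule$T_D_ms,
    schedule$T_A_ms, schedule$T_I_ms,
    attr(schedule, "I_0"), attr(schedule, "I_1"), attr(schedule, "I_R"),
    params$nx, params$tau_u, params$tau, params$beta, params$q_plus,
    params$gamma, params$kappa, params$sigma_W, params$weight_harmonics,
    params$firing_rate_mode == "heaviside", dt,
    if (params$sigma_W > 0) 2000 else 0, rec)
  out <- data.frame(
    trial = seq_along(schedule$theta_deg),
    theta_deg = schedule$theta_deg,
    response_deg = rad2deg(res$response),
    T_D_ms = schedule$T_D_ms,
    T_I_ms = schedule$T_I_ms,
    valid = res$valid
  )
  out$response_deg[!out$valid] <- NA_real_
  out$bias_deg <- ang_diff_deg(out$response_deg, out$theta_deg)
  out$prev_theta_deg <- c(NA_real_, out$theta_deg[-nrow(out)])
  out <- out[, c("trial", "theta_deg", "response_deg", "bias_deg",
                 "prev_theta_deg", "T_D_ms", "T_I_ms", "valid")]
  class(out) <- c("trial_results", "data.frame")
  if (rec > 0) {
    attr(out, "trajectories") <- lapply(res$traj, function(m) {
      data.frame(time_ms = m[, 1], center_deg = rad2deg(m[, 2]),
                 displacement_deg = rad2deg(m[, 3]))
    })
  }
  out
}

#' Ensemble of delay-period bump trajectories
#'
#' For each path: a fresh network starts from a briefly suppressed quiescent
#' state (as after a preceding response), a cue at 0 deg is presented for
#' `T_C` ms, and the bump then evolves through a delay of `duration` ms while
#' its unwrapped displacement from the delay-onset position is recorded every
#' `record_every` ms. Used for variance-versus-time analyses of memory
#' degradation.
#'
#' @param params a [field_params()] (`beta = 0` gives the static-synapse
#'   network).
#' @param n_paths number of independent paths.
#' @param duration delay length, ms.
#' @param seed integer seed.
#' @param dt integration step, ms.
#' @param record_every recording interval, ms.
#' @param T_C cue duration, ms.
#' @return object of class `delay_ensemble`: list with `times_ms` and
#'   `displacement_deg` (matrix, paths x times).
#' @export
delay_ensemble <- function(params, n_paths, duration, seed = 1, dt = 0.1,
                           record_every = 10, T_C = 150) {
  stopifnot(inherits(params, "field_params"))
  set.seed(seed)
  m <- nf_delay_ensemble(
    n_paths, duration, record_every, T_C,
    params$nx, params$tau_u, params$tau, params$beta, params$q_plus,
    params$gamma, params$kappa, params$sigma_W, params$weight_harmonics,
    params$firing_rate_mode == "heaviside", dt, 200)
  structure(list(times_ms = seq(0, by = record_every,
                                length.out = ncol(m)),
                 displacement_deg = m * 180 / pi),
            class = "delay_ensemble")
}
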