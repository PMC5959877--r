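#' Parameters of the low-dimensional bump + facilitation model
#'
#' The reduction tracks the bump position theta(t), the center theta_q(t) of
#' the facilitation laid down in the current trial, and slowly varying
#' facilitation amplitudes for the previous and current trials. Drift comes
#' from the Heaviside-limit potential gradient of the facilitation footprint;
#' noise is the diffusion projected from the full field equations.
#'
#' @param half_width_rad bump half-width a in radians (from
#'   [stationary_bump()]); must lie in (0, pi).
#' @param beta,q_plus,tau,tau_u facilitation and synaptic parameters,
#'   matching [field_params()] defaults.
#' @param sigma effective noise amplitude (rad per sqrt(ms)); by default
#'   derived as sqrt(2 D) from [diffusion_coefficient()] via
#'   `reduced_params_from_field()`.
#' @param dt integration step, ms.
#' @return object of class `reduced_params`.
#' @export
reduced_params <- function(half_width_rad, beta = 0.01, q_plus = 2,
                           tau = 1000, tau_u = 10, sigma = 0, dt = 0.1) {
  if (!(half_width_rad > 0 && half_width_rad < pi))
    stop("`half_width_rad` must be in (0, pi)", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  structure(list(half_width_rad = half_width_rad, beta = beta,
                 q_plus = q_plus, tau = tau, tau_u = tau_u,
                 sigma = sigma, dt = dt),
            class = "reduced_params")
}

#' Reduced-model parameters derived from field parameters
#'
#' Computes the stationary bump half-width and the projected diffusion
#' coefficient from a [field_params()] object, so the reduced model is run
#' at parameters matched to the full network.
#'
#' @param params a [field_params()].
#' @param noise if `FALSE`, sets the reduced noise amplitude to zero.
#' @param dt integration step, ms.
#' @return a [reduced_params()].
#' @export
reduced_params_from_field <- function(params, noise = TRUE, dt = 0.1) {
  bump <- stationary_bump(params)
  sig <- if (noise && params$sigma_W > 0) {
    sqrt(2 * diffusion_coefficient(bump, params))
  } else 0
  reduced_params(bump$half_width_rad, beta = params$beta,
                 q_plus = params$q_plus, tau = params$tau,
                 tau_u = params$tau_u, sigma = sig, dt = dt)
}

#' Facilitation amplitude kinetics (closed form)
#'
#' The amplitude A(t) of the facilitation bump laid down in a trial rises as
#' 1 - exp(-t/tau) while the bump is active (cue + delay) and decays as
#' exp(-(t - t_off)/tau) afterwards; the linear ODE is integrated exactly.
#' At the start of the next trial, after an intertrial gap `gap` ms, the
#' amplitude is (1 - exp(-(T_C + T_D)/tau)) * exp(-gap/tau).
#'
#' @param t time since trial start, ms (vectorized). Times before the trial
#'   start return 0.
#' @param active_ms duration of the active period T_C + T_D, ms.
#' @param tau facilitation time constant, ms.
#' @return amplitude values in `[0, 1]`.
#' @export
#' @examples
#' facilitation_amplitude(1000, active_ms = 1000, tau = 1000)  # 1 - exp(-1)
facilitation_amplitude <- function(t, active_ms, tau = 1000) {
  A_end <- 1 - exp(-active_ms / tau)
  ifelse(t < 0, 0,
         ifelse(t <= active_ms, 1 - exp(-t / tau),
                A_end * exp(-(t - active_ms) / tau)))
}

#' Heaviside-limit potential gradient of the facilitation footprint
#'
#' The drift exerted on the bump at wrapped offset `delta` (radians) from a
#' stationary facilitation profile:
#' -dU/dtheta = beta q_plus / (2 (1+beta) tan a) *
#'   (sign(delta) (1 - cos delta) - tan(a) sin delta)
#' for |delta| < 2a and 0 otherwise. The function is odd in `delta` and
#' attracts the bump towards the facilitation center.
#'
#' @param delta wrapped offset theta - theta', radians (vectorized).
#' @param params a [reduced_params()].
#' @return drift values (radians per tau_u time unit).
#' @export
potential_gradient <- function(delta, params) {
  stopifnot(inherits(params, "reduced_params"))
  a <- params$half_width_rad
  c0 <- params$beta * params$q_plus / (2 * (1 + params$beta) * tan(a))
  out <- c0 * (sign(delta) * (1 - cos(delta)) - tan(a) * sin(delta))
  out[abs(delta) >= 2 * a] <- 0
  out
}

#' Scaled circular difference driving the facilitation center
#'
#' The shorter signed arc from theta to theta_q, scaled by (1 + beta); this
#' is the restoring term in tau d(theta_q)/dt = -d(theta_q - theta), giving
#' relaxation of theta_q toward a clamped theta at rate (1 + beta)/tau.
#'
#' @param dq offset theta_q - theta, radians (vectorized).
#' @param beta facilitation onset rate.
#' @return scaled signed arc, |result|/(1+beta) <= pi.
#' @export
circular_difference <- function(dq, beta = 0.01) {
  (1 + beta) * wrap_rad(dq)
}

#' Projected diffusion coefficient of the bump position
#'
#' Effective diffusion of the bump center under the spatially correlated
#' field noise, obtained by projecting the noise onto the translation mode:
#' the projected variance rate is
#' sigma^2 = (integral integral V(x) C(x-y) V(y) dy dx) /
#'           (integral U'(x) V(x) dx)^2,
#' with V the adjoint null vector (a rate per tau_u-unit of time), and
#' D = sigma^2 / (2 tau_u) in physical ms units. In Heaviside mode V
#' is the delta pair at +-a and the expression is closed form,
#' D = sigma_W^2 / (8 tau_u sin^2 a); in sigmoid mode V = F'(U) U' and
#' the integrals are evaluated by quadrature on the grid. An equivalent
#' direct derivation: the bump is a first-harmonic profile of amplitude
#' 2 sin(a), and the rank-two cosine noise shifts its phase by its
#' sine-component over the amplitude, giving a displacement variance rate of
#' sigma_W^2 / (4 sin(a)^2) per tau_u-unit of time -- the same value.
#'
#' Units: D is in rad^2 per ms, so the unwrapped bump displacement variance
#' grows as 2 D t with t in ms (facilitation off).
#'
#' @param bump a [stationary_bump()] profile.
#' @param params the [field_params()] used to build the bump (supplies
#'   `sigma_W` and the grid).
#' @return nonnegative diffusion coefficient D (rad^2/ms).
#' @export
diffusion_coefficient <- function(bump, params) {
  stopifnot(inherits(bump, "bump_profile"), inherits(params, "field_params"))
  sW <- params$sigma_W
  if (sW == 0) return(0)
  if (identical(bump$null_vector, "delta_pair")) {
    a <- bump$half_width_rad
    return(sW^2 / (8 * params$tau_u * sin(a)^2))
  }
  x <- field_grid_rad(params)
  dxr <- 2 * pi / params$nx
  V <- bump$null_vector
  u <- bump$u
  n <- length(u)
  du <- (u[c(2:n, 1)] - u[c(n, 1:(n - 1))]) / (2 * dxr)
  denom <- sum(du * V) * dxr
  if (abs(denom) < 1e-12)
    stop("degenerate projection: flat bump (zero denominator)", call. = FALSE)
  ## C(x-y) = sW^2 cos(x-y): numerator = sW^2 [(int V cos)^2 + (int V sin)^2]
  vc <- sum(V * cos(x)) * dxr
  vs <- sum(V * sin(x)) * dxr
  num <- sW^2 * (vc^2 + vs^2)
  num / denom^2 / (2 * params$tau_u)
}

#' Simulate the reduced bump + facilitation model over a trial schedule
#'
#' Euler-Maruyama integration of the coupled equations for the bump position
#' and the facilitation center during each trial's cue and delay: the bump is
#' clamped to the target during the cue; during the delay it is attracted by
#' the decaying facilitation of the previous trial (centered on the previous
#' target) and by the growing facilitation of the current trial (centered on
#' theta_q, which itself trails the bump). Responses are read at delay end.
#' Facilitation amplitudes follow the exact exponential kinetics; the
#' intertrial decay spans the full response-to-cue gap (inactivation period
#' plus intertrial interval).
#'
#' @param schedule a [build_schedule()] trial schedule.
#' @param params a [reduced_params()].
#' @param seed integer seed.
#' @param record_every optional interval (ms) to record (theta, theta_q)
#'   during delays; attached as attribute `"trajectories"`.
#' @return a `trial_results` data.frame with the same core columns as
#'   [run_trials()] plus `theta_q_deg`, `A_prev`, `A_curr`.
#' @export
simulate_reduced <- function(schedule, params, seed = 1, record_every = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"), inherits(params, "reduced_params"))
  set.seed(seed)
  rec <- if (is.null(record_every)) 0 else record_every
  res <- red_run_trials(
    deg2rad(schedule$theta_deg), schedule$T_C_ms, schedule$T_D_ms,
    schedule$T_A_ms, schedule$T_I_ms,
    params$half_width_rad, params$beta, params$q_plus, params$tau,
    params$tau_u, params$sigma, params$dt, rec)
  out <- data.frame(
    trial = seq_along(schedule$theta_deg),
    theta_deg = schedule$theta_deg,
    response_deg = rad2deg(res$response),
    T_D_ms = schedule$T_D_ms,
    T_I_ms = schedule$T_I_ms,
    valid = TRUE
  )
  out$bias_deg <- ang_diff_deg(out$response_deg, out$theta_deg)
  out$prev_theta_deg <- c(NA_real_, out$theta_deg[-nrow(out)])
  out$theta_q_deg <- rad2deg(res$theta_q)
  out$A_prev <- res$A_prev
  out$A_curr <- res$A_curr
  out <- out[, c("trial", "theta_deg", "response_deg", "bias_deg",
                 "prev_theta_deg", "T_D_ms", "T_I_ms", "valid",
                 "theta_q_deg", "A_prev", "A_curr")]
  class(out) <- c("trial_results", "data.frame")
  if (rec > 0) {
    attr(out, "trajectories") <- lapply(res$traj, function(m) {
      data.frame(time_ms = m[, 1], theta_deg = rad2deg(m[, 2]),
                 theta_q_deg = rad2deg(m[, 3]))
    })
  }
  out
}
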