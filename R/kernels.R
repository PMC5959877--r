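#' Self-conjugate tuning kernel on the circle
#'
#' The observer's assumed probability f_{theta'}(theta) that the next target
#' falls at `theta` given that the previous target was `theta'` and the
#' generating distribution has not changed in between. The family is an
#' exponential of cosines,
#'   f_{theta'}(theta) = N_theta * exp(sum_j a_j cos(omega_j (theta - theta'))),
#' with omega_j = j * pi / 180 for theta in degrees, so the j-th harmonic has
#' period 360/j degrees. The kernel is even and shift invariant, hence
#' self-conjugate: f_{theta'}(theta) = f_theta(theta').
#'
#' @param amplitudes numeric vector of harmonic amplitudes `a_j`
#'   (dimensionless); `a_j = 0` for all j gives the uniform density. The
#'   default single harmonic `a_1 = 2` is the comparison kernel whose central
#'   region matches the facilitation-derived kernel shape.
#' @return an object of class `tuning_kernel`.
#' @export
#' @examples
#' k <- tuning_kernel(2)
#' g <- angle_grid(360)
#' f <- kernel_density(k, 0, g)
#' sum(f) * attr(g, "spacing")  # integrates to 1
tuning_kernel <- function(amplitudes = 2) {
  if (!is.numeric(amplitudes) || anyNA(amplitudes) || any(!is.finite(amplitudes)))
    stop("`amplitudes` must be finite numeric", call. = FALSE)
  structure(list(amplitudes = as.numeric(amplitudes),
                 n_harmonics = length(amplitudes)),
            class = "tuning_kernel")
}

#' @export
print.tuning_kernel <- function(x, ...) {
  cat("tuning kernel: exponential of", x$n_harmonics, "cosine harmonic(s), a =",
      paste(signif(x$amplitudes, 4), collapse = ", "), "\n")
  invisible(x)
}

## Unnormalized log-kernel at wrapped differences `delta` (degrees).
kernel_log_unnorm <- function(kernel, delta) {
  out <- 0
  for (j in seq_along(kernel$amplitudes)) {
    out <- out + kernel$amplitudes[j] * cos(j * pi / 180 * delta)
  }
  out
}

#' Evaluate a tuning kernel as a density on a grid
#'
#' Returns the kernel density centered at `center`, normalized so its Riemann
#' sum over the grid equals 1 (units 1/deg).
#'
#' @param kernel a [tuning_kernel()].
#' @param center center angle in degrees.
#' @param grid an [angle_grid()] (or uniform periodic vector of degrees).
#' @return numeric density over `grid` (1/deg), shift invariant and even
#'   about `center`.
#' @export
kernel_density <- function(kernel, center, grid) {
  grid <- check_grid(grid)
  dx <- grid_spacing(grid)
  lf <- kernel_log_unnorm(kernel, ang_diff_deg(as.numeric(grid), center))
  f <- exp(lf - max(lf))
  f / (sum(f) * dx)
}
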