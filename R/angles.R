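#' Wrap angles to [-180, 180) degrees
#'
#' @param theta numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval `[-180, 180)`.
#' @export
#' @examples
#' wrap_deg(c(185, -181, 360))
wrap_deg <- function(theta) {
  ((theta + 180) %% 360) - 180
}

#' Wrap angles to [-pi, pi) radians
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to `[-pi, pi)`.
#' @export
wrap_rad <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Signed wrapped difference in degrees
#'
#' Shortest signed arc from `b` to `a`, i.e. `a - b` wrapped into
#' `(-180, 180]`. This is the convention used for response biases, so that
#' the bias of a response at -179 deg to a target at 179 deg is +2 deg.
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return signed differences in `(-180, 180]`.
#' @export
#' @examples
#' ang_diff_deg(-179, 179)  # +2
ang_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

deg2rad <- function(theta) theta * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Uniform periodic grid over the target-angle circle
#'
#' Angles are measured in degrees over `[-180, 180)`. The grid is uniform and
#' periodic: the point at 180 is identified with -180 and not repeated.
#'
#' @param n number of grid points; the spacing is `360 / n`. The default
#'   `n = 2000` gives 0.18 deg spacing, the resolution used for the field
#'   simulations.
#' @return an object of class `angle_grid`: numeric vector of angles with
#'   attribute `spacing` (degrees).
#' @export
#' @examples
#' g <- angle_grid(8)
#' attr(g, "spacing")
angle_grid <- function(n = 2000) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("`n` must be a single integer >= 2", call. = FALSE)
  dx <- 360 / n
  g <- seq(-180, 180 - dx, by = dx)
  structure(g, spacing = dx, class = "angle_grid")
}

## Accepts either an angle_grid or a raw uniform periodic vector of degrees.
check_grid <- function(grid) {
  if (length(grid) < 2)
    stop("invalid grid: need at least 2 points", call. = FALSE)
  d <- diff(as.numeric(grid))
  if (any(abs(d - d[1]) > 1e-9))
    stop("invalid grid: spacing is not uniform", call. = FALSE)
  dx <- d[1]
  if (abs(length(grid) * dx - 360) > 1e-6)
    stop("invalid grid: must cover 360 degrees periodically", call. = FALSE)
  structure(as.numeric(grid), spacing = dx, class = "angle_grid")
}

grid_spacing <- function(grid) {
  sp <- attr(grid, "spacing")
  if (is.null(sp)) sp <- diff(as.numeric(grid))[1]
  sp
}
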