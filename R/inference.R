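#' Predictive distribution over the next target angle
#'
#' Container for the observer's gridded predictive density
#' L_{n+1,theta} = P(theta_{n+1} = theta | theta_{1:n}, eps). Densities carry
#' units of 1/deg; the uniform level is 1/360 per degree.
#'
#' @param grid an [angle_grid()].
#' @param density nonnegative density values over `grid`; renormalized so the
#'   Riemann sum equals 1.
#' @return object of class `predictive_dist` with elements `grid`, `density`
#'   and `uniform_level` (= 1/360).
#' @export
predictive_dist <- function(grid, density) {
  grid <- check_grid(grid)
  if (length(density) != length(grid))
    stop("`density` must match grid length", call. = FALSE)
  if (any(!is.finite(density)) || any(density < 0))
    stop("`density` must be finite and nonnegative", call. = FALSE)
  dx <- grid_spacing(grid)
  z <- sum(density) * dx
  if (z <= 0) stop("`density` must have positive mass", call. = FALSE)
  structure(list(grid = grid, density = density / z, uniform_level = 1 / 360),
            class = "predictive_dist")
}

#' @export
print.predictive_dist <- function(x, ...) {
  cat(sprintf("predictive distribution on %d-point grid (dx = %.4g deg); peak %.4g/deg at %.2f deg\n",
              length(x$grid), grid_spacing(x$grid),
              max(x$density), x$grid[which.max(x$density)]))
  invisible(x)
}

#' @export
as.data.frame.predictive_dist <- function(x, ...) {
  data.frame(angle_deg = as.numeric(x$grid), density = x$density)
}

#' Write a predictive distribution to a two-column CSV
#'
#' @param x a [predictive_dist()].
#' @param path output file path.
#' @export
write_predictive_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

## exact uniform density (bypasses renormalization so every node is 1/360)
uniform_dist <- function(grid) {
  grid <- check_grid(grid)
  structure(list(grid = grid, density = rep(1 / 360, length(grid)),
                 uniform_level = 1 / 360),
            class = "predictive_dist")
}

check_eps <- function(eps) {
  if (length(eps) != 1L || !is.finite(eps) || eps < 0 || eps > 1)
    stop("`eps` must be a probability in [0, 1]", call. = FALSE)
  eps
}

#' Run-length prior under a fixed environmental change rate
#'
#' Probability that the target-generating distribution has stayed unchanged
#' for the last `l` trials (l = 0..n), given change rate `eps` per trial:
#' P(l) = eps (1-eps)^l for l < n and (1-eps)^n for l = n.
#'
#' @param n number of observed trials (>= 0).
#' @param eps assumed change probability per trial, in `[0, 1]`.
#' @return numeric vector of length `n + 1`, probabilities of run lengths
#'   `0:n`; sums to 1 exactly.
#' @export
#' @examples
#' runlength_prior(2, 0.5)  # 0.5, 0.25, 0.25
runlength_prior <- function(n, eps) {
  check_eps(eps)
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != round(n))
    stop("`n` must be a single integer >= 0", call. = FALSE)
  if (n == 0) return(1)
  l <- 0:(n - 1)
  c(eps * (1 - eps)^l, (1 - eps)^n)
}

## Normalized product of kernel densities over a set of observed targets.
## Returns the uniform density for an empty set. Computed in log space to
## avoid underflow for long histories.
segment_density <- function(targets, kernel, grid) {
  grid <- check_grid(grid)
  if (length(targets) == 0) return(rep(1 / 360, length(grid)))
  lf <- 0
  for (th in targets) {
    lf <- lf + kernel_log_unnorm(kernel, ang_diff_deg(as.numeric(grid), th))
  }
  f <- exp(lf - max(lf))
  f / (sum(f) * grid_spacing(grid))
}

#' Exact sequential predictive distribution
#'
#' The full run-length mixture: each run length l (number of most recent
#' trials generated by the current, unchanged distribution) contributes the
#' normalized product of the kernel densities of the last l observations,
#' weighted by the run-length prior [runlength_prior()]. An empty history
#' returns the uniform distribution, as does `eps = 1` (the observer assumes
#' every trial resets the environment).
#'
#' @param history numeric vector of observed target angles theta_{1:n}
#'   (degrees, oldest first).
#' @param kernel a [tuning_kernel()].
#' @param eps assumed environmental change rate in `[0, 1]`.
#' @param grid an [angle_grid()].
#' @return a [predictive_dist()].
#' @export
predict_exact <- function(history, kernel, eps, grid = angle_grid()) {
  grid <- check_grid(grid)
  check_eps(eps)
  history <- wrap_deg(as.numeric(history))
  n <- length(history)
  if (n == 0 || eps == 1) return(uniform_dist(grid))
  w <- runlength_prior(n, eps)
  dens <- rep(0, length(grid))
  for (l in 0:n) {
    if (w[l + 1] == 0) next
    seg <- if (l == 0) numeric(0) else history[(n - l + 1):n]
    dens <- dens + w[l + 1] * segment_density(seg, kernel, grid)
  }
  predictive_dist(grid, dens)
}

#' Predictive distribution for a static environment (eps = 0)
#'
#' With no assumed environmental change, every observation is weighted
#' equally and the predictive density is the normalized product of all
#' observation kernels. Equivalently it can be built iteratively, multiplying
#' in one kernel per trial; both give identical densities.
#'
#' @inheritParams predict_exact
#' @return a [predictive_dist()]; an empty history gives the uniform
#'   distribution.
#' @export
predict_static <- function(history, kernel, grid = angle_grid()) {
  grid <- check_grid(grid)
  history <- wrap_deg(as.numeric(history))
  predictive_dist(grid, segment_density(history, kernel, grid))
}

#' Rapid-change truncation of the predictive distribution
#'
#' For an observer who assumes the environment changes nearly every trial
#' (eps near 1), only the most recent targets matter. The first-order
#' truncation is the printed mixture
#'   L = eps / 360 + (1 - eps) f_{theta_n}(theta),
#' which is already normalized. The second-order truncation keeps in addition
#' the term eps (1-eps)^2 times the normalized product of the last two
#' observation kernels, and is renormalized on the grid.
#'
#' @param targets most recent observed targets, oldest first; order 1 uses
#'   the last element only, order 2 the last two.
#' @param order truncation order, 1 or 2.
#' @inheritParams predict_exact
#' @return a [predictive_dist()].
#' @export
predict_rapid <- function(targets, kernel, eps, grid = angle_grid(), order = 1) {
  grid <- check_grid(grid)
  check_eps(eps)
  if (eps == 0) stop("`eps` must be in (0, 1] for the rapid-change limit", call. = FALSE)
  if (!order %in% c(1, 2)) stop("`order` must be 1 or 2", call. = FALSE)
  targets <- wrap_deg(as.numeric(targets))
  n <- length(targets)
  if (n < 1) stop("need at least one observed target", call. = FALSE)
  th_n <- targets[n]
  f_n <- segment_density(th_n, kernel, grid)
  dens <- eps / 360 + (1 - eps) * f_n
  if (order == 2 && n >= 2) {
    ## eps P0 + eps (1-eps) f_n + eps (1-eps)^2 P0 f_n f_{n-1} / P(seg);
    ## with the segment marginal-likelihood normalizer the last term is the
    ## normalized two-kernel product. Common factor eps divided out before
    ## renormalization.
    prod2 <- segment_density(targets[(n - 1):n], kernel, grid)
    dens <- 1 / 360 + (1 - eps) * f_n + (1 - eps)^2 * prod2
  }
  predictive_dist(grid, dens)
}

#' Slowly-changing-environment truncation of the predictive distribution
#'
#' First-order truncation in small eps: the full product of all observation
#' kernels with weight (1 - n eps), plus eps times the sum over shorter
#' trailing segments, renormalized on the grid. At eps = 0 this reduces to
#' [predict_static()].
#'
#' @inheritParams predict_exact
#' @return a [predictive_dist()]. A warning is issued for `eps > 0.2`, where
#'   the truncation is unreliable.
#' @export
predict_small_eps <- function(history, kernel, eps, grid = angle_grid()) {
  grid <- check_grid(grid)
  check_eps(eps)
  if (eps > 0.2)
    warning("small-eps truncation requested with eps > 0.2; result may be inaccurate")
  history <- wrap_deg(as.numeric(history))
  n <- length(history)
  if (n == 0) return(uniform_dist(grid))
  ## terms are products of f_j / P0 under the independence assumption
  ## P(theta_seg) = P0^l; assembled in log space, one final renormalization.
  dx <- grid_spacing(grid)
  log_f <- lapply(history, function(th) {
    lf <- kernel_log_unnorm(kernel, ang_diff_deg(as.numeric(grid), th))
    f <- exp(lf - max(lf))
    log(f / (sum(f) * dx)) + log(360)  # log(f_j / P0)
  })
  ## trailing cumulative sums: S_l = sum_{j = n-l+1..n} log(f_j/P0), S_0 = 0
  S <- vector("list", n + 1)
  S[[1]] <- rep(0, length(grid))
  for (l in 1:n) S[[l + 1]] <- S[[l]] + log_f[[n - l + 1]]
  M <- max(vapply(S, max, numeric(1)))
  dens <- (1 - n * eps) * exp(S[[n + 1]] - M)
  for (l in 0:(n - 1)) dens <- dens + eps * exp(S[[l + 1]] - M)
  dens <- pmax(dens, 0)
  predictive_dist(grid, dens)
}
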