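## Independent oracles used across the suite.

## Brute-force change-point enumeration of the sequential predictive
## distribution: enumerate all 2^n configurations of change indicators at the
## n trial boundaries; each contributes the normalized product of the kernel
## densities over the trailing unchanged segment, weighted by the
## configuration probability.
enumerate_predictive <- function(history, kernel, eps, grid) {
  n <- length(history)
  dx <- attr(grid, "spacing")
  norm_prod <- function(targets) {
    if (length(targets) == 0) return(rep(1 / 360, length(grid)))
    f <- rep(1, length(grid))
    for (th in targets) f <- f * kernel_density(kernel, th, grid)
    f / (sum(f) * dx)
  }
  dens <- rep(0, length(grid))
  for (cfg in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(cfg))[1:n]   # bits[j]: change at boundary j
    p <- prod(ifelse(bits == 1, eps, 1 - eps))
    last <- if (any(bits == 1)) max(which(bits == 1)) else 0
    seg <- if (last == n) numeric(0) else history[(last + 1):n]
    dens <- dens + p * norm_prod(seg)
  }
  dens / (sum(dens) * dx)
}

## direct quadrature of the exponential-of-cosines kernel density
quadrature_kernel <- function(a1, center, grid) {
  dx <- attr(grid, "spacing")
  v <- exp(a1 * cos(pi / 180 * (as.numeric(grid) - center)))
  v / (sum(v) * dx)
}

## run-length probabilities by explicit enumeration of change/no-change
## sequences over n steps
enumerate_runlength <- function(n, eps) {
  probs <- numeric(n + 1)
  for (cfg in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(cfg))[1:n]
    p <- prod(ifelse(bits == 1, eps, 1 - eps))
    last <- if (any(bits == 1)) max(which(bits == 1)) else 0
    l <- n - last
    probs[l + 1] <- probs[l + 1] + p
  }
  probs
}

## total-variation distance between a binned empirical sample and a density
tv_distance <- function(samples, grid, density, n_bins = 60) {
  edges <- seq(-180, 180, length.out = n_bins + 1)
  counts <- table(cut(samples, edges, include.lowest = TRUE))
  p_emp <- as.numeric(counts) / length(samples)
  dx <- attr(grid, "spacing")
  cdf_bin <- function(lo, hi) {
    sel <- as.numeric(grid) >= lo & as.numeric(grid) < hi
    sum(density[sel]) * dx
  }
  p_th <- mapply(cdf_bin, edges[-length(edges)], edges[-1])
  p_th <- p_th / sum(p_th)
  0.5 * sum(abs(p_emp - p_th))
}
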