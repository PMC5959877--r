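g <- angle_grid(720)   # 0.5 deg resolution is ample for these checks
dx <- attr(g, "spacing")
k1 <- tuning_kernel(1)

test_that("tuning kernel densities are normalized, even, and shift invariant", {
  f0 <- kernel_density(tuning_kernel(0), 0, g)
  expect_equal(f0, rep(1 / 360, length(g)), tolerance = 1e-12)
  f <- kernel_density(k1, 0, g)
  expect_lt(abs(sum(f) * dx - 1), 1e-10)
  expect_equal(as.numeric(g)[which.max(f)], 0)
  ## even about the center
  expect_equal(f, rev(c(f[-1], f[1])), tolerance = 1e-12)
  ## shift invariance: recentered density is a circular shift
  f90 <- kernel_density(k1, 90, g)
  shift <- 90 / dx
  expect_equal(f90, f[((seq_along(f) - 1 - shift) %% length(f)) + 1],
               tolerance = 1e-12)
  ## self-conjugacy f_a(b) = f_b(a) on a handful of angle pairs
  for (pair in list(c(10, 40), c(-120, 35), c(170, -170))) {
    ia <- which.min(abs(ang_diff_deg(as.numeric(g), pair[1])))
    ib <- which.min(abs(ang_diff_deg(as.numeric(g), pair[2])))
    expect_equal(kernel_density(k1, pair[2], g)[ia],
                 kernel_density(k1, pair[1], g)[ib], tolerance = 1e-12)
  }
})

test_that("kernel density matches direct quadrature of the cosine exponential", {
  f <- kernel_density(k1, 0, g)
  expect_equal(f, quadrature_kernel(1, 0, g), tolerance = 1e-12)
  idx <- vapply(c(0, 90, 180), function(th) which.min(abs(as.numeric(g) - th)), 1L)
  expect_equal(f[idx], quadrature_kernel(1, 0, g)[idx], tolerance = 1e-12)
})

test_that("kernel evaluation rejects non-uniform grids", {
  expect_error(kernel_density(k1, 0, c(-180, -90, 0, 45)), "invalid grid")
})

test_that("run-length prior follows the printed geometric form", {
  expect_equal(runlength_prior(2, 0.5), c(0.5, 0.25, 0.25))
  expect_equal(runlength_prior(4, 1), c(1, 0, 0, 0, 0))
  expect_equal(sum(runlength_prior(7, 0.37)), 1)
  ## enumeration over explicit change/no-change sequences
  expect_equal(runlength_prior(5, 0.1), enumerate_runlength(5, 0.1),
               tolerance = 1e-12)
  expect_error(runlength_prior(3, 1.2), "probability")
})

test_that("exact predictive distribution: uniform limits", {
  u <- predict_exact(numeric(0), k1, 0.3, g)
  expect_equal(u$density, rep(1 / 360, length(g)), tolerance = 1e-12)
  u2 <- predict_exact(c(10, -40, 80), k1, 1, g)
  expect_equal(u2$density, rep(1 / 360, length(g)), tolerance = 1e-12)
})

test_that("exact predictive matches change-point enumeration oracle", {
  set.seed(42)
  for (eps in c(0.1, 0.5, 0.9)) {
    for (n in c(3, 5)) {
      hist <- runif(n, -180, 180)
      got <- predict_exact(hist, k1, eps, g)$density
      want <- enumerate_predictive(hist, k1, eps, g)
      expect_lt(max(abs(got - want)), 1e-10)
    }
  }
})

test_that("exact predictive with eps = 0 equals the static product", {
  set.seed(7)
  for (n in c(1, 4, 8)) {
    hist <- runif(n, -180, 180)
    expect_lt(max(abs(predict_exact(hist, k1, 0, g)$density -
                      predict_static(hist, k1, g)$density)), 1e-12)
  }
})

test_that("static predictive: single observation, batch-iterative identity, permutation invariance", {
  f <- predict_static(25, k1, g)
  expect_equal(f$density, kernel_density(k1, 25, g), tolerance = 1e-12)
  ## iterative one-step updates agree with the batch product
  hist <- c(-60, 10, 45, 170)
  batch <- predict_static(hist, k1, g)$density
  iter <- rep(1 / 360, length(g))
  for (th in hist) {
    iter <- iter * kernel_density(k1, th, g)
    iter <- iter / (sum(iter) * dx)
  }
  expect_lt(max(abs(batch - iter)), 1e-12)
  ## permutation invariance
  expect_lt(max(abs(batch - predict_static(rev(hist), k1, g)$density)), 1e-12)
})

test_that("repeated identical observations sharpen the static predictive", {
  peaks <- vapply(1:5, function(n) max(predict_static(rep(0, n), k1, g)$density), 1)
  expect_true(all(diff(peaks) > 0))
})

test_that("rapid-change truncation: printed mixture and uniform limit", {
  r <- predict_rapid(0, k1, 0.8, g, order = 1)
  expect_equal(r$density, 0.8 / 360 + 0.2 * kernel_density(k1, 0, g),
               tolerance = 1e-12)
  r1 <- predict_rapid(c(20, 50), k1, 1, g)
  expect_equal(r1$density, rep(1 / 360, length(g)), tolerance = 1e-12)
  expect_error(predict_rapid(0, k1, 0.5, g, order = 3), "order")
})

test_that("rapid truncation converges to the exact single-target mixture as eps -> 1", {
  dists <- vapply(c(0.9, 0.99, 0.999), function(eps) {
    max(abs(predict_rapid(30, k1, eps, g, 1)$density -
            predict_exact(30, k1, eps, g)$density))
  }, 1)
  expect_equal(dists, c(0, 0, 0), tolerance = 1e-12)  # order 1 is exact at n = 1
  ## for a two-target history the truncations differ; both shrink with eps
  d2 <- vapply(c(0.9, 0.99, 0.999), function(eps) {
    max(abs(predict_rapid(c(-45, 30), k1, eps, g, 1)$density -
            predict_exact(c(-45, 30), k1, eps, g)$density))
  }, 1)
  expect_true(all(diff(d2) < 0))
})

test_that("second-order rapid truncation beats first order on a two-target history", {
  hist <- c(-45, 30)
  for (eps in c(0.7, 0.8, 0.9, 0.99)) {
    exact <- predict_exact(hist, k1, eps, g)$density
    d1 <- max(abs(predict_rapid(hist, k1, eps, g, 1)$density - exact))
    d2 <- max(abs(predict_rapid(hist, k1, eps, g, 2)$density - exact))
    expect_lt(d2, d1)
  }
})

test_that("small-eps truncation: static limit, printed n = 1 form, accuracy ordering", {
  hist <- c(-20, 65, 140)
  expect_lt(max(abs(predict_small_eps(hist, k1, 0, g)$density -
                    predict_static(hist, k1, g)$density)), 1e-12)
  ## n = 1: mixture of the kernel and uniform terms, renormalized
  eps <- 0.05
  want <- (1 - eps) * kernel_density(k1, 40, g) * 360 + eps
  want <- want / (sum(want) * dx)
  expect_lt(max(abs(predict_small_eps(40, k1, eps, g)$density - want)), 1e-12)
  ## closer to exact than the rapid-change truncation when eps is small
  exact <- predict_exact(hist, k1, 0.01, g)$density
  d_small <- max(abs(predict_small_eps(hist, k1, 0.01, g)$density - exact))
  d_rapid <- max(abs(predict_rapid(hist, k1, 0.01, g, 1)$density - exact))
  expect_lt(d_small, d_rapid)
  expect_warning(predict_small_eps(hist, k1, 0.5, g), "eps")
})

test_that("every predictive distribution is nonnegative and normalized", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(0:6, 1)
    hist <- runif(n, -180, 180)
    eps <- runif(1)
    d <- predict_exact(hist, k1, eps, g)
    expect_true(all(d$density >= 0))
    expect_lt(abs(sum(d$density) * dx - 1), 1e-10)
  }
})
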