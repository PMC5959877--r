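p_fast <- field_params(dx = 0.72)          # 500-point fast profile
p_h <- field_params(dx = 0.72, firing_rate_mode = "heaviside")

test_that("Heaviside stationary bump solves the threshold condition exactly", {
  b <- stationary_bump(p_h)
  a_root <- (pi - asin(0.1)) / 2            # stable wide branch of sin(2a) = kappa
  expect_equal(b$half_width_rad, a_root, tolerance = 1e-12)
  expect_equal(sin(2 * b$half_width_rad), 0.1, tolerance = 1e-12)
  expect_equal(b$amplitude, 2 * sin(a_root), tolerance = 1e-9)
  ## U(+-a) = kappa: evaluate the closed-form profile at the half-width
  expect_equal(2 * sin(a_root) * cos(a_root), 0.1, tolerance = 1e-12)
})

test_that("stationary bump satisfies the convolution fixed-point equation", {
  ## sigmoid mode: the gridded convolution reproduces the profile to
  ## round-off; Heaviside mode: the closed form is checked analytically
  ## (int_{-a}^{a} cos(x - y) dy = 2 sin(a) cos(x))
  b <- stationary_bump(p_fast)
  resid <- serialwm:::field_convolve(serialwm:::firing_rate(b$u, p_fast), p_fast) - b$u
  expect_lt(max(abs(resid)), 1e-8)
  bh <- stationary_bump(p_h)
  x <- pi / 180 * as.numeric(field_grid(p_h))
  expect_equal(bh$u, 2 * sin(bh$half_width_rad) * cos(x), tolerance = 1e-12)
  ## weak coupling with a high threshold admits no suprathreshold solution
  expect_error(stationary_bump(field_params(dx = 0.72, weight_harmonics = 0.5,
                                            kappa = 0.6)), "no bump")
})

test_that("sigmoid bump is close to the high-gain limit", {
  bh <- stationary_bump(p_h)
  bs <- stationary_bump(p_fast)
  expect_lt(abs(bs$amplitude - bh$amplitude) / bh$amplitude, 0.02)
  expect_lt(abs(bs$half_width_deg - bh$half_width_deg), 2)
})

test_that("stationary facilitation is the printed plateau over the bump", {
  b <- stationary_bump(p_h)
  Q <- stationary_stf(p_h, b)
  plateau <- 0.01 * 2 / 1.01
  x <- as.numeric(field_grid(p_h))
  inside <- abs(x) < b$half_width_deg - 1
  outside <- abs(x) > b$half_width_deg + 1
  expect_equal(unique(Q[inside]), plateau, tolerance = 1e-12)
  expect_true(all(Q[outside] == 0))
  p0 <- field_params(dx = 0.72, beta = 0, firing_rate_mode = "heaviside")
  expect_true(all(stationary_stf(p0, b) == 0))
})

test_that("facilitation ODE relaxes to the stationary plateau under a clamped bump", {
  b <- stationary_bump(p_h)
  Fu <- serialwm:::firing_rate(b$u, p_h)
  q <- rep(0, p_h$nx)
  dt <- 1
  for (i in 1:20000) {
    q <- q + dt / p_h$tau * (-q + p_h$beta * Fu * (p_h$q_plus - q))
  }
  expect_lt(max(abs(q - stationary_stf(p_h, b))), 1e-6)
})

test_that("noise increments have the stated mean and spatial covariance", {
  p <- field_params(dx = 45)               # 8-point grid for cheap Monte Carlo
  set.seed(5)
  n <- 1e5; dt <- 1
  m <- t(replicate(n, noise_increment(p, dt)))
  se <- p$sigma_W * sqrt(dt) / sqrt(n)
  expect_true(all(abs(colMeans(m)) < 3 * se))
  ## x = 0 vs y = 0: variance sigma_W^2 dt; x = 0 vs y = 90: zero covariance
  x <- as.numeric(field_grid(p))
  i0 <- which(x == 0); i90 <- which(x == 90)
  expect_lt(abs(var(m[, i0]) - p$sigma_W^2 * dt) / (p$sigma_W^2 * dt), 0.05)
  expect_lt(abs(cor(m[, i0], m[, i90])), 0.01)
  ## increments at distinct times are uncorrelated
  expect_lt(abs(cor(m[seq(1, n - 1, 2), i0], m[seq(2, n, 2), i0])), 0.01)
})

test_that("the stationary bump is a fixed point of the deterministic step", {
  p <- field_params(dx = 0.72, beta = 0, sigma_W = 0)
  b <- stationary_bump(p)
  st <- list(u = b$u, q = rep(0, p$nx))
  st2 <- field_step(st, p, 0, dt = 0.5)
  expect_lt(max(abs(st2$u - st$u)), 1e-8)
  expect_true(all(st2$q == 0))
})

test_that("subthreshold activity decays at rate 1/tau_u", {
  p <- field_params(dx = 0.72, sigma_W = 0)
  u0 <- rep(0.02, p$nx)                    # far below threshold, F ~ const
  st <- list(u = u0, q = rep(0, p$nx))
  st2 <- field_step(st, p, 0, dt = 0.1)
  ## mean-free coupling kills the uniform convolution term entirely
  expect_equal(st2$u, u0 * (1 - 0.1 / p$tau_u), tolerance = 1e-10)
})

test_that("a facilitated patch offset from the bump attracts it", {
  p <- field_params(dx = 1.44, sigma_W = 0)   # 250 points: cheap pure-R loop
  b <- stationary_bump(p)
  Q <- stationary_stf(p, b)
  x <- as.numeric(field_grid(p))
  shift <- round(30 / p$dx)
  q30 <- Q[((seq_along(Q) - 1 - shift) %% length(Q)) + 1]  # patch at +30 deg
  st <- list(u = b$u, q = q30)
  for (i in 1:2000) st <- field_step(st, p, 0, dt = 0.5)   # 1 s
  center <- bump_center(st$u, field_grid(p))
  expect_gt(center, 1)      # moved toward the facilitated location
  expect_lt(center, 30.1)
})

test_that("bump collapse and step blow-up are reported", {
  p <- field_params(dx = 0.72, sigma_W = 0)
  expect_error(field_step(list(u = rep(Inf, p$nx), q = rep(0, p$nx)), p, 0, 0.1),
               "blow-up")
})

test_that("bump_center: node readout, subthreshold none, tie centroid", {
  grid <- angle_grid(2000)                  # dx = 0.18: 17.28 is a node
  u <- 2 * cos(pi / 180 * (as.numeric(grid) - 17.28))
  expect_equal(bump_center(u, grid), 17.28)
  expect_true(is.na(bump_center(rep(-1, 2000), grid)))
  u2 <- rep(0, 2000); u2[c(500, 502)] <- 0.5  # symmetric tie around node 501
  expect_equal(bump_center(u2, grid, kappa = 0.1),
               as.numeric(grid)[501], tolerance = 1e-9)
})

test_that("argmax and circular-centroid readouts agree on noisy bumps", {
  p <- field_params(dx = 1.44, sigma_W = 0.05)   # strong noise, coarse grid
  b <- stationary_bump(p)
  g <- field_grid(p)
  xr <- pi / 180 * as.numeric(g)
  set.seed(31)
  st <- list(u = b$u, q = rep(0, p$nx))
  dis <- numeric(1000)
  for (i in 1:5000) {
    st <- field_step(st, p, 0, dt = 0.5, noise = noise_increment(p, 0.5))
    if (i %% 5 == 0) {
      am <- bump_center(st$u, g)
      w <- pmax(st$u, 0)
      cen <- atan2(sum(sin(xr) * w), sum(cos(xr) * w)) * 180 / pi
      dis[i / 5] <- abs(ang_diff_deg(am, cen))
    }
  }
  expect_lt(mean(dis), 3 * p$dx)
})

test_that("noise-free trials reproduce the cue exactly and bias toward the previous target", {
  p <- field_params(dx = 0.72, sigma_W = 0)
  s1 <- build_schedule(1, delay = 1000, iti = 1000, sampler = 45)
  r1 <- run_trials(s1, p, seed = 1, dt = 0.5)
  expect_equal(r1$bias_deg, 0, tolerance = 1e-9)
  expect_true(r1$valid)
  s2 <- build_schedule(2, delay = 2000, iti = 1000, sampler = c(45, 0))
  r2 <- run_trials(s2, p, seed = 1, dt = 0.5)
  expect_gt(r2$bias_deg[2], 0)
})

test_that("noise-free responses are equivariant under global rotation of targets", {
  p <- field_params(dx = 0.72, sigma_W = 0)
  s <- build_schedule(3, delay = 1000, iti = 1000, sampler = c(45, 0, -120))
  r <- run_trials(s, p, seed = 1, dt = 0.5)
  srot <- build_schedule(3, delay = 1000, iti = 1000, sampler = c(45, 0, -120) + 36)
  rrot <- run_trials(srot, p, seed = 1, dt = 0.5)
  expect_equal(ang_diff_deg(rrot$response_deg, r$response_deg + 36),
               rep(0, 3), tolerance = 1e-6)
})

test_that("fast profile matches the printed-resolution profile on a fixed trial", {
  sched <- build_schedule(2, delay = 1000, iti = 1000, sampler = c(60, 0))
  pf <- field_params(dx = 0.72, sigma_W = 0)
  pp <- field_params(dx = 0.18, sigma_W = 0)
  rf <- run_trials(sched, pf, seed = 1, dt = 0.5)
  rp <- run_trials(sched, pp, seed = 1, dt = 0.1)
  expect_lt(max(abs(ang_diff_deg(rf$response_deg, rp$response_deg))), 0.5)
})

test_that("facilitation stays within its physical bounds during trials", {
  p <- field_params(dx = 1.44)
  b <- stationary_bump(p)
  st <- list(u = b$u, q = rep(0, p$nx))
  set.seed(8)
  for (i in 1:500) {
    st <- field_step(st, p, 0, dt = 0.5, noise = noise_increment(p, 0.5))
    expect_true(all(st$q >= -1e-9 & st$q <= p$q_plus + 1e-9))
  }
})
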