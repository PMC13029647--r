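test_that("mu1 equals D on a flat chemostat series", {
  s <- cell_count_series(seq(0, 20, 2), rep(180, 11))
  est <- estimate_mu1(s, D = 0.2)
  expect_equal(est$mu1, rep(0.2, 11))
})

test_that("mu1 recovers D + g on an exponential series", {
  g <- 0.15
  tt <- seq(0, 10, 0.05)  # dense so finite differences are near-exact
  s <- cell_count_series(tt, 50 * exp(g * tt))
  est <- estimate_mu1(s, D = 0.2)
  inner <- est$mu1[3:(length(tt) - 2)]
  expect_equal(inner, rep(0.2 + g, length(inner)), tolerance = 1e-3)
})

test_that("mu1 on a noisy steady control averages to D", {
  set.seed(5)
  sdlog <- sqrt(log(1 + 0.1^2))
  tt <- seq(0, 33, 3)
  s <- cell_count_series(tt, 200 * rlnorm(length(tt), -sdlog^2 / 2, sdlog))
  est <- estimate_mu1(s, D = 0.2)
  expect_lt(abs(mean(est$mu1) - 0.2), 0.05)
  expect_error(estimate_mu1(cell_count_series(0:3, c(0, 1, 2, 3)), 0.2),
               "positive")
})

test_that("pointwise mu2 matches direct substitution on constant series", {
  tt <- seq(0, 12, 2)
  ctrl <- cell_count_series(tt, rep(100, 7))
  # X2 constant and equal to X1: mu2 = 0
  expd <- cell_count_series(tt, rep(100, 7), "experimental")
  expect_equal(estimate_mu2_pointwise(ctrl, expd, 0.2)$mu2, rep(0, 7))
  # X2 constant = 50, X1 = 100, D = 0.2: mu2 = (0 - 20 + 10)/50
  expd2 <- cell_count_series(tt, rep(50, 7), "experimental")
  expect_equal(estimate_mu2_pointwise(ctrl, expd2, 0.2)$mu2, rep(-0.2, 7))
})

test_that("pointwise mu2 recovers the generating rate on dense data", {
  p <- cascade_params(D = 0.2, mu2 = -1.07, X1_0 = 200, X2_0 = 200)
  tt <- seq(0, 30, 0.1)
  traj <- simulate_cascade(p, tt)
  ctrl <- cell_count_series(tt, traj$X1)
  expd <- cell_count_series(tt, traj$X2, "experimental")
  est <- estimate_mu2_pointwise(ctrl, expd, 0.2)
  inner <- est$mu2[3:(nrow(est) - 2)]
  expect_lt(max(abs(inner - (-1.07))), 0.05)
})

test_that("pointwise mu2 error shrinks with the grid step", {
  p <- cascade_params(D = 0.2, mu2 = -0.6, X1_0 = 200, X2_0 = 200)
  err <- sapply(c(1, 0.5, 0.1), function(h) {
    tt <- seq(0, 20, h)
    traj <- simulate_cascade(p, tt)
    est <- estimate_mu2_pointwise(cell_count_series(tt, traj$X1),
                                  cell_count_series(tt, traj$X2,
                                                    "experimental"), 0.2)
    max(abs(est$mu2[3:(nrow(est) - 2)] + 0.6))
  })
  expect_true(all(diff(err) < 0))
})

test_that("global mu2 fit is exact on noise-free data and ~0 on control", {
  tt <- seq(0, 33, 3)
  ctrl <- cell_count_series(tt, rep(200, length(tt)))
  p <- cascade_params(D = 0.2, mu2 = -0.5, X1_0 = 200, X2_0 = 200)
  expd <- cell_count_series(tt, analytic_X2(tt, p), "experimental")
  fit <- fit_mu2_constant(ctrl, expd, 0.2, n_boot = 0)
  expect_equal(fit$mu2, -0.5, tolerance = 1e-6)
  # series identical to control: mu2 ~ 0
  fit0 <- fit_mu2_constant(ctrl, cell_count_series(tt, rep(200, length(tt)),
                                                   "experimental"),
                           0.2, n_boot = 0)
  expect_lt(abs(fit0$mu2), 1e-4)
})

test_that("fitted mu2 is negative when X2 settles below X1", {
  set.seed(9)
  tt <- seq(0, 33, 3)
  sdlog <- sqrt(log(1 + 0.1^2))
  p <- cascade_params(D = 0.2, mu2 = -0.8, X1_0 = 200, X2_0 = 200)
  for (i in 1:10) {
    ctrl <- cell_count_series(tt, 200 * rlnorm(12, -sdlog^2 / 2, sdlog))
    expd <- cell_count_series(tt, analytic_X2(tt, p) *
                                rlnorm(12, -sdlog^2 / 2, sdlog),
                              "experimental")
    expect_lt(fit_mu2_constant(ctrl, expd, 0.2, n_boot = 0)$mu2, 0)
  }
})

test_that("bootstrap half-width is seeded and reproducible", {
  set.seed(31)
  tt <- seq(0, 33, 3)
  sdlog <- sqrt(log(1 + 0.1^2))
  p <- cascade_params(D = 0.2, mu2 = -0.5, X1_0 = 200, X2_0 = 200)
  ctrl <- cell_count_series(tt, 200 * rlnorm(12, -sdlog^2 / 2, sdlog))
  expd <- cell_count_series(tt, analytic_X2(tt, p) *
                              rlnorm(12, -sdlog^2 / 2, sdlog), "experimental")
  f1 <- fit_mu2_constant(ctrl, expd, 0.2, n_boot = 50, seed = 4)
  f2 <- fit_mu2_constant(ctrl, expd, 0.2, n_boot = 50, seed = 4)
  expect_identical(f1$boot, f2$boot)
  expect_true(is.finite(f1$half_width) && f1$half_width > 0)
})

test_that("series constructors and grid handling reject bad input", {
  expect_error(cell_count_series(c(0, 1), c(1, 2)), "at least 3")
  expect_error(cell_count_series(c(0, 1, 1), c(1, 2, 3)), "increasing")
  expect_error(cell_count_series(0:3, c(1, -1, 2, 3)), "non-negative")
  # non-overlapping grids
  ctrl <- cell_count_series(0:5, rep(10, 6))
  expd <- cell_count_series(10:15, rep(10, 6), "experimental")
  expect_error(estimate_mu2_pointwise(ctrl, expd, 0.2), "overlap")
  # zero counts floored with a warning in the pointwise estimator
  expd0 <- cell_count_series(0:5, c(4, 2, 0, 2, 4, 4), "experimental")
  expect_warning(estimate_mu2_pointwise(ctrl, expd0, 0.2), "floored")
})
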