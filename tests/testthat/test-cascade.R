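test_that("cascade_rhs matches the cell balance and its fixed points", {
  # steady reactor 1: mu1 = D gives dX1 = 0
  p <- cascade_params(D = 0.2, mu1 = 0.2, mu2 = -0.3, X1_0 = 100)
  expect_equal(unname(cascade_rhs(100, 100, p)[1]), 0)
  # empty reactors stay empty
  expect_equal(unname(cascade_rhs(0, 0, p)), c(0, 0))
  # direct substitution: D*X1 + (mu2 - D)*X2
  p2 <- cascade_params(D = 0.2, mu2 = -1.0, X1_0 = 200, X2_0 = 50)
  expect_equal(unname(cascade_rhs(200, 50, p2)[2]), 0.2 * 200 + (-1.2) * 50)
  expect_error(cascade_rhs(-1, 10, p), "non-negative")
})

test_that("cascade_params validates its invariants", {
  expect_error(cascade_params(D = 0), "positive")
  expect_error(cascade_params(D = 0.2, X1_0 = -5), "non-negative")
  expect_error(cascade_params(D = NA_real_), "finite")
})

test_that("analytic_X2 satisfies initial condition and mu2 = 0 limit", {
  p <- cascade_params(D = 0.2, mu2 = -1.07, X1_0 = 200, X2_0 = 75)
  expect_equal(analytic_X2(0, p), 75)
  # mu2 = 0: X2 converges to X1
  p0 <- cascade_params(D = 0.2, mu2 = 0, X1_0 = 140, X2_0 = 10)
  expect_equal(analytic_X2(500, p0), 140, tolerance = 1e-10)
  expect_error(analytic_X2(10, cascade_params(D = 0.2, mu2 = 0.2)),
               "degenerate|linear")
})

test_that("closed form agrees with high-accuracy ODE integration", {
  # frozen spot check: D=0.2, X1=200, mu2=-1.07, tau=30
  p <- cascade_params(D = 0.2, mu2 = -1.07, X1_0 = 200, X2_0 = 200)
  tt <- seq(0, 30, by = 0.5)
  traj <- simulate_cascade(p, tt)
  expect_equal(traj$X2, analytic_X2(tt, p), tolerance = 1e-6)
  # randomized draws, fixed seed
  set.seed(42)
  for (i in 1:25) {
    D <- runif(1, 0.05, 1)
    p <- cascade_params(D = D, mu2 = runif(1, -2, D - 0.01),
                        X1_0 = runif(1, 10, 400), X2_0 = runif(1, 0, 400))
    tt <- seq(0, 50, length.out = 51)
    traj <- simulate_cascade(p, tt)
    ref <- analytic_X2(tt, p)
    expect_lt(max(abs(traj$X2 - ref) / pmax(ref, 1e-8)), 1e-5)
  }
})

test_that("steady_state_X2 gives the closed-form plateau or divergence", {
  expect_equal(steady_state_X2(cascade_params(D = 0.2, mu2 = 0, X1_0 = 123)),
               123)
  p <- cascade_params(D = 0.2, mu2 = -1.07, X1_0 = 200)
  expect_equal(steady_state_X2(p), 40 / 1.27)
  # cross-check by long-horizon integration
  traj <- simulate_cascade(p, seq(0, 200, length.out = 201))
  expect_equal(traj$X2[201], 40 / 1.27, tolerance = 1e-6)
  div <- steady_state_X2(cascade_params(D = 0.2, mu2 = 0.3))
  expect_identical(unname(as.numeric(div)), Inf)
  expect_true(attr(div, "diverges"))
})

test_that("regime classification covers all five branches", {
  expect_identical(classify_regime(cascade_params(D = 0.2, mu2 = 0.1)),
                   "STABILIZE_ABOVE_X1")
  expect_identical(classify_regime(cascade_params(D = 0.2, mu2 = 0)),
                   "EQUAL_X1")
  expect_identical(classify_regime(cascade_params(D = 0.2, mu2 = -1.07)),
                   "BELOW_X1")
  expect_identical(classify_regime(cascade_params(D = 0.2, mu2 = 0.5)),
                   "EXPONENTIAL_GROWTH")
  expect_identical(classify_regime(cascade_params(D = 0.2, mu2 = 0.2)),
                   "LINEAR_GROWTH")
})

test_that("regime label is consistent with the long-horizon limit vs X1", {
  set.seed(7)
  D <- 0.3
  for (mu2 in c(runif(5, -2, -0.01), 0, runif(5, 0.01, D - 0.01))) {
    p <- cascade_params(D = D, mu2 = mu2, X1_0 = 150, X2_0 = 150)
    lim <- steady_state_X2(p)
    lab <- classify_regime(p)
    if (lab == "BELOW_X1") expect_lt(lim, p$X1_0)
    if (lab == "EQUAL_X1") expect_equal(lim, p$X1_0)
    if (lab == "STABILIZE_ABOVE_X1") expect_gt(lim, p$X1_0)
  }
})

test_that("simulate_cascade handles fixed point and the linear regime", {
  # mu1 = D, mu2 = 0, X2_0 = X1_0: everything constant
  p <- cascade_params(D = 0.25, mu2 = 0, X1_0 = 90, X2_0 = 90)
  traj <- simulate_cascade(p, seq(0, 20, 2))
  expect_equal(traj$X1, rep(90, 11))
  expect_equal(traj$X2, rep(90, 11), tolerance = 1e-7)
  # mu2 = D: X2 grows linearly with slope D * X1
  pl <- cascade_params(D = 0.2, mu2 = 0.2, X1_0 = 100, X2_0 = 30)
  tt <- seq(0, 10, 1)
  trl <- simulate_cascade(pl, tt)
  expect_equal(trl$X2, 30 + 0.2 * 100 * tt, tolerance = 1e-6)
})

test_that("transient-X1 mode integrates both equations", {
  p <- cascade_params(D = 0.2, mu1 = 0.3, mu2 = 0, X1_0 = 50, X2_0 = 50)
  traj <- simulate_cascade(p, seq(0, 10, 1), steady_state = FALSE)
  expect_equal(traj$X1, 50 * exp(0.1 * traj$time_days), tolerance = 1e-6)
})

test_that("trajectory CSV round-trips", {
  p <- cascade_params(D = 0.2, mu2 = -0.5, X1_0 = 200, X2_0 = 100)
  traj <- simulate_cascade(p, seq(0, 10, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$X2, traj$X2, tolerance = 1e-9)
})
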