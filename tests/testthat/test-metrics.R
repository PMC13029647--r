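test_that("threshold crossing is located by linear interpolation", {
  s <- reactor_series(0:12, pH = 1.6 - 0.05 * (0:12))
  expect_equal(time_to_threshold(s, "pH", 1.2, "falling"), 8)
  # starting at the threshold
  s2 <- reactor_series(0:3, Eh_mV = c(800, 820, 840, 860))
  expect_equal(time_to_threshold(s2, "Eh_mV", 800, "rising"), 0)
  # never crossing
  expect_true(is.na(time_to_threshold(s, "pH", 0.5, "falling")))
  expect_error(time_to_threshold(s, "Eh_mV", 800, "rising"), "not present")
  # snapped mode reports the next sample time
  expect_equal(time_to_threshold(s, "pH", 1.19, "falling", snap = TRUE), 9)
})

test_that("raising a falling threshold never increases the crossing time", {
  set.seed(21)
  for (i in 1:10) {
    ph <- cummin(1.8 - cumsum(runif(15, 0, 0.08)))
    s <- reactor_series(seq(0, 28, 2), pH = ph)
    t_low <- time_to_threshold(s, "pH", 1.2, "falling")
    t_high <- time_to_threshold(s, "pH", 1.3, "falling")
    if (!is.na(t_low) && !is.na(t_high)) expect_lte(t_high, t_low)
  }
})

test_that("ferrous depletion requires a sustained sub-LOD tail", {
  s <- reactor_series(c(0, 6, 9, 12, 15),
                      fe2_gL = c(0.7, 0.7, 0.3, 0, 0))
  expect_equal(fe2_depletion_time(s, lod = 0.05), 12)
  # all-zero series depletes at the first sample
  s0 <- reactor_series(0:4, fe2_gL = rep(0, 5))
  expect_equal(fe2_depletion_time(s0), 0)
  # a transient dip does not count; the later sustained crossing does
  sd_ <- reactor_series(0:5, fe2_gL = c(0.7, 0.01, 0.4, 0.3, 0.02, 0))
  expect_equal(fe2_depletion_time(sd_), 4)
  # never sustained
  sn <- reactor_series(0:3, fe2_gL = c(0.5, 0.01, 0.4, 0.5))
  expect_true(is.na(fe2_depletion_time(sn)))
})

test_that("depletion time ignores appended post-depletion zeros", {
  s <- reactor_series(c(0, 6, 9, 12, 15), fe2_gL = c(0.7, 0.7, 0.3, 0, 0))
  s_ext <- reactor_series(c(0, 6, 9, 12, 15, 18, 21),
                          fe2_gL = c(0.7, 0.7, 0.3, 0, 0, 0, 0))
  expect_equal(fe2_depletion_time(s_ext), fe2_depletion_time(s))
})

test_that("lag phase is the interpolated sustained k-fold increase", {
  s <- reactor_series(c(0, 8, 16, 20, 24), cells_1e7_mL = c(1, 1, 1, 4, 16))
  expect_equal(lag_phase_duration(s, k_fold = 2), 16 + 4 / 3)
  # constant series never ends its lag
  sc <- reactor_series(0:4, cells_1e7_mL = rep(3, 5))
  expect_true(is.na(lag_phase_duration(sc)))
  # exponential growth from t = 0: lag ~ doubling time
  tt <- seq(0, 10, 0.25)
  se <- reactor_series(tt, cells_1e7_mL = 2 * exp(0.5 * tt))
  expect_equal(lag_phase_duration(se, k_fold = 2), log(2) / 0.5,
               tolerance = 0.05)
  # a spike that drops back is not a sustained crossing
  sp <- reactor_series(0:5, cells_1e7_mL = c(1, 5, 1, 1, 4, 16))
  expect_gt(lag_phase_duration(sp), 3)
  expect_error(lag_phase_duration(
    reactor_series(0:3, cells_1e7_mL = c(0, 1, 2, 3))), "positive")
})

test_that("reactor_series validates and warns on iron inconsistency", {
  expect_error(reactor_series(c(0, 0, 1), pH = c(1, 1, 1)), "increasing")
  expect_error(reactor_series(0:2, fe2_gL = c(1, -1, 1)), "negative")
  expect_warning(
    reactor_series(0:2, fe2_gL = c(1, 1, 1), fe3_gL = c(1, 1, 1),
                   fetot_gL = c(5, 5, 5)),
    "differs")
})

test_that("batch_metrics summarises a run and tolerates missing columns", {
  s <- reactor_series(seq(0, 28, 2),
                      pH = 1.6 - 0.03 * seq(0, 28, 2),
                      cells_1e7_mL = pmax(1, seq(-5, 9, 1)) * 2)
  m <- batch_metrics(s)
  expect_true(is.finite(m$t_pH))
  expect_true(is.na(m$t_Eh))          # no Eh column
  expect_true(is.na(m$t_fe2_depletion))
})
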