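test_that("burst-onset detection finds injected onsets and obeys the gap rule", {
  # constant subthreshold trace: no onsets
  expect_length(detect_burst_onsets(rep(-0.25, 1000), 1e-3), 0)

  fx <- make_voltage_with_bursts(c(1.0, 1.5, 2.0), dt = 1e-3)
  on <- detect_burst_onsets(fx$v, fx$dt, threshold = -0.05)
  expect_length(on, 3)
  expect_true(all(abs(as.numeric(on) - c(1.0, 1.5, 2.0)) <= 2e-3))

  # two crossings 1 ms apart with a 50 ms quiescence rule: one onset
  v <- rep(-0.2, 200)
  v[c(100, 102)] <- 0.1
  on2 <- detect_burst_onsets(v, 1e-3, threshold = 0, min_gap = 0.05)
  expect_length(on2, 1)
})

test_that("burst phase interpolates linearly between onsets and flags outside", {
  expect_equal(phase_from_onsets(c(0, 1, 3), 2), 2 * pi + pi)
  on <- c(0.5, 1.0, 1.7, 2.1)
  expect_equal(phase_from_onsets(on, 0.5) %% (2 * pi), 0)
  expect_equal(phase_from_onsets(on, 0.75) %% (2 * pi), pi)
  expect_equal(phase_from_onsets(on, 2.1), 2 * pi * 3)
  expect_true(is.na(phase_from_onsets(on, 0.4)))
  expect_true(is.na(phase_from_onsets(on, 2.2)))
  expect_true(all(is.na(phase_from_onsets(numeric(0), c(1, 2)))))
  # continuity and monotonicity on a dense grid
  t <- seq(0.5, 2.1, by = 1e-3)
  ph <- phase_from_onsets(on, t)
  expect_true(all(diff(ph) > 0))
})

test_that("order parameter equals the complex mean and its invariances hold", {
  expect_equal(order_parameter(rep(1.3, 50))$R, 1)
  # roots of unity sum to zero
  expect_lt(order_parameter(2 * pi * (0:9) / 10)$R, 1e-12)
  expect_equal(order_parameter(c(0, pi / 2))$R, sqrt(2) / 2)
  expect_equal(order_parameter(c(0, pi / 2))$Theta, pi / 4)

  set.seed(13)
  for (i in 1:1000) {
    ph <- runif(sample(2:40, 1), -10, 10)
    got <- order_parameter(ph)
    want <- oracle_order_parameter(ph)
    expect_equal(got$R, unname(want["R"]), tolerance = 1e-12)
  }
  # global phase shift and neuron permutation leave R unchanged
  set.seed(14)
  ph <- runif(30, 0, 2 * pi)
  for (i in 1:20) {
    expect_equal(order_parameter(ph + runif(1, -10, 10))$R,
                 order_parameter(ph)$R, tolerance = 1e-12)
    expect_equal(order_parameter(sample(ph))$R, order_parameter(ph)$R,
                 tolerance = 1e-12)
  }
  expect_error(order_parameter(c(NA_real_, NA_real_)), "valid phases")
})

test_that("time-resolved R and its window average behave as derived", {
  # two identical trains: R(t) = 1 wherever defined
  tr <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  sy <- sync_series(tr, dt_grid = 0.01)
  expect_true(all(abs(sy$R[is.finite(sy$R)] - 1) < 1e-12))
  expect_equal(mean_R(sy), 1, tolerance = 1e-12)

  # synthetic series: linear ramp averages to its midpoint
  ramp <- structure(list(times = seq(0, 1, by = 1e-3),
                         R = seq(0, 1, by = 1e-3)), class = "sync_series")
  expect_equal(mean_R(ramp), 0.5, tolerance = 1e-3)
  expect_equal(mean_R(ramp, c(0, 0.5)), 0.25, tolerance = 1e-3)
  # sampled sine over whole periods averages to its offset
  t <- seq(0, 4 * pi, length.out = 20001)
  sine <- structure(list(times = t, R = 0.5 + 0.4 * sin(t)),
                    class = "sync_series")
  expect_equal(mean_R(sine), 0.5, tolerance = 1e-3)
  expect_error(mean_R(ramp, c(2, 3)))
})
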