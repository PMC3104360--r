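test_that("Morris-Lecar gating curves take canonical values and are monotone", {
  p <- ml_params()
  gc <- ml_gating_curves(p$v1, p)
  expect_equal(gc$m_inf, 0.5)
  gc3 <- ml_gating_curves(p$v3, p)
  expect_equal(gc3$w_inf, 0.5)
  expect_equal(gc3$tau_w, 1)
  far <- ml_gating_curves(10, p)
  expect_equal(far$m_inf, 1, tolerance = 1e-12)
  expect_equal(far$w_inf, 1, tolerance = 1e-12)

  v <- seq(-1, 1, length.out = 2001)
  curves <- ml_gating_curves(v, p)
  expect_true(all(diff(curves$m_inf) >= 0))
  expect_true(all(diff(curves$w_inf) >= 0))
  expect_true(all(curves$tau_w > 0))
  expect_true(all(curves$m_inf >= 0 & curves$m_inf <= 1))
})

test_that("Morris-Lecar derivatives match the closed-form right-hand side", {
  p <- ml_params()
  g <- gate_params()
  st <- list(v = 0, w = 0, I_slow = 0, s = 0)
  d <- ml_derivatives(st, v_delayed = p$v_star, params = p, gate = g)
  expect_equal(d$dv, oracle_ml_dv(0, 0, 0, 0, p), tolerance = 1e-14)
  # set-point equilibrium of the slow current
  expect_equal(d$dI_slow, 0)

  # general random states against the independent arithmetic
  set.seed(42)
  for (i in 1:25) {
    st <- list(v = runif(1, -0.5, 0.3), w = runif(1), I_slow = runif(1, -0.1, 0.1),
               s = runif(1))
    Iin <- rnorm(3, 0, 0.05)
    d <- ml_derivatives(st, v_delayed = rnorm(1, -0.2, 0.1),
                        I_syn = Iin[1], I_noise = Iin[2], I_stim = Iin[3],
                        X1 = 1, params = p, gate = g)
    expect_equal(d$dv, oracle_ml_dv(st$v, st$w, st$I_slow, sum(Iin), p),
                 tolerance = 1e-13)
  }
  # the slow-current relaxation term
  p2 <- ml_params(alpha = 0.5)
  d2 <- ml_derivatives(list(v = 0, w = 0, I_slow = 0.02, s = 0),
                       v_delayed = -0.3, params = p2)
  expect_equal(d2$dI_slow, p2$eps_mean * (p2$v_star + 0.3 - 0.5 * 0.02))

  expect_error(ml_derivatives(st, v_delayed = NULL, params = p),
               "history")
})

test_that("Izhikevich Euler step matches a scalar oracle and applies the reset", {
  p <- izh_params()
  # spike reset: crossing the apex sets v to c_reset and bumps u by d
  st <- izh_step(list(v = 29.5, u = 0), I_total = 50, dt = 0.1, p)
  expect_true(st$spiked)
  expect_equal(st$v, -50)
  orc <- oracle_izh_step(29.5, 0, 50, 0.1)
  expect_equal(st$u, orc$u)

  # rest state: the stable root of the quadratic with u = b v is a fixed point
  roots <- Re(polyroot(c(140, 5 - p$b, 0.04)))
  v_rest <- min(roots)                     # stable branch
  st0 <- izh_step(list(v = v_rest, u = p$b * v_rest), I_total = 0, dt = 0.1, p)
  expect_equal(st0$v, v_rest, tolerance = 1e-10)
  expect_equal(st0$u, p$b * v_rest, tolerance = 1e-10)

  set.seed(1)
  for (i in 1:100) {
    v <- runif(1, -80, 29); u <- runif(1, -15, 15); I <- runif(1, -5, 30)
    got <- izh_step(list(v = v, u = u), I, 0.1, p)
    want <- oracle_izh_step(v, u, I, 0.1)
    expect_identical(got$v, want$v)
    expect_identical(got$u, want$u)
  }
  expect_error(izh_step(list(v = 1e308, u = 0), 1e308, 1, p), "non-finite")
})

test_that("synaptic gate kinetics have the derived steady state and stay bounded", {
  g <- gate_params()
  # fully driven gate equilibrium alpha/(alpha+beta) = 2/3
  expect_equal(gate_derivative(2 / 3, 10, g), 0, tolerance = 1e-12)
  expect_equal(gate_derivative(0, 10, g), g$alpha_s, tolerance = 1e-10)
  expect_equal(gate_derivative(0, g$theta_s, g), g$alpha_s / 2)
  expect_equal(gate_derivative(0, -100, g), 0, tolerance = 1e-15)

  # boundedness under random bounded voltage traces (Euler integration)
  set.seed(11)
  dt <- 0.05
  for (k in 1:20) {
    v <- cumsum(rnorm(4000, 0, 0.05))
    v <- 0.4 * sin(v) + rnorm(4000, 0, 0.2)   # bounded, erratic
    s <- runif(1)
    for (i in seq_along(v)) s <- s + dt * gate_derivative(s, v[i], g)
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("spike trains are segmented into bursts by the gap rule", {
  # three 4-spike bursts, 10 ms ISIs, 300 ms apart
  spk <- c(outer(c(0, .01, .02, .03), c(1, 1.3, 1.6), "+"))
  spk <- sort(spk)
  expect_equal(burst_spike_counts(spk, drop_edges = FALSE), rep(4L, 3))
  on <- burst_onsets_from_spikes(spk)
  expect_equal(as.numeric(on), c(1, 1.3, 1.6))
  expect_length(burst_spike_counts(numeric(0)), 0)
})
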