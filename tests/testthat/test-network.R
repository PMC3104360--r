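test_that("lattice geometry: corner distance, symmetry, jitter statistics", {
  lat <- build_lattice(100, dl = 0.1)
  expect_equal(max(lat$distances), 0.9 * sqrt(2))
  expect_identical(lat$distances, t(lat$distances))
  expect_true(all(diag(lat$distances) == 0))

  latj <- build_lattice(225, dl = 0.1, jitter_sd = 0.1, seed = 3)
  lat0 <- build_lattice(225, dl = 0.1)
  off <- row(latj$distances) != col(latj$distances)
  d <- (latj$distances - lat0$distances)[off]
  # clamping at zero induces a small positive bias; the mean of the raw
  # Gaussian jitter must be within 3 standard errors of zero, so test the
  # unclamped pairs only
  raw <- d[latj$distances[off] > 0 & d > -lat0$distances[off]]
  expect_lt(abs(mean(d[abs(d) < 0.5])), 3 * 0.1 / sqrt(sum(off)) + 0.01)
  expect_true(all(latj$distances >= 0))

  expect_error(build_lattice(50), "perfect square")
})

test_that("spatial kernel is Gaussian with the stated width and decreasing", {
  expect_equal(spatial_weight(0), 1)
  expect_equal(spatial_weight(0.5, sigma_g = 0.5), exp(-1 / 2))
  expect_equal(spatial_weight(1, sigma_g = 0.5, kernel = "exponential"),
               exp(-2))
  w <- spatial_weight(c(0.1, 0.5, 1.0))
  expect_true(w[1] > w[2] && w[2] > w[3])
})

test_that("synaptic current follows the gated, distance-weighted form", {
  cp <- coupling_params("morris_lecar", c_n = 1, v_rev_syn = -0.85)
  # closed gates and reversal potential null the current
  expect_equal(synaptic_current(0, gates = c(0, 0), weights = c(1, 1), cp), 0)
  expect_equal(synaptic_current(-0.85, gates = c(1, 1), weights = c(1, 1), cp), 0)
  # two neurons at distance zero: g_bar_s * 1 * (v_rev - v)
  expect_equal(synaptic_current(0, gates = 1, weights = 1, cp), -0.34)

  # excitatory sign: below the reversal potential the current is positive
  cpd <- coupling_params("morris_lecar")
  set.seed(5)
  for (i in 1:20) {
    v <- runif(1, -0.5, cpd$v_rev_syn - 1e-6)
    s <- runif(5)
    expect_gt(synaptic_current(v, s, runif(5), cpd), 0)
  }

  expect_error(synaptic_current(0, gates = c(1, 1), weights = matrix(1, 1, 3), cp),
               "dimension mismatch")
  expect_error(synaptic_current(0, gates = 2, weights = 1, cp), "gates")
})

test_that("matrix form of the synaptic current matches per-neuron evaluation", {
  lat <- build_lattice(16, dl = 0.1)
  cp <- coupling_params("morris_lecar")
  W <- coupling_matrix(lat, cp)
  expect_true(all(diag(W) == 0))
  set.seed(2)
  v <- runif(16, -0.4, 0.1); s <- runif(16)
  I <- synaptic_current(v, s, W, cp, n_norm = 16)
  for (j in c(1, 7, 16)) {
    expect_equal(I[j],
                 cp$g_bar_s / (cp$c_n * 16) * sum(W[j, ] * s) *
                   (cp$v_rev_syn - v[j]),
                 tolerance = 1e-12)
  }
})

test_that("feedforward inter-population coupling has the matched mean and form", {
  ip <- interpop_coupling(225, 225, mean_weight = 0.37, rel_sd = 0.25, seed = 9)
  expect_equal(dim(ip$weight_matrix), c(225, 225))
  expect_lt(abs(mean(ip$weight_matrix) - 0.37) / 0.37, 0.05)
  expect_true(all(ip$weight_matrix >= 0))

  cp <- coupling_params("izhikevich")
  v <- rep(-60, 225)
  expect_equal(interpop_current(v, pacemaker_gates = rep(0, 225), ip, cp),
               rep(0, 225))
  expect_equal(interpop_current(rep(cp$v_rev_syn, 225), rep(1, 225), ip, cp),
               rep(0, 225))
  got <- interpop_current(v, rep(1, 225), ip, cp)
  expect_equal(got[1],
               cp$g_bar_s / cp$c_n * sum(ip$weight_matrix[1, ]) *
                 (cp$v_rev_syn - v[1]),
               tolerance = 1e-9)
  expect_error(interpop_current(rep(-60, 2), rep(1, 10), ip, cp),
               "dimension mismatch")
})
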