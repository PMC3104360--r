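test_that("biphasic pulse is charge balanced exactly for any parameters", {
  set.seed(3)
  for (i in 1:50) {
    f <- runif(1, 50, 200)
    tp <- runif(1, 0.05, 1)
    tn <- runif(1, 1, min(4, 1000 / f - tp - 0.1))
    a <- runif(1, 0.1, 10)
    tr <- pulse_train(f, tp, tn, a)
    expect_equal(tr$amp_pos * tr$t_pos_ms + tr$amp_neg * tr$t_neg_ms, 0)
  }
  tr <- pulse_train()
  expect_equal(tr$amp_neg / tr$amp_pos, -0.2 / 3)
  expect_equal(tr$period_ms, 1000 / 130)
  expect_equal((tr$t_pos_ms + tr$t_neg_ms) / tr$period_ms, 3.2 / (1000 / 130))
  expect_error(pulse_train(130, 4, 4), "exceed the period")
})

test_that("waveform is periodic with zero integral over each period", {
  tr <- pulse_train()
  t <- seq(0, tr$period_ms, by = 1e-4)[-1]
  # Riemann integral over one period
  expect_lt(abs(sum(pulse_waveform(t, tr)) * 1e-4), 1e-3 * tr$amp_pos)
  # exact periodicity and segment values
  tt <- runif(200, 0, 100)
  expect_equal(pulse_waveform(tt, tr), pulse_waveform(tt + 3 * tr$period_ms, tr))
  expect_equal(pulse_waveform(0.1, tr), tr$amp_pos)
  expect_equal(pulse_waveform(1.5, tr), tr$amp_neg)
  expect_equal(pulse_waveform(5, tr), 0)
})

test_that("electrode layouts sit at the lattice and quadrant centroids", {
  lat <- build_lattice(100, dl = 0.1)
  ec <- electrode_layout("center", lat)
  expect_equal(unname(ec$positions[1, ]), c(0.45, 0.45))
  expect_equal(ec$c_n_stim, 1)

  eq <- electrode_layout("quad", lat)
  expect_equal(nrow(eq$positions), 4)
  expect_equal(nrow(unique(eq$positions)), 4)
  # symmetric under 90-degree rotation about the centroid
  ctr <- c(0.45, 0.45)
  rot <- cbind(ctr[1] - (eq$positions[, 2] - ctr[2]),
               ctr[2] + (eq$positions[, 1] - ctr[1]))
  expect_equal(rot[order(rot[, 1], rot[, 2]), ],
               unname(eq$positions[order(eq$positions[, 1], eq$positions[, 2]), ]),
               tolerance = 1e-12)

  # 15x15: each electrode equidistant from its quadrant's corners
  lat15 <- build_lattice(225, dl = 0.1)
  e15 <- electrode_layout("quad", lat15)
  el <- e15$positions[1, ]   # (0.35, 0.35), quadrant [0, 0.7]^2
  corners <- rbind(c(0, 0), c(0.7, 0), c(0, 0.7), c(0.7, 0.7))
  dd <- sqrt(rowSums(sweep(corners, 2, el)^2))
  expect_equal(max(dd) - min(dd), 0, tolerance = 1e-12)

  expect_error(electrode_layout("ring", lat), "arg")
})

test_that("stimulation current decays with distance, obeys the window, and is
           layout-invariant in total", {
  lat <- build_lattice(100, dl = 0.1)
  tr <- pulse_train()
  win <- stim_window(4.5, 9)
  ec <- electrode_layout("center", lat, c_s = 0.1, decay_len = 0.15)

  t1 <- 4.5 + 1e-4   # 0.1 ms into a positive pulse phase
  expect_equal(stim_current(c(0, 0), t = 1, ec, tr, win), 0)   # before onset
  expect_equal(stim_current(c(0.45, 0.45), t = t1, ec, tr, win),
               0.1 * tr$amp_pos)                               # at electrode
  # nonincreasing in distance at a time with W(t) > 0
  d <- seq(0, 0.6, by = 0.1)
  I <- vapply(d, function(x) stim_current(c(0.45 + x, 0.45), t1, ec, tr, win),
              numeric(1))
  expect_true(all(diff(I) <= 0))

  # summed delivered stimulation is independent of the electrode count
  eq <- electrode_layout("quad", lat, c_s = 0.1, decay_len = 0.15)
  tot <- function(arr) {
    sum(vapply(seq_len(100), function(j)
      abs(stim_current(lat$positions[j, ], t1, arr, tr, win)), numeric(1)))
  }
  expect_lt(abs(tot(eq) / tot(ec) - 1), 0.01)
})
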