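# Independent oracles, coded separately from the package internals.

# order parameter by explicit complex summation (loop, no vectorization)
oracle_order_parameter <- function(phases) {
  re <- 0; im <- 0; n <- 0
  for (p in phases) {
    if (is.finite(p)) {
      re <- re + cos(p); im <- im + sin(p); n <- n + 1
    }
  }
  c(R = sqrt(re^2 + im^2) / n, Theta = atan2(im / n, re / n))
}

# one scalar forward-Euler step of the quadratic spiking model
oracle_izh_step <- function(v, u, I, dt, a = 0.02, b = 0.2, c = -50,
                            d = 0.7, cut = 30) {
  vn <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  un <- u + dt * (a * (b * v - u))
  spiked <- vn >= cut
  if (spiked) { vn <- c; un <- un + d }
  list(v = vn, u = un, spiked = spiked)
}

# closed-form Morris-Lecar voltage derivative (independent arithmetic)
oracle_ml_dv <- function(v, w, I_slow, I_in, p) {
  m <- 0.5 * (1 + tanh((v - p$v1) / p$v2))
  (-p$g_ca * m * (v - p$v_ca) - p$g_k * w * (v - p$v_k) -
      p$g_l * (v - p$v_l) + I_slow + I_in) / p$C
}

# scalar RK4 integration of one isolated Morris-Lecar neuron with the
# constant-history delayed slow current, mirroring a fixed-step grid
oracle_ml_isolated <- function(v0, w0, i0, s0, eps, p, g, dt, n_steps) {
  tau_steps <- p$tau_j / dt
  stopifnot(tau_steps == round(tau_steps))
  hist <- rep(v0, n_steps + 1)
  rhs <- function(v, w, isl, s, vdel) {
    m <- 0.5 * (1 + tanh((v - p$v1) / p$v2))
    winf <- 0.5 * (1 + tanh((v - p$v3) / p$v4))
    tw <- 1 / cosh((v - p$v3) / (2 * p$v4))
    h <- 1 / (1 + exp(-(v - g$theta_s) / g$sigma_s))
    c((-p$g_ca * m * (v - p$v_ca) - p$g_k * w * (v - p$v_k) -
         p$g_l * (v - p$v_l) + isl) / p$C,
      p$phi * (winf - w) / tw,
      eps * (p$v_star - vdel - p$alpha * isl),
      g$alpha_s * h * (1 - s) - g$beta_s * s)
  }
  y <- c(v0, w0, i0, s0)
  out <- matrix(NA_real_, n_steps, 4)
  vdel_at <- function(i, off) {
    # linear interpolation at fractional step index i - tau_steps + off,
    # constant initial history before step 0
    x <- i - tau_steps + off
    if (x > i) x <- i
    f <- floor(x)
    h0 <- if (f < 0) v0 else hist[f + 1]
    h1 <- if (f + 1 < 0) v0 else hist[f + 2]
    (1 - (x - f)) * h0 + (x - f) * h1
  }
  for (i in seq_len(n_steps) - 1L) {
    hist[i + 1] <- y[1]
    k1 <- rhs(y[1], y[2], y[3], y[4], vdel_at(i, 0))
    y2 <- y + dt / 2 * k1
    k2 <- rhs(y2[1], y2[2], y2[3], y2[4], vdel_at(i, 0.5))
    y3 <- y + dt / 2 * k2
    k3 <- rhs(y3[1], y3[2], y3[3], y3[4], vdel_at(i, 0.5))
    y4 <- y + dt * k3
    k4 <- rhs(y4[1], y4[2], y4[3], y4[4], vdel_at(i, 1))
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- y
  }
  out
}

# small deterministic Izhikevich scenario used by several engine tests
small_izh_scenario <- function(n = 25, duration = 2, seed = 7,
                               D_noise = 1e-5, g_bar_s = 0.2) {
  scenario("izhikevich", n_neurons = n, duration = duration,
           jitter_sd = 0.1,
           coupling = coupling_params("izhikevich", g_bar_s = g_bar_s),
           noise = noise_params(D_noise = D_noise),
           seeds = list(lattice = seed, init = seed + 1, noise = seed + 2))
}
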