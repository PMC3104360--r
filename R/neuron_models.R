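#' Morris-Lecar gating curves
#'
#' Steady-state activation of the calcium and potassium channels and the
#' potassium gating time constant, in the canonical hyperbolic forms
#' \eqn{m_\infty(v) = \frac12(1 + \tanh((v - v_1)/v_2))},
#' \eqn{w_\infty(v) = \frac12(1 + \tanh((v - v_3)/v_4))},
#' \eqn{\tau_w(v) = 1/\cosh((v - v_3)/(2 v_4))}.
#'
#' @param v membrane potential (vectorized).
#' @param params an [ml_params()] object.
#' @return A list with components \code{m_inf}, \code{w_inf} (both in
#'   [0, 1], nondecreasing in \code{v}) and \code{tau_w} (> 0).
#' @export
#' @examples
#' ml_gating_curves(0.1, ml_params())
ml_gating_curves <- function(v, params = ml_params()) {
  stopifnot(inherits(params, "ml_params"))
  list(m_inf = 0.5 * (1 + tanh((v - params$v1) / params$v2)),
       w_inf = 0.5 * (1 + tanh((v - params$v3) / params$v4)),
       tau_w = 1 / cosh((v - params$v3) / (2 * params$v4)))
}

#' Morris-Lecar state derivatives
#'
#' Right-hand side of the four Morris-Lecar equations for one neuron:
#' membrane potential, potassium gating variable, slow feedback current,
#' and synaptic gate.  The slow current integrates the delayed membrane
#' potential, \eqn{dI^{slow}/dt = \epsilon_j (v^* - v(t-\tau_j) - \alpha
#' I^{slow})}, modelling the inhibitory GPe loop.
#'
#' @param state list or named vector with \code{v}, \code{w},
#'   \code{I_slow}, \code{s}.
#' @param v_delayed membrane potential of the same neuron \code{tau_j}
#'   time units in the past.
#' @param I_syn,I_noise,I_stim synaptic, background-noise and stimulation
#'   currents.
#' @param X1 stimulation window indicator (0 or 1).
#' @param params an [ml_params()] object; \code{eps_j} overrides the
#'   neuron's slow-current rate (defaults to \code{params$eps_mean}).
#' @param gate a [gate_params()] object.
#' @param eps_j per-neuron slow-current rate.
#' @return List with \code{dv}, \code{dw}, \code{dI_slow}, \code{ds}.
#' @seealso [gate_derivative()], [ml_gating_curves()]
#' @export
ml_derivatives <- function(state, v_delayed, I_syn = 0, I_noise = 0,
                           I_stim = 0, X1 = 0, params = ml_params(),
                           gate = gate_params(), eps_j = params$eps_mean) {
  stopifnot(inherits(params, "ml_params"))
  if (missing(v_delayed) || is.null(v_delayed) || !is.finite(v_delayed))
    stop("'v_delayed' is required: the delayed-feedback history must cover tau_j")
  st <- as.list(state)
  gc <- ml_gating_curves(st$v, params)
  dv <- (-params$g_ca * gc$m_inf * (st$v - params$v_ca) -
           params$g_k * st$w * (st$v - params$v_k) -
           params$g_l * (st$v - params$v_l) +
           st$I_slow + I_syn + I_noise + params$s1 * X1 * I_stim) / params$C
  dw <- params$phi * (gc$w_inf - st$w) / gc$tau_w
  dI <- eps_j * (params$v_star - v_delayed - params$alpha * st$I_slow)
  ds <- gate_derivative(st$s, st$v, gate)
  list(dv = dv, dw = dw, dI_slow = dI, ds = ds)
}

#' One forward-Euler step of the Izhikevich neuron
#'
#' Advances \eqn{dv/dt = 0.04 v^2 + 5 v + 140 - u + I} and
#' \eqn{du/dt = a (b v - u)} by \code{dt}, then applies the after-spike
#' reset: if the updated \code{v} reaches \code{spike_cut}, \code{v} is set
#' to \code{c_reset} and \code{u} incremented by \code{d}.
#'
#' @param state list or named vector with \code{v}, \code{u} (and
#'   optionally \code{s}, passed through unchanged).
#' @param I_total total input current (tonic drive + synaptic + noise +
#'   stimulation).
#' @param dt step size in ms (> 0).
#' @param params an [izh_params()] object.
#' @return List with updated \code{v}, \code{u}, \code{s} (if supplied)
#'   and logical \code{spiked}.
#' @export
#' @examples
#' izh_step(list(v = 29.9, u = 0), I_total = 10, dt = 0.1, izh_params())
izh_step <- function(state, I_total, dt, params = izh_params()) {
  stopifnot(inherits(params, "izh_params"), dt > 0)
  st <- as.list(state)
  v <- st$v + dt * (0.04 * st$v^2 + 5 * st$v + 140 - st$u + I_total)
  u <- st$u + dt * params$a * (params$b * st$v - st$u)
  if (!is.finite(v) || !is.finite(u))
    stop("non-finite Izhikevich state after step (dt too large?)")
  spiked <- v >= params$spike_cut
  if (spiked) {
    v <- params$c_reset
    u <- u + params$d
  }
  out <- list(v = v, u = u, spiked = spiked)
  if (!is.null(st$s)) out$s <- st$s
  out
}

#' Synaptic gate derivative
#'
#' First-order Terman-style kinetics of the synaptic gating variable,
#' \eqn{ds/dt = \alpha_s H_\infty(v)(1-s) - \beta_s s}, which keeps
#' \eqn{s} in [0, 1] for any bounded voltage trajectory.
#'
#' @param s gate value in [0, 1] (vectorized).
#' @param v presynaptic membrane potential.
#' @param gate a [gate_params()] object.
#' @return ds/dt.
#' @export
gate_derivative <- function(s, v, gate = gate_params()) {
  stopifnot(inherits(gate, "gate_params"))
  if (any(s < -1e-12 | s > 1 + 1e-12))
    stop("'s' must lie in [0, 1]")
  h_inf <- 1 / (1 + exp(-(v - gate$theta_s) / gate$sigma_s))
  gate$alpha_s * h_inf * (1 - s) - gate$beta_s * s
}

#' Group spike times into bursts and count spikes per burst
#'
#' Splits an ordered spike train into bursts wherever the inter-spike
#' interval exceeds \code{gap_factor} times the median interval (the
#' median is dominated by the fast intra-burst intervals of a bursting
#' train), and returns the spike count of each burst.
#'
#' @param spike_times strictly increasing spike times.
#' @param gap_factor multiple of the median inter-spike interval that
#'   separates bursts.
#' @param drop_edges drop the first and last burst, which may be truncated
#'   by the observation window.
#' @return Integer vector of spikes per burst (possibly empty).
#' @export
burst_spike_counts <- function(spike_times, gap_factor = 3,
                               drop_edges = TRUE) {
  n <- length(spike_times)
  if (n < 2) return(integer(0))
  isi <- diff(spike_times)
  gaps <- which(isi > gap_factor * median(isi))
  counts <- diff(c(0L, gaps, n))
  if (drop_edges && length(counts) > 2)
    counts <- counts[-c(1L, length(counts))]
  as.integer(counts)
}

#' Detect spike times from a sampled voltage trace
#'
#' Upward threshold crossings of a regularly sampled membrane-potential
#' series, with crossing times refined by linear interpolation.
#'
#' @param v voltage samples.
#' @param dt sample interval.
#' @param threshold spike detection threshold (default 0, suitable for
#'   both the dimensionless Morris-Lecar spikes peaking near 0.14 and the
#'   Izhikevich spikes peaking at +30 mV).
#' @return Spike times (same unit as \code{dt}), possibly empty.
#' @export
detect_spikes <- function(v, dt, threshold = 0) {
  stopifnot(length(v) >= 2, dt > 0)
  below <- v[-length(v)] < threshold
  above <- v[-1] >= threshold
  i <- which(below & above)
  if (length(i) == 0) return(numeric(0))
  frac <- (threshold - v[i]) / (v[i + 1] - v[i])
  (i - 1 + frac) * dt
}
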