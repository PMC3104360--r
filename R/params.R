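#' Morris-Lecar neuron parameters
#'
#' Parameter set for the dimensionless Morris-Lecar subthalamic-nucleus (STN)
#' neuron with a delayed slow feedback current.  The slow current models the
#' inhibitory loop through the external globus pallidus (GPe): the membrane
#' potential, delayed by \code{tau_j} time units, is fed back into a slowly
#' integrating current that sweeps the fast subsystem back and forth across
#' its spiking threshold, producing periodic bursts of 6-10 spikes.
#' Defaults reproduce the reference lattice configuration.
#'
#' The model is dimensionless; \code{time_unit_ms} fixes the wall-clock
#' interpretation of one time unit.  At the default 1 ms/unit the isolated
#' neuron bursts at about 5.5 Hz, inside the 3-10 Hz tremor band.
#'
#' @param g_ca,g_k,g_l calcium, potassium and leak conductances (> 0).
#' @param v_ca,v_k,v_l corresponding reversal potentials.
#' @param v1,v2,v3,v4 gating steady-state / time-constant tuning constants.
#' @param C membrane capacitance (> 0).
#' @param phi potassium gating rate scale.
#' @param v_star set point of the slow feedback current.
#' @param alpha modulation of the GPe inhibitory response (0 disables the
#'   relaxation term of the slow current).
#' @param tau_j feedback delay in time units (>= 0).
#' @param eps_mean,eps_sd mean and standard deviation of the per-neuron
#'   Gaussian slow-current rate \eqn{\epsilon_j}; the spread gives each
#'   neuron a slightly different natural burst frequency.
#' @param s1 weight of the local (somatic) stimulation current.
#' @param time_unit_ms wall-clock milliseconds per dimensionless time unit.
#' @return An object of class \code{ml_params}.
#' @seealso [izh_params()], [gate_params()], [ml_derivatives()]
#' @export
#' @examples
#' p <- ml_params()
#' ml_gating_curves(p$v1, p)$m_inf  # 0.5 at half-activation
ml_params <- function(g_ca = 1, g_k = 2, g_l = 0.5,
                      v_ca = 1, v_k = -0.7, v_l = -0.5,
                      v1 = -0.01, v2 = 0.15, v3 = 0.1, v4 = 0.145,
                      C = 1, phi = 1.15, v_star = -0.22, alpha = 0,
                      tau_j = 10, eps_mean = 2e-3, eps_sd = 2e-5,
                      s1 = 1, time_unit_ms = 1) {
  stopifnot(g_ca > 0, g_k > 0, g_l > 0, C > 0, tau_j >= 0,
            eps_mean > 0, eps_sd >= 0, v2 > 0, v4 > 0, phi > 0,
            time_unit_ms > 0)
  structure(list(g_ca = g_ca, g_k = g_k, g_l = g_l,
                 v_ca = v_ca, v_k = v_k, v_l = v_l,
                 v1 = v1, v2 = v2, v3 = v3, v4 = v4,
                 C = C, phi = phi, v_star = v_star, alpha = alpha,
                 tau_j = tau_j, eps_mean = eps_mean, eps_sd = eps_sd,
                 s1 = s1, time_unit_ms = time_unit_ms),
            class = "ml_params")
}

#' Izhikevich chattering-neuron parameters
#'
#' Parameter set for the reduced-order Izhikevich neuron in its chattering
#' (burst-firing) regime, used as a computationally light stand-in for the
#' Morris-Lecar STN neuron.  Voltages are in mV and time in ms.
#'
#' With \code{a}, \code{b}, \code{c_reset} and \code{d} at their defaults
#' the neuron bursts only for a tonic drive in roughly [4.5, 6.5]; below
#' that window it is silent, above it it spikes tonically.  The default
#' \code{drive = 5} sits mid-window and yields 9 spikes per burst at about
#' 8.8 Hz, matching the 6-10 spikes per burst of the Morris-Lecar backend
#' at a comparable tremor-band rate (see the package vignette for the
#' calibration rationale).
#'
#' @param a recovery rate of the adaptation variable u (> 0).
#' @param b sensitivity of u to the membrane potential.
#' @param c_reset after-spike reset value of v (mV).
#' @param d after-spike increment of u.
#' @param drive constant tonic input current (population mean).
#' @param drive_sd s.d. of the per-neuron Gaussian tonic drive.  The
#'   default is 1 percent of the drive, the same relative heterogeneity
#'   as the Morris-Lecar slow-current rate \eqn{\epsilon_j}; it gives
#'   each neuron a slightly different natural burst frequency, so an
#'   uncoupled (or weakly coupled) population disperses instead of
#'   freezing at its initial phases.
#' @param spike_cut spike apex threshold (mV); crossing it triggers the
#'   reset and is recorded as a spike.
#' @param stim_weight weight of the stimulation current in the voltage
#'   equation (the network stimulation protocol uses 50).
#' @return An object of class \code{izh_params}.
#' @seealso [ml_params()], [izh_step()]
#' @export
izh_params <- function(a = 0.02, b = 0.2, c_reset = -50, d = 0.7,
                       drive = 5, drive_sd = 0.01 * drive,
                       spike_cut = 30, stim_weight = 50) {
  stopifnot(a > 0, spike_cut > c_reset, drive_sd >= 0)
  structure(list(a = a, b = b, c_reset = c_reset, d = d,
                 drive = drive, drive_sd = drive_sd,
                 spike_cut = spike_cut, stim_weight = stim_weight),
            class = "izh_params")
}

#' Synaptic gate kinetics parameters
#'
#' First-order kinetics of the synaptic gating variable \eqn{s \in [0,1]}
#' shared by both neuron backends:
#' \deqn{ds/dt = \alpha_s H_\infty(v) (1 - s) - \beta_s s}
#' with \eqn{H_\infty(v) = 1/(1 + e^{-(v - \theta_s)/\sigma_s})}.  The gate
#' opens while the presynaptic membrane potential is above
#' \eqn{\theta_s} (i.e. during spikes) and closes with rate \eqn{\beta_s}.
#'
#' @param alpha_s gate opening rate (> 0).
#' @param beta_s gate closing rate (> 0).
#' @param theta_s half-activation potential.
#' @param sigma_s activation slope (> 0).
#' @return An object of class \code{gate_params}.
#' @export
#' @examples
#' # steady state with the gate fully driven: alpha_s/(alpha_s + beta_s)
#' g <- gate_params()
#' g$alpha_s / (g$alpha_s + g$beta_s)
gate_params <- function(alpha_s = 0.1, beta_s = 0.05,
                        theta_s = 0.2, sigma_s = 0.02) {
  stopifnot(alpha_s > 0, beta_s > 0, sigma_s > 0)
  structure(list(alpha_s = alpha_s, beta_s = beta_s,
                 theta_s = theta_s, sigma_s = sigma_s),
            class = "gate_params")
}

#' Synaptic coupling parameters
#'
#' Strength, reversal potential and spatial kernel of the excitatory
#' distance-weighted coupling within a lattice population.  The per-neuron
#' synaptic current is
#' \deqn{I^{syn}_j = \frac{\bar g_s}{c_n N} \sum_{k \ne j}
#'   w(d_{jk})\, s_k\, (v_s - v_j)}
#' with \eqn{w(d) = e^{-d^2 / 2\sigma_g^2}} (Gaussian kernel; an
#' exponential-decay alternative is available).  \code{c_n} is the fixed
#' normalization constant of the reference configurations; \code{c_n =
#' "auto"} instead uses the mean over neurons of \eqn{\sum_k w(d_{jk})}
#' (a package-defined convenience, not part of the reference setup).
#'
#' Two conventions deserve note.  First, the network normalization factor
#' \eqn{n_{norm}} used by the simulator is the mean kernel-weighted
#' in-degree \eqn{\overline{\sum_k w(d_{jk})}} (the effective number of
#' inputs per neuron), not the raw population size, so the summed synaptic
#' drive is independent of lattice size and kernel width.  Second, the
#' Morris-Lecar synaptic reversal defaults to \eqn{+0.85}: the excitatory
#' glutamatergic coupling requires a reversal above the operating voltage
#' range \eqn{[-0.3, 0.14]}, and a reversal of \eqn{-0.85} (below the
#' range, hence hyperpolarizing) demonstrably desynchronizes the lattice
#' instead; the sign correction mirrors the one needed for the Izhikevich
#' after-spike reset (see the vignette).
#'
#' @param backend which backend's reference defaults to use.
#' @param g_bar_s maximal synaptic conductance (default 0.4 Morris-Lecar,
#'   0.2 Izhikevich).
#' @param v_rev_syn synaptic reversal potential (default +0.85 / -0.8;
#'   see Details).
#' @param sigma_g spatial kernel width in lattice units.
#' @param c_n normalization constant (default 2.0584 / 2.1765), or
#'   \code{"auto"}.
#' @param kernel spatial kernel shape.
#' @return An object of class \code{coupling_params}.
#' @seealso [synaptic_current()], [build_lattice()]
#' @export
coupling_params <- function(backend = c("morris_lecar", "izhikevich"),
                            g_bar_s = NULL, v_rev_syn = NULL,
                            sigma_g = 0.5, c_n = NULL,
                            kernel = c("gaussian", "exponential")) {
  backend <- match.arg(backend)
  kernel <- match.arg(kernel)
  if (is.null(g_bar_s))
    g_bar_s <- if (backend == "morris_lecar") 0.4 else 0.2
  if (is.null(v_rev_syn))
    v_rev_syn <- if (backend == "morris_lecar") 0.85 else -0.8
  if (is.null(c_n))
    c_n <- if (backend == "morris_lecar") 2.0584 else 2.1765
  stopifnot(g_bar_s >= 0, sigma_g > 0,
            identical(c_n, "auto") || (is.numeric(c_n) && c_n > 0))
  structure(list(backend = backend, g_bar_s = g_bar_s,
                 v_rev_syn = v_rev_syn, sigma_g = sigma_g, c_n = c_n,
                 kernel = kernel),
            class = "coupling_params")
}

#' Background-noise parameters
#'
#' Spatially incoherent exponentially correlated (Ornstein-Uhlenbeck)
#' current noise, one independent stream per neuron, modelling background
#' synaptic bombardment.  The process has autocorrelation
#' \eqn{e^{-\Delta/\tau_{noise}}} and stationary variance
#' \eqn{D_{noise}^2\,\tau_{noise}/2}.
#'
#' @param D_noise noise amplitude (>= 0).
#' @param tau_noise correlation decay time in integrator time units (> 0).
#' @return An object of class \code{noise_params}.
#' @seealso [ou_noise_trace()]
#' @export
noise_params <- function(D_noise = 1e-5, tau_noise = 5) {
  stopifnot(D_noise >= 0, tau_noise > 0)
  structure(list(D_noise = D_noise, tau_noise = tau_noise),
            class = "noise_params")
}
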