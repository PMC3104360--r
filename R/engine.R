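#' Stimulation protocol
#'
#' Bundles the electrode layout mode, pulse train, window and spatial
#' parameters of a DBS protocol.
#'
#' @param mode electrode layout: one central electrode or four electrodes
#'   at the quadrant centroids.
#' @param train a [pulse_train()] object.
#' @param window a [stim_window()] object.
#' @param c_s stimulation strength.
#' @param decay_len spatial decay constant of the activation profile in
#'   lattice units (default: the synaptic kernel width).
#' @return An object of class \code{stim_protocol}.
#' @export
stim_protocol <- function(mode = c("center", "quad"),
                          train = pulse_train(),
                          window = stim_window(4.5, 9),
                          c_s = 0.1, decay_len = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(train, "pulse_train"), inherits(window, "stim_window"),
            c_s >= 0, decay_len > 0)
  structure(list(mode = mode, train = train, window = window,
                 c_s = c_s, decay_len = decay_len),
            class = "stim_protocol")
}

#' Simulation scenario configuration
#'
#' Aggregates every ingredient of a network run: neuron backend, lattice,
#' coupling, noise, optional stimulation, integration and recording
#' settings, and explicit seeds for each source of randomness.  Backend
#' defaults reproduce the reference configurations: a regular 10x10
#' Morris-Lecar lattice simulated for 9 s (step 0.025 time units), and a
#' distance-jittered 15x15 Izhikevich lattice simulated for 7 s (Euler
#' step 0.1 ms).
#'
#' @param backend neuron model.
#' @param n_neurons population size (perfect square).
#' @param duration simulated time in seconds.
#' @param dt integration step in the backend's time unit (dimensionless
#'   units for Morris-Lecar, ms for Izhikevich).
#' @param dl lattice spacing.
#' @param jitter_sd Gaussian distance-jitter s.d. (default 0 for
#'   Morris-Lecar, 0.1 for Izhikevich).
#' @param neuron an [ml_params()] or [izh_params()] object.
#' @param gate a [gate_params()] object.
#' @param coupling a [coupling_params()] object.
#' @param noise a [noise_params()] object.
#' @param stimulation a [stim_protocol()] object, or \code{NULL} for no
#'   stimulation.
#' @param record_dt recording interval in seconds.
#' @param seeds named list of integer seeds: \code{lattice} (distance
#'   jitter), \code{init} (initial conditions and per-neuron rates),
#'   \code{noise} (background noise stream).
#' @return An object of class \code{scenario}.
#' @seealso [simulate_network()], [simulate_two_populations()]
#' @export
scenario <- function(backend = c("morris_lecar", "izhikevich"),
                     n_neurons = NULL, duration = NULL, dt = NULL,
                     dl = 0.1, jitter_sd = NULL,
                     neuron = NULL, gate = gate_params(),
                     coupling = NULL, noise = noise_params(),
                     stimulation = NULL, record_dt = 1e-3,
                     seeds = list(lattice = 1L, init = 2L, noise = 3L)) {
  backend <- match.arg(backend)
  if (backend == "morris_lecar") {
    if (is.null(n_neurons)) n_neurons <- 100
    if (is.null(duration)) duration <- 9
    if (is.null(dt)) dt <- 0.025
    if (is.null(jitter_sd)) jitter_sd <- 0
    if (is.null(neuron)) neuron <- ml_params()
    stopifnot(inherits(neuron, "ml_params"))
  } else {
    if (is.null(n_neurons)) n_neurons <- 225
    if (is.null(duration)) duration <- 7
    if (is.null(dt)) dt <- 0.1
    if (is.null(jitter_sd)) jitter_sd <- 0.1
    if (is.null(neuron)) neuron <- izh_params()
    stopifnot(inherits(neuron, "izh_params"))
  }
  if (is.null(coupling)) coupling <- coupling_params(backend)
  stopifnot(inherits(coupling, "coupling_params"),
            inherits(noise, "noise_params"), inherits(gate, "gate_params"),
            is.null(stimulation) || inherits(stimulation, "stim_protocol"),
            duration > 0, dt > 0, record_dt > 0,
            all(c("lattice", "init", "noise") %in% names(seeds)))
  if (!is.null(stimulation) && duration < stimulation$window$t_off)
    stop("'duration' must cover the stimulation window")
  structure(list(backend = backend, n_neurons = n_neurons,
                 duration = duration, dt = dt, dl = dl,
                 jitter_sd = jitter_sd, neuron = neuron, gate = gate,
                 coupling = coupling, noise = noise,
                 stimulation = stimulation, record_dt = record_dt,
                 seeds = lapply(seeds, as.integer)),
            class = "scenario")
}

# seconds -> engine time units
engine_time_unit_ms <- function(config) {
  if (config$backend == "morris_lecar") config$neuron$time_unit_ms else 1
}

# waveform + window in engine time units; zero-amplitude train if no stim
engine_stim <- function(config, lattice) {
  unit <- engine_time_unit_ms(config)
  if (is.null(config$stimulation)) {
    return(list(gain = numeric(lattice$n_neurons),
                wave = c(1000 / 130 / unit, 0.2 / unit, 3 / unit, 0, 0),
                on = -1, off = -1, layout = NULL))
  }
  p <- config$stimulation
  layout <- electrode_layout(p$mode, lattice, c_s = p$c_s,
                             decay_len = p$decay_len)
  weight <- if (config$backend == "morris_lecar") config$neuron$s1
            else config$neuron$stim_weight
  tr <- p$train
  list(gain = stim_gain_vector(lattice, layout) * weight,
       wave = c(tr$period_ms / unit, tr$t_pos_ms / unit, tr$t_neg_ms / unit,
                tr$amp_pos, tr$amp_neg),
       on = p$window$t_on * 1000 / unit, off = p$window$t_off * 1000 / unit,
       layout = layout)
}

# pre-scaled coupling matrix: kernel * g_bar_s / (c_n * n_norm), where
# n_norm is the mean kernel-weighted in-degree (effective inputs/neuron)
scaled_coupling <- function(lattice, coupling, g_bar_s = coupling$g_bar_s) {
  W <- coupling_matrix(lattice, coupling)
  denom <- resolve_c_n(coupling, W) * mean(rowSums(W))
  if (g_bar_s == 0 || denom == 0) return(W * 0)  # decoupled / single neuron
  W * (g_bar_s / denom)
}

draw_initial_state <- function(config) {
  n <- config$n_neurons
  if (config$backend == "morris_lecar") {
    v0 <- runif(n, -0.3, 0.14)
    list(v0 = v0, w0 = ml_gating_curves(v0, config$neuron)$w_inf,
         i0 = numeric(n), s0 = numeric(n),
         eps = rnorm(n, config$neuron$eps_mean, config$neuron$eps_sd))
  } else {
    # u0 sits on the quiescent branch of the burst cycle (rest exists for
    # u > drive - 15.6; bursts end near u = drive - 10), mid-quiescence,
    # so burst phases start moderately aligned (R already high, as for
    # random initial conditions of a relaxation oscillator ensemble) and
    # the per-neuron drive dispersion supplies long-run phase spread
    v0 <- runif(n, -65, -50)
    drv <- config$neuron$drive
    list(v0 = v0, u0 = runif(n, drv - 13, drv - 11), s0 = numeric(n),
         drive = rnorm(n, drv, config$neuron$drive_sd))
  }
}

#' Simulate a lattice network
#'
#' Integrates the full network defined by a [scenario()]:
#' Morris-Lecar with fixed-step RK4 and a per-neuron delayed-feedback
#' history buffer, or Izhikevich with forward Euler and post-step reset.
#' Initial membrane potentials are drawn uniformly over the model's
#' typical range, gates start closed, the slow current at zero
#' (Izhikevich: \code{u = b v}); the delay history before t = 0 is the
#' constant initial state.  All randomness is controlled by the
#' scenario's named seeds, so identical configurations reproduce
#' bit-identical traces.
#'
#' @param config a [scenario()] object.
#' @return An object of class \code{dbs_sim}: list with \code{times} (s),
#'   \code{V}, \code{S}, \code{I_ion} (neurons x samples; \code{I_ion} is
#'   the total non-stimulation current used for the LFP), \code{spikes}
#'   (Izhikevich only: per-neuron spike times in s), \code{lattice},
#'   \code{layout} and the \code{config} echo.
#' @seealso [compute_sync()], [simulated_lfp()], [simulate_two_populations()]
#' @export
#' @examples
#' \donttest{
#' cfg <- scenario("izhikevich", n_neurons = 25, duration = 2,
#'                 jitter_sd = 0)
#' sim <- simulate_network(cfg)
#' mean_R(compute_sync(sim))
#' }
simulate_network <- function(config) {
  stopifnot(inherits(config, "scenario"))
  lattice <- build_lattice(config$n_neurons, dl = config$dl,
                           jitter_sd = config$jitter_sd,
                           seed = config$seeds$lattice)
  G <- scaled_coupling(lattice, config$coupling)
  set.seed(config$seeds$init)
  init <- draw_initial_state(config)
  st <- engine_stim(config, lattice)
  unit <- engine_time_unit_ms(config)
  dur_units <- config$duration * 1000 / unit
  n_steps <- as.integer(round(dur_units / config$dt)) + 1L
  stride <- max(1L, as.integer(round(config$record_dt * 1000 / unit /
                                       config$dt)))
  set.seed(config$seeds$noise)
  if (config$backend == "morris_lecar") {
    raw <- cpp_simulate_ml(G, st$gain, init$v0, init$w0, init$i0, init$s0,
                           init$eps, unclass(config$neuron),
                           unclass(config$gate),
                           config$coupling$v_rev_syn, st$wave, st$on,
                           st$off, config$noise$D_noise,
                           config$noise$tau_noise, config$dt, n_steps,
                           stride, config$neuron$tau_j)
    spikes <- NULL
  } else {
    raw <- cpp_simulate_izh(G, st$gain, init$v0, init$u0, init$s0,
                            init$drive, unclass(config$neuron),
                            unclass(config$gate),
                            config$coupling$v_rev_syn, st$wave, st$on,
                            st$off, config$noise$D_noise,
                            config$noise$tau_noise, config$dt, n_steps,
                            stride)
    spikes <- split(raw$spike_t / 1000,
                    factor(raw$spike_id, levels = seq_len(config$n_neurons)))
  }
  structure(list(backend = config$backend,
                 times = raw$times * unit / 1000,
                 V = raw$V, S = raw$S, I_ion = raw$I_ion,
                 spikes = spikes, lattice = lattice, layout = st$layout,
                 config = config),
            class = "dbs_sim")
}

#' Simulate the pacemaker/driven two-population experiment
#'
#' Two Izhikevich lattice populations: a strongly coupled pacemaker
#' (population 1) drives a second population through random Gaussian
#' feedforward synapses whose mean strength equals the mean
#' intra-pacemaker coupling weight; the driven population keeps only a
#' weak intra-coupling (a fraction \code{driven_g_frac} of the pacemaker
#' conductance) that by itself does not induce synchronization.  Because
#' the neurons are identical deterministic oscillators, any appreciable
#' intra-coupling eventually locks an isolated population; the default
#' fraction is chosen so an isolated driven population stays at its
#' initial phase dispersion (mean R below 0.5) over the simulated
#' horizon.
#' Stimulation, if present, targets population 1 only.  Both populations
#' are integrated jointly on a shared time grid.
#'
#' @param config a [scenario()] for the pacemaker population (Izhikevich
#'   backend).
#' @param driven_g_frac intra-coupling conductance of the driven
#'   population as a fraction of the pacemaker's.
#' @param interpop_rel_sd relative s.d. of the Gaussian feedforward
#'   weights.
#' @param interpop_seed seed for the feedforward weight draw.
#' @return An object of class \code{dbs_sim_pair}: list with
#'   \code{pacemaker} and \code{driven} (\code{dbs_sim} objects) and the
#'   \code{coupling} ([interpop_coupling()]) used.  The driven
#'   population's lattice uses seed \code{seeds$lattice + 1} and its
#'   initial state \code{seeds$init + 1}.
#' @export
simulate_two_populations <- function(config, driven_g_frac = 0.01,
                                     interpop_rel_sd = 0.25,
                                     interpop_seed = config$seeds$init + 100L) {
  stopifnot(inherits(config, "scenario"),
            config$backend == "izhikevich",
            driven_g_frac >= 0, driven_g_frac <= 1)
  n <- config$n_neurons
  lat1 <- build_lattice(n, dl = config$dl, jitter_sd = config$jitter_sd,
                        seed = config$seeds$lattice)
  lat2 <- build_lattice(n, dl = config$dl, jitter_sd = config$jitter_sd,
                        seed = config$seeds$lattice + 1L)
  cp <- config$coupling
  W1 <- coupling_matrix(lat1, cp)
  W2 <- coupling_matrix(lat2, cp)
  c_n <- resolve_c_n(cp, W1)
  mean_w <- mean(W1[row(W1) != col(W1)])
  ipc <- interpop_coupling(n, n, mean_weight = mean_w,
                           rel_sd = interpop_rel_sd, seed = interpop_seed)
  sc <- cp$g_bar_s / (c_n * mean(rowSums(W1)))
  G <- matrix(0, 2 * n, 2 * n)
  G[seq_len(n), seq_len(n)] <- W1 * sc
  G[n + seq_len(n), n + seq_len(n)] <- W2 * sc * driven_g_frac
  G[n + seq_len(n), seq_len(n)] <- ipc$weight_matrix * sc
  set.seed(config$seeds$init)
  init1 <- draw_initial_state(config)
  set.seed(config$seeds$init + 1L)
  init2 <- draw_initial_state(config)
  st <- engine_stim(config, lat1)
  gain <- c(st$gain, numeric(n))   # stimulation reaches population 1 only
  dur_ms <- config$duration * 1000
  n_steps <- as.integer(round(dur_ms / config$dt)) + 1L
  stride <- max(1L, as.integer(round(config$record_dt * 1000 / config$dt)))
  set.seed(config$seeds$noise)
  raw <- cpp_simulate_izh(G, gain, c(init1$v0, init2$v0),
                          c(init1$u0, init2$u0), c(init1$s0, init2$s0),
                          c(init1$drive, init2$drive),
                          unclass(config$neuron), unclass(config$gate),
                          cp$v_rev_syn, st$wave, st$on, st$off,
                          config$noise$D_noise, config$noise$tau_noise,
                          config$dt, n_steps, stride)
  times <- raw$times / 1000
  spl <- function(rows, lat, keep_spk) {
    spk <- raw$spike_id %in% keep_spk
    structure(list(backend = "izhikevich", times = times,
                   V = raw$V[rows, , drop = FALSE],
                   S = raw$S[rows, , drop = FALSE],
                   I_ion = raw$I_ion[rows, , drop = FALSE],
                   spikes = split(raw$spike_t[spk] / 1000,
                                  factor(raw$spike_id[spk] -
                                           (keep_spk[1] - 1L),
                                         levels = seq_len(n))),
                   lattice = lat, layout = st$layout, config = config),
              class = "dbs_sim")
  }
  structure(list(pacemaker = spl(seq_len(n), lat1, seq_len(n)),
                 driven = spl(n + seq_len(n), lat2, n + seq_len(n)),
                 coupling = ipc, driven_g_frac = driven_g_frac),
            class = "dbs_sim_pair")
}

#' @export
print.dbs_sim <- function(x, ...) {
  cat(sprintf("Network simulation [%s]: %d neurons, %.3g s (%d samples)\n",
              x$backend, nrow(x$V), max(x$times), ncol(x$V)))
  if (!is.null(x$layout))
    cat(sprintf("  stimulation: %s layout (%d electrode%s), window [%g, %g] s\n",
                x$layout$mode, nrow(x$layout$positions),
                if (nrow(x$layout$positions) > 1) "s" else "",
                x$config$stimulation$window$t_on,
                x$config$stimulation$window$t_off))
  invisible(x)
}

#' @export
print.dbs_sim_pair <- function(x, ...) {
  cat("Two-population simulation (pacemaker -> driven)\n")
  print(x$pacemaker); print(x$driven)
  invisible(x)
}

#' @export
summary.dbs_sim <- function(object, ...) {
  sy <- compute_sync(object)
  out <- list(backend = object$backend, n_neurons = nrow(object$V),
              duration = max(object$times),
              mean_R = mean_R(sy),
              stimulated = !is.null(object$layout))
  if (out$stimulated) {
    w <- object$config$stimulation$window
    out$mean_R_pre <- mean_R(sy, c(0, w$t_on))
    out$mean_R_stim <- mean_R(sy, c(w$t_on, w$t_off))
  }
  structure(out, class = "summary.dbs_sim")
}

#' @export
print.summary.dbs_sim <- function(x, ...) {
  cat(sprintf("%s network, %d neurons, %.3g s\n", x$backend, x$n_neurons,
              x$duration))
  cat(sprintf("  mean R (whole run): %.3f\n", x$mean_R))
  if (x$stimulated)
    cat(sprintf("  mean R before stimulation: %.3f; during stimulation: %.3f\n",
                x$mean_R_pre, x$mean_R_stim))
  invisible(x)
}

#' @export
plot.dbs_sim <- function(x, neurons = NULL, ...) {
  if (is.null(neurons))
    neurons <- unique(round(seq(1, nrow(x$V), length.out = 4)))
  sy <- compute_sync(x)
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  matplot(x$times, t(x$V[neurons, , drop = FALSE]), type = "l", lty = 1,
          xlab = "", ylab = "v", ...)
  if (!is.null(x$layout))
    abline(v = c(x$config$stimulation$window$t_on,
                 x$config$stimulation$window$t_off), lty = 3)
  plot(sy$times, sy$R, type = "l", ylim = c(0, 1), xlab = "time [s]",
       ylab = "R(t)")
  invisible(x)
}
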