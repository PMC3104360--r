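#' Detect burst onsets in a membrane-potential trace
#'
#' A burst onset is an upward crossing of \code{threshold} preceded by a
#' quiescent interval of at least \code{min_gap} (measured to the previous
#' crossing).  With \code{min_gap = NULL} the gap is set automatically to
#' 3 times the median inter-crossing interval, which for a bursting trace
#' is dominated by the fast intra-burst inter-spike interval.
#'
#' @param v voltage samples on a regular grid.
#' @param dt sample interval in seconds.
#' @param threshold burst/spike detection threshold (dimensionless for
#'   Morris-Lecar, mV for Izhikevich).
#' @param min_gap minimal quiescence before an onset, in seconds, or
#'   \code{NULL} for the automatic rule.
#' @return An object of class \code{burst_train}: strictly increasing
#'   onset times in seconds (possibly empty if the trace never crosses
#'   the threshold).
#' @seealso [phase_from_onsets()], [burst_onsets_from_spikes()]
#' @export
detect_burst_onsets <- function(v, dt, threshold = -0.05, min_gap = NULL) {
  stopifnot(length(v) >= 2, dt > 0)
  cross <- detect_spikes(v, dt, threshold)
  burst_onsets_from_spikes(cross, min_gap = min_gap)
}

#' Burst onsets from a spike train
#'
#' Groups spike (or threshold-crossing) times into bursts by the
#' quiescence rule and returns the first spike time of each burst.
#'
#' @param spike_times increasing spike times in seconds.
#' @param min_gap minimal quiescence separating bursts (seconds), or
#'   \code{NULL} for 3 times the median inter-spike interval.
#' @return An object of class \code{burst_train}.
#' @export
burst_onsets_from_spikes <- function(spike_times, min_gap = NULL) {
  n <- length(spike_times)
  if (n == 0)
    return(structure(numeric(0), class = "burst_train"))
  if (n == 1)
    return(structure(spike_times, class = "burst_train"))
  isi <- diff(spike_times)
  if (is.null(min_gap)) min_gap <- 3 * median(isi)
  onsets <- spike_times[c(TRUE, isi >= min_gap)]
  structure(onsets, class = "burst_train", min_gap = min_gap)
}

#' @export
print.burst_train <- function(x, ...) {
  cat(sprintf("Burst train: %d onsets", length(x)))
  if (length(x))
    cat(sprintf(" over [%.3g, %.3g] s", x[1], x[length(x)]))
  cat("\n")
  invisible(x)
}

#' Burst phase by linear interpolation between onsets
#'
#' Reconstructs a per-neuron phase from its burst-onset times: the phase
#' advances by \eqn{2\pi} per burst and linearly in between,
#' \deqn{\phi(t) = 2\pi k + 2\pi \frac{t - t_k}{t_{k+1} - t_k},
#'   \qquad t \in [t_k, t_{k+1}).}
#' Times outside the covered interval (before the first or after the last
#' onset) are flagged invalid (\code{NA}) rather than extrapolated, and
#' are excluded from the order parameter downstream.
#'
#' @param train a [burst_onsets_from_spikes()] / [detect_burst_onsets()]
#'   object (or a sorted numeric vector of onset times).
#' @param t evaluation times (vectorized).
#' @return Phase in radians at each \code{t} (\code{NA} outside the
#'   covered range; requires at least two onsets).
#' @export
#' @examples
#' phase_from_onsets(c(0, 1, 3), 2)  # 2*pi + pi
phase_from_onsets <- function(train, t) {
  on <- as.numeric(train)
  out <- rep(NA_real_, length(t))
  L <- length(on)
  if (L < 2) return(out)
  k <- findInterval(t, on)
  ok <- k >= 1 & k <= L - 1
  kk <- k[ok]
  out[ok] <- 2 * pi * (kk - 1) +
    2 * pi * (t[ok] - on[kk]) / (on[kk + 1] - on[kk])
  out[t == on[L]] <- 2 * pi * (L - 1)
  out
}

#' Kuramoto order parameter of a phase vector
#'
#' \eqn{R e^{i\Theta} = \frac{1}{N}\sum_j e^{i\phi_j}}: \eqn{R = 1} is
#' perfect in-phase synchronization, \eqn{R = 0} complete
#' desynchronization.  \code{NA} phases (neurons without a covered burst
#' interval) are excluded; at least one valid phase is required.
#'
#' @param phases phase vector in radians (may contain \code{NA}).
#' @return List with \code{R} in [0, 1] and mean phase \code{Theta} in
#'   [-pi, pi).
#' @export
#' @examples
#' order_parameter(c(0, pi / 2))$R  # sqrt(2)/2
order_parameter <- function(phases) {
  ph <- phases[is.finite(phases)]
  if (length(ph) == 0)
    stop("no valid phases: all samples are outside covered burst intervals")
  z <- mean(exp(1i * ph))
  list(R = Mod(z), Theta = Arg(z))
}

#' Time-resolved synchronization of a set of burst trains
#'
#' Reconstructs each neuron's burst phase on a uniform time grid
#' (default 1 ms) and computes the time-resolved order parameter
#' \eqn{R(t)} and mean phase \eqn{\Theta(t)} over the neurons with a
#' valid phase at each sample.
#'
#' @param trains list of burst trains (one per neuron).
#' @param t_range length-2 range of the grid in seconds (default: span of
#'   all onsets).
#' @param dt_grid grid spacing in seconds.
#' @return An object of class \code{sync_series}: list with \code{times},
#'   \code{R}, \code{Theta}, \code{n_valid} (valid neurons per sample)
#'   and the \code{phases} matrix (neurons x time).
#' @export
sync_series <- function(trains, t_range = NULL, dt_grid = 1e-3) {
  stopifnot(is.list(trains), length(trains) >= 1, dt_grid > 0)
  if (is.null(t_range)) {
    all_on <- unlist(trains, use.names = FALSE)
    if (length(all_on) < 2) stop("no burst onsets to build a grid from")
    t_range <- range(all_on)
  }
  times <- seq(t_range[1], t_range[2], by = dt_grid)
  phases <- t(vapply(trains, phase_from_onsets, numeric(length(times)),
                     t = times))
  z <- exp(1i * phases)
  n_valid <- colSums(is.finite(phases))
  zbar <- colSums(z, na.rm = TRUE) / pmax(n_valid, 1)
  R <- ifelse(n_valid > 0, Mod(zbar), NA_real_)
  Theta <- ifelse(n_valid > 0, Arg(zbar), NA_real_)
  structure(list(times = times, R = R, Theta = Theta,
                 n_valid = n_valid, phases = phases),
            class = "sync_series")
}

#' @export
print.sync_series <- function(x, ...) {
  cat(sprintf("Synchronization series: %d neurons, t in [%.3g, %.3g] s, mean R = %.3f\n",
              nrow(x$phases), min(x$times), max(x$times),
              mean(x$R, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.sync_series <- function(x, ...) {
  plot(x$times, x$R, type = "l", ylim = c(0, 1),
       xlab = "time [s]", ylab = "R(t)", ...)
  invisible(x)
}

#' Time-averaged order parameter
#'
#' Mean of \eqn{R(t)} over a time window, excluding invalid samples.
#'
#' @param series a [sync_series()] object.
#' @param window length-2 window in seconds (default: full support).
#' @return Scalar mean R.
#' @export
mean_R <- function(series, window = NULL) {
  stopifnot(inherits(series, "sync_series"))
  keep <- rep(TRUE, length(series$times))
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] < window[2])
    keep <- series$times >= window[1] & series$times <= window[2]
  }
  r <- series$R[keep]
  r <- r[is.finite(r)]
  if (length(r) == 0) stop("empty window: no valid R samples")
  mean(r)
}

#' Burst-phase synchronization of a simulation
#'
#' Detects per-neuron burst onsets of a [simulate_network()] trace and
#' returns its time-resolved order parameter.  For the Izhikevich backend
#' the exact spike (reset) times recorded by the integrator are used; for
#' Morris-Lecar, threshold crossings of the recorded membrane potential.
#'
#' @param sim a \code{dbs_sim} object.
#' @param threshold burst detection threshold; default -0.05
#'   (dimensionless) for Morris-Lecar and 0 mV for Izhikevich.
#' @param min_gap minimal quiescence separating bursts in seconds
#'   (\code{NULL}: automatic rule, see [detect_burst_onsets()]).
#' @param dt_grid grid spacing of the R(t) series in seconds.
#' @return A [sync_series()] object spanning the full simulated interval.
#' @export
compute_sync <- function(sim, threshold = NULL, min_gap = NULL,
                         dt_grid = 1e-3) {
  stopifnot(inherits(sim, "dbs_sim"))
  if (!is.null(sim$spikes)) {
    trains <- lapply(sim$spikes, burst_onsets_from_spikes, min_gap = min_gap)
  } else {
    if (is.null(threshold))
      threshold <- if (sim$backend == "morris_lecar") -0.05 else 0
    dt <- sim$times[2] - sim$times[1]
    trains <- apply(sim$V, 1, detect_burst_onsets, dt = dt,
                    threshold = threshold, min_gap = min_gap,
                    simplify = FALSE)
  }
  sync_series(trains, t_range = range(sim$times), dt_grid = dt_grid)
}
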