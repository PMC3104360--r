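#' Simulated local field potential
#'
#' Point-source summation of per-neuron ionic currents at a virtual
#' recording electrode,
#' \deqn{LFP(t) = R_e \sum_j I_j(t) / r_j,}
#' with \eqn{r_j} the neuron-electrode distance and \eqn{R_e} the
#' (homogeneous) extracellular resistivity.  The stimulation current is
#' excluded from \eqn{I_j} upstream.  A distance floor avoids the
#' singularity when the electrode coincides with a neuron.
#'
#' @param currents n_neurons x n_times matrix of total non-stimulation
#'   ionic currents.
#' @param positions n_neurons x 2 neuron coordinates.
#' @param electrode_pos length-2 recording-electrode coordinate.
#' @param times optional sample times in seconds.
#' @param R_e extracellular resistivity.
#' @param dist_floor minimal effective distance (lattice units).
#' @return An object of class \code{lfp_trace}: list with \code{times},
#'   \code{lfp}, \code{electrode_pos}, \code{R_e}.
#' @export
#' @examples
#' lfp_from_currents(matrix(1, 2, 1), rbind(c(1, 0), c(2, 0)),
#'                   c(0, 0))$lfp  # 1/1 + 1/2
lfp_from_currents <- function(currents, positions, electrode_pos,
                              times = NULL, R_e = 1, dist_floor = 0.05) {
  stopifnot(is.matrix(currents), nrow(currents) == nrow(positions),
            length(electrode_pos) == 2, R_e > 0, dist_floor >= 0)
  r <- sqrt((positions[, 1] - electrode_pos[1])^2 +
              (positions[, 2] - electrode_pos[2])^2)
  r <- pmax(r, dist_floor)
  lfp <- R_e * as.vector(crossprod(currents, 1 / r))
  if (is.null(times)) times <- seq_len(ncol(currents)) - 1
  structure(list(times = times, lfp = lfp,
                 electrode_pos = electrode_pos, R_e = R_e),
            class = "lfp_trace")
}

#' LFP of a simulated network
#'
#' Convenience wrapper: sums the recorded ionic currents of a
#' [simulate_network()] trace at a recording electrode placed at the
#' lattice centroid (the default), with a distance floor of half the
#' lattice spacing.
#'
#' @param sim a \code{dbs_sim} object.
#' @param electrode_pos recording coordinate (default: lattice centroid).
#' @param R_e extracellular resistivity.
#' @return An \code{lfp_trace} object.
#' @export
simulated_lfp <- function(sim, electrode_pos = NULL, R_e = 1) {
  stopifnot(inherits(sim, "dbs_sim"))
  if (is.null(electrode_pos))
    electrode_pos <- colMeans(sim$lattice$positions)
  lfp_from_currents(sim$I_ion, sim$lattice$positions, electrode_pos,
                    times = sim$times, R_e = R_e,
                    dist_floor = sim$lattice$dl / 2)
}

#' Spectrogram of an LFP trace in dB
#'
#' Short-time power spectrum (Hann window) of a regularly sampled LFP,
#' \eqn{10 \log_{10}} power, resolving the 5-20 Hz band in which the
#' pathologically synchronized network concentrates its activity.
#'
#' @param trace an \code{lfp_trace} object, or a numeric series (then
#'   \code{fs} must be given).
#' @param window_len window length in seconds.
#' @param overlap fractional window overlap in [0, 1).
#' @param fs sampling rate in Hz (derived from \code{trace$times} for an
#'   \code{lfp_trace}).
#' @return An object of class \code{spectrogram_db}: list with \code{db}
#'   and \code{power} (frequency x time matrices), \code{f} (Hz),
#'   \code{t} (s).
#' @export
spectrogram_db <- function(trace, window_len = 1, overlap = 0.75,
                           fs = NULL) {
  if (inherits(trace, "lfp_trace")) {
    fs <- 1 / (trace$times[2] - trace$times[1])
    x <- trace$lfp
  } else {
    stopifnot(!is.null(fs))
    x <- as.numeric(trace)
  }
  stopifnot(overlap >= 0, overlap < 1, window_len > 0)
  n <- round(window_len * fs)
  if (n > length(x))
    stop("window longer than the trace")
  sg <- signal::specgram(x - mean(x), n = n, Fs = fs,
                         window = signal::hanning(n),
                         overlap = round(overlap * n))
  power <- Mod(sg$S)^2
  structure(list(db = 10 * log10(power + .Machine$double.xmin),
                 power = power, f = as.numeric(sg$f),
                 t = as.numeric(sg$t)),
            class = "spectrogram_db")
}

#' @export
plot.spectrogram_db <- function(x, fmax = 60, ...) {
  keep <- x$f <= fmax
  image(x$t, x$f[keep], t(x$db[keep, , drop = FALSE]),
        xlab = "time [s]", ylab = "frequency [Hz]",
        col = hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Fractional band power of a spectrogram
#'
#' Power in a frequency band divided by the total power, both summed over
#' a time window of the spectrogram: a scalar summary of how much of the
#' LFP activity is concentrated in (for example) the 5-20 Hz band.
#'
#' @param spec a [spectrogram_db()] object.
#' @param band length-2 frequency band in Hz.
#' @param window optional length-2 time window in seconds.
#' @return Fraction in [0, 1].
#' @export
band_power_ratio <- function(spec, band, window = NULL) {
  stopifnot(inherits(spec, "spectrogram_db"), length(band) == 2,
            band[1] < band[2])
  fin <- spec$f >= band[1] & spec$f <= band[2]
  if (!any(fin)) stop("empty band: no frequency bins in [",
                      band[1], ", ", band[2], "] Hz")
  keep <- rep(TRUE, length(spec$t))
  if (!is.null(window))
    keep <- spec$t >= window[1] & spec$t <= window[2]
  if (!any(keep)) stop("empty time window")
  sum(spec$power[fin, keep, drop = FALSE]) /
    sum(spec$power[, keep, drop = FALSE])
}
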