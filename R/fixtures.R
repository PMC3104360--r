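#' Specification of a synthetic burst population
#'
#' Ground-truth fixture for the synchronization metrics: a population of
#' neurons bursting on a common periodic grid with Gaussian per-onset
#' timing jitter.  For Gaussian phase jitter the expected order parameter
#' has the closed form of the Gaussian characteristic function,
#' \deqn{R_{expected} = \exp\left(-\tfrac12 (2\pi f \sigma)^2\right),}
#' with \eqn{f} the burst rate and \eqn{\sigma} the onset jitter s.d.
#'
#' @param n_neurons population size.
#' @param burst_rate bursts per second (> 0).
#' @param phase_dispersion s.d. of the onset jitter in seconds (>= 0).
#' @param duration total duration in seconds.
#' @param seed RNG seed.
#' @return An object of class \code{burst_spec}.
#' @seealso [make_burst_population()]
#' @export
synthetic_burst_spec <- function(n_neurons, burst_rate, phase_dispersion,
                                 duration, seed = 1) {
  stopifnot(n_neurons >= 1, burst_rate > 0, phase_dispersion >= 0,
            duration > 1 / burst_rate)
  structure(list(n_neurons = n_neurons, burst_rate = burst_rate,
                 phase_dispersion = phase_dispersion,
                 duration = duration, seed = seed),
            class = "burst_spec")
}

#' Generate a synthetic burst population with known synchronization
#'
#' Onset times are a common periodic grid plus independent Gaussian
#' jitter per neuron and per burst; each train is sorted so onsets stay
#' increasing even under large dispersion.
#'
#' \code{R_expected} is the population order parameter sampled at the
#' common grid instants, where each neuron's phase error is the full
#' jitter of a single onset.  Between onsets the linear phase
#' interpolation mixes two independent jitters (error variance
#' \eqn{((1-u)^2 + u^2)\sigma_\phi^2} at interpolation fraction
#' \eqn{u}), so the time-averaged \eqn{R(t)} lies slightly above
#' \code{R_expected}, approximately \eqn{\exp(-\sigma_\phi^2/3)}.
#'
#' @param spec a [synthetic_burst_spec()] object.
#' @return List with \code{trains} (list of onset-time vectors),
#'   \code{grid} (the unjittered common onset times),
#'   \code{R_expected} (analytic ground truth at the grid instants) and
#'   \code{spec}.
#' @export
#' @examples
#' pop <- make_burst_population(synthetic_burst_spec(50, 5, 0, 4))
#' pop$R_expected  # 1: zero dispersion
make_burst_population <- function(spec) {
  stopifnot(inherits(spec, "burst_spec"))
  set.seed(spec$seed)
  period <- 1 / spec$burst_rate
  grid <- seq(period, spec$duration - period / 2, by = period)
  trains <- lapply(seq_len(spec$n_neurons), function(j) {
    on <- sort(grid + rnorm(length(grid), 0, spec$phase_dispersion))
    structure(on, class = "burst_train")
  })
  R_expected <- exp(-(2 * pi * spec$burst_rate * spec$phase_dispersion)^2 / 2)
  list(trains = trains, grid = grid, R_expected = R_expected, spec = spec)
}

#' Default stereotyped burst template
#'
#' A short train of clipped-sinusoid "spikes" riding on the baseline,
#' used to paint bursts into a synthetic voltage trace.  The shape is
#' irrelevant to the burst-onset metrics by design; only the first
#' threshold crossing matters.
#'
#' @param dt sample interval in seconds.
#' @param n_spikes spikes per burst.
#' @param spike_ms width of one spike in ms.
#' @param gap_ms gap between spikes in ms.
#' @param amp spike amplitude above baseline.
#' @return Numeric template (deviation from baseline).
#' @export
burst_template <- function(dt, n_spikes = 6, spike_ms = 3, gap_ms = 5,
                           amp = 0.35) {
  sp <- max(2L, round(spike_ms / 1000 / dt))
  gp <- max(1L, round(gap_ms / 1000 / dt))
  one <- amp * pmax(sin(seq(0, pi, length.out = sp)), 0)
  as.vector(vapply(seq_len(n_spikes),
                   function(i) c(one, numeric(gp)),
                   numeric(sp + gp)))
}

#' Synthetic voltage trace with bursts at known onsets
#'
#' Baseline plus copies of a burst template at the given onset times plus
#' white Gaussian noise, for round-trip testing of the burst-onset
#' detector.
#'
#' @param onsets onset times in seconds (strictly increasing).
#' @param dt sample interval in seconds.
#' @param duration trace duration in seconds (default: last onset plus
#'   template length plus 0.1 s).
#' @param burst_shape template added at each onset (default
#'   [burst_template()]).
#' @param noise_sd white-noise s.d.
#' @param baseline resting potential.
#' @param seed optional RNG seed for the noise.
#' @return List with \code{v}, \code{dt}, \code{onsets}.
#' @export
make_voltage_with_bursts <- function(onsets, dt = 1e-3, duration = NULL,
                                     burst_shape = NULL, noise_sd = 0,
                                     baseline = -0.25, seed = NULL) {
  stopifnot(all(diff(onsets) > 0) || length(onsets) <= 1, dt > 0)
  if (is.null(burst_shape)) burst_shape <- burst_template(dt)
  if (length(onsets) > 1 && length(burst_shape) * dt > min(diff(onsets)))
    stop("burst template longer than the minimal inter-onset gap ",
         "(overlapping templates)")
  if (is.null(duration))
    duration <- (if (length(onsets)) max(onsets) else 0) +
      length(burst_shape) * dt + 0.1
  n <- ceiling(duration / dt)
  v <- rep(baseline, n)
  for (on in onsets) {
    i0 <- round(on / dt) + 1L
    ii <- i0:min(i0 + length(burst_shape) - 1L, n)
    v[ii] <- v[ii] + burst_shape[seq_along(ii)]
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + rnorm(n, 0, noise_sd)
  }
  list(v = v, dt = dt, onsets = onsets)
}
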