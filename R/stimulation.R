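#' Charge-balanced biphasic pulse train
#'
#' High-frequency DBS waveform \eqn{W(t)}: within each period a short
#' positive pulse of width \code{t_pos_ms} is followed by a longer
#' negative pulse of width \code{t_neg_ms} whose amplitude is derived so
#' the net charge per period is exactly zero
#' (\code{amp_neg = -amp_pos * t_pos_ms / t_neg_ms}), as required
#' clinically to avoid charge deposition in the tissue.
#'
#' @param freq_hz pulse repetition rate in Hz.
#' @param t_pos_ms positive-phase width in ms.
#' @param t_neg_ms negative-phase width in ms.
#' @param amp_pos positive amplitude in normalized units (the electrode
#'   strength \code{c_s} scales the delivered current).
#' @return An object of class \code{pulse_train} with the derived
#'   \code{amp_neg} and \code{period_ms}.
#' @export
#' @examples
#' tr <- pulse_train()
#' tr$amp_pos * tr$t_pos_ms + tr$amp_neg * tr$t_neg_ms  # exactly 0
pulse_train <- function(freq_hz = 130, t_pos_ms = 0.2, t_neg_ms = 3,
                        amp_pos = 1) {
  stopifnot(freq_hz > 0, t_pos_ms > 0, t_neg_ms > 0)
  period_ms <- 1000 / freq_hz
  if (t_pos_ms + t_neg_ms > period_ms)
    stop("pulse widths exceed the period (", signif(period_ms, 6), " ms)")
  structure(list(freq_hz = freq_hz, t_pos_ms = t_pos_ms,
                 t_neg_ms = t_neg_ms, amp_pos = amp_pos,
                 amp_neg = -amp_pos * t_pos_ms / t_neg_ms,
                 period_ms = period_ms),
            class = "pulse_train")
}

#' Evaluate the pulse-train waveform
#'
#' \eqn{W(t)} is periodic with period \code{1000/freq_hz} ms:
#' \code{amp_pos} on [0, t_pos), \code{amp_neg} on [t_pos, t_pos + t_neg),
#' zero for the rest of the period.
#'
#' @param t_ms time in ms (vectorized).
#' @param train a [pulse_train()] object.
#' @return Waveform amplitude at \code{t_ms}.
#' @export
pulse_waveform <- function(t_ms, train = pulse_train()) {
  stopifnot(inherits(train, "pulse_train"))
  tt <- t_ms %% train$period_ms
  ifelse(tt < train$t_pos_ms, train$amp_pos,
         ifelse(tt < train$t_pos_ms + train$t_neg_ms, train$amp_neg, 0))
}

#' Stimulation on/off window
#'
#' @param t_on,t_off onset and offset times in seconds (\code{t_on <
#'   t_off}).  The window indicator \eqn{X_1(t)} is 1 on
#'   [t_on, t_off) and 0 elsewhere.
#' @return An object of class \code{stim_window}.
#' @export
stim_window <- function(t_on, t_off) {
  stopifnot(t_on < t_off)
  structure(list(t_on = t_on, t_off = t_off), class = "stim_window")
}

#' Electrode layout on a lattice
#'
#' Builds the stimulation electrode array: either one electrode at the
#' lattice centroid (\code{"center"}) or four electrodes at the centroids
#' of the four equal quadrants (\code{"quad"}).  The layout normalization
#' \code{c_n_stim} is the ratio of the summed spatial activation
#' \eqn{\sum_j \sum_k e^{-d_{jk}/\lambda}} of the layout to that of the
#' single central electrode, so the total delivered stimulation is
#' independent of the number of electrodes used.
#'
#' @param mode \code{"center"} or \code{"quad"}.
#' @param lattice a [build_lattice()] object.
#' @param c_s stimulation strength parameter.
#' @param decay_len spatial decay constant of the exponential activation
#'   profile, in lattice units.
#' @return An object of class \code{electrode_array}: list with
#'   \code{positions} (k x 2), \code{mode}, \code{c_s}, \code{decay_len},
#'   \code{c_n_stim}.
#' @export
#' @examples
#' lat <- build_lattice(100)
#' electrode_layout("center", lat)$positions  # (0.45, 0.45)
electrode_layout <- function(mode = c("center", "quad"), lattice,
                             c_s = 0.1, decay_len = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(lattice, "lattice"), c_s >= 0, decay_len > 0)
  ctr <- colMeans(lattice$positions)
  if (mode == "center") {
    pos <- matrix(ctr, 1, 2, byrow = TRUE)
  } else {
    m <- round(sqrt(lattice$n_neurons))
    off <- (m - 1) * lattice$dl / 4          # quarter of the sheet extent
    pos <- cbind(ctr[1] + c(-off, -off, off, off),
                 ctr[2] + c(-off, off, -off, off))
  }
  colnames(pos) <- c("x", "y")
  act_sum <- function(epos) {
    s <- 0
    for (k in seq_len(nrow(epos))) {
      d <- sqrt((lattice$positions[, 1] - epos[k, 1])^2 +
                  (lattice$positions[, 2] - epos[k, 2])^2)
      s <- s + sum(exp(-d / decay_len))
    }
    s
  }
  ref <- act_sum(matrix(ctr, 1, 2, byrow = TRUE))
  structure(list(positions = pos, mode = mode, c_s = c_s,
                 decay_len = decay_len, c_n_stim = act_sum(pos) / ref),
            class = "electrode_array")
}

#' Stimulation current at a neuron
#'
#' Per-neuron DBS current: the pulse train, gated by the stimulation
#' window, delivered through every electrode with exponential spatial
#' decay,
#' \deqn{I^{stim}_j(t) = \frac{c_s}{c_n^{stim}} \sum_k
#'   e^{-\|y_j - y^k\|/\lambda}\; X_1(t)\, W(t).}
#'
#' @param neuron_pos length-2 neuron coordinate.
#' @param t time in seconds (vectorized).
#' @param array an [electrode_layout()] object.
#' @param train a [pulse_train()] object.
#' @param window a [stim_window()] object.
#' @return Stimulation current at each \code{t}.
#' @export
stim_current <- function(neuron_pos, t, array, train = pulse_train(),
                         window) {
  stopifnot(inherits(array, "electrode_array"),
            inherits(window, "stim_window"), length(neuron_pos) == 2)
  d <- sqrt((array$positions[, 1] - neuron_pos[1])^2 +
              (array$positions[, 2] - neuron_pos[2])^2)
  gain <- array$c_s / array$c_n_stim * sum(exp(-d / array$decay_len))
  x1 <- as.numeric(t >= window$t_on & t < window$t_off)
  gain * x1 * pulse_waveform(t * 1000, train)
}

# per-neuron spatial stimulation gains for the engine (without the
# backend-specific stimulation weight)
stim_gain_vector <- function(lattice, array) {
  g <- numeric(lattice$n_neurons)
  for (k in seq_len(nrow(array$positions))) {
    d <- sqrt((lattice$positions[, 1] - array$positions[k, 1])^2 +
                (lattice$positions[, 2] - array$positions[k, 2])^2)
    g <- g + exp(-d / array$decay_len)
  }
  array$c_s / array$c_n_stim * g
}
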