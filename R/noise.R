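#' Exponentially correlated background-noise traces
#'
#' Generates one independent stationary Ornstein-Uhlenbeck current per
#' neuron, the model of spatially incoherent background synaptic
#' bombardment: \eqn{dI/dt = -I/\tau + D\,\xi(t)} with
#' \eqn{\xi} unit-variance Gaussian white noise.  The exact exponential
#' update is used,
#' \deqn{I(t+\Delta) = I(t) e^{-\Delta/\tau} +
#'   \sigma_{eq}\sqrt{1 - e^{-2\Delta/\tau}}\; z,\qquad z \sim N(0,1),}
#' with stationary s.d. \eqn{\sigma_{eq} = D\sqrt{\tau/2}}, so the
#' autocorrelation \eqn{e^{-\Delta/\tau}} and variance are independent of
#' the step size.  The first sample of each row is drawn from the
#' stationary distribution.
#'
#' This is the "offline" noise path; the network integrators stream the
#' identical update internally.
#'
#' @param n_neurons number of independent rows.
#' @param n_steps number of time samples per row.
#' @param dt sample interval in integrator time units (> 0).
#' @param params a [noise_params()] object.
#' @param seed optional RNG seed.
#' @return n_neurons x n_steps matrix of noise currents.
#' @export
#' @examples
#' tr <- ou_noise_trace(2, 1000, 0.1, noise_params(), seed = 1)
#' sd(tr[1, ])  # ~ D * sqrt(tau / 2)
ou_noise_trace <- function(n_neurons, n_steps, dt, params = noise_params(),
                           seed = NULL) {
  stopifnot(inherits(params, "noise_params"), dt > 0,
            n_neurons >= 1, n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (params$D_noise == 0)
    return(matrix(0, n_neurons, n_steps))
  edt <- exp(-dt / params$tau_noise)
  sig_eq <- params$D_noise * sqrt(params$tau_noise / 2)
  sig_up <- sig_eq * sqrt(1 - edt^2)
  out <- matrix(0, n_neurons, n_steps)
  out[, 1] <- rnorm(n_neurons, 0, sig_eq)
  for (i in seq_len(n_steps - 1L))
    out[, i + 1L] <- out[, i] * edt + rnorm(n_neurons, 0, sig_up)
  out
}
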