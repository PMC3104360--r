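#' Write a scenario to a YAML file
#'
#' Serializes a [scenario()] as a flat YAML document so runs can be
#' archived and replayed.  All parameter blocks (neuron, gate, coupling,
#' noise, stimulation, seeds) are written with their exact keys.
#'
#' @param config a [scenario()] object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario"))
  x <- list(backend = config$backend, n_neurons = config$n_neurons,
            duration = config$duration, dt = config$dt, dl = config$dl,
            jitter_sd = config$jitter_sd, record_dt = config$record_dt,
            neuron = unclass(config$neuron), gate = unclass(config$gate),
            coupling = unclass(config$coupling),
            noise = unclass(config$noise), seeds = config$seeds)
  if (!is.null(config$stimulation)) {
    p <- config$stimulation
    x$stimulation <- list(mode = p$mode, freq_hz = p$train$freq_hz,
                          t_pos_ms = p$train$t_pos_ms,
                          t_neg_ms = p$train$t_neg_ms,
                          amp_pos = p$train$amp_pos, c_s = p$c_s,
                          window = c(p$window$t_on, p$window$t_off),
                          decay_len = p$decay_len)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a scenario from a YAML file
#'
#' Counterpart of [write_scenario()].  Packaged reference configurations
#' are available via \code{system.file("extdata", "ml_fig1.yaml",
#' package = "dbsnet")} and \code{"izh_fig6.yaml"}.
#'
#' @param path YAML file path.
#' @return A [scenario()] object.
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  stim <- NULL
  if (!is.null(x$stimulation)) {
    s <- x$stimulation
    stim <- stim_protocol(mode = s$mode,
                          train = pulse_train(s$freq_hz, s$t_pos_ms,
                                              s$t_neg_ms, s$amp_pos),
                          window = stim_window(s$window[1], s$window[2]),
                          c_s = s$c_s, decay_len = s$decay_len)
  }
  neuron <- if (x$backend == "morris_lecar") do.call(ml_params, x$neuron)
            else do.call(izh_params, x$neuron)
  cpl <- x$coupling
  scenario(backend = x$backend, n_neurons = x$n_neurons,
           duration = x$duration, dt = x$dt, dl = x$dl,
           jitter_sd = x$jitter_sd, neuron = neuron,
           gate = do.call(gate_params, x$gate),
           coupling = coupling_params(cpl$backend, cpl$g_bar_s,
                                      cpl$v_rev_syn, cpl$sigma_g, cpl$c_n,
                                      cpl$kernel),
           noise = do.call(noise_params, x$noise), stimulation = stim,
           record_dt = x$record_dt, seeds = x$seeds)
}
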