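#' Build a square lattice of neurons
#'
#' Places \code{n_neurons} (a perfect square) on a regular square grid with
#' spacing \code{dl}, ordered lexicographically, and computes the pairwise
#' distance matrix.  With \code{jitter_sd > 0} an independent Gaussian
#' perturbation is added to each ordered pair's distance (not to the
#' positions), clamped at zero, emulating heterogeneous effective
#' connectivity ("random lattice"); the jittered matrix is therefore not
#' symmetric in general.
#'
#' @param n_neurons number of neurons; must be a perfect square.
#' @param dl lattice spacing (> 0).
#' @param jitter_sd standard deviation of the Gaussian distance jitter
#'   (0 = regular lattice).
#' @param seed optional RNG seed for the jitter draw.
#' @return An object of class \code{lattice}: list with \code{positions}
#'   (n x 2 matrix), \code{distances} (n x n, zero diagonal),
#'   \code{n_neurons}, \code{dl}, \code{jitter_sd}, \code{seed}.
#' @export
#' @examples
#' lat <- build_lattice(100, dl = 0.1)
#' max(lat$distances)  # corner to corner: 0.9 * sqrt(2)
build_lattice <- function(n_neurons, dl = 0.1, jitter_sd = 0, seed = NULL) {
  m <- round(sqrt(n_neurons))
  if (m * m != n_neurons)
    stop("'n_neurons' must be a perfect square (got ", n_neurons, ")")
  stopifnot(dl > 0, jitter_sd >= 0)
  idx <- seq_len(n_neurons) - 1L
  positions <- cbind(x = (idx %% m) * dl, y = (idx %/% m) * dl)
  D <- as.matrix(stats::dist(positions))
  dimnames(D) <- NULL
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    D <- pmax(D + matrix(rnorm(n_neurons^2, 0, jitter_sd),
                         n_neurons, n_neurons), 0)
    diag(D) <- 0
  }
  structure(list(positions = positions, distances = D,
                 n_neurons = n_neurons, dl = dl,
                 jitter_sd = jitter_sd, seed = seed),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  m <- round(sqrt(x$n_neurons))
  cat(sprintf("Square lattice: %d neurons (%dx%d), spacing %g%s\n",
              x$n_neurons, m, m, x$dl,
              if (x$jitter_sd > 0)
                sprintf(", distance jitter sd %g", x$jitter_sd) else ""))
  invisible(x)
}

#' Distance-dependent synaptic weight
#'
#' Spatial kernel of the local coupling: \eqn{w(d) = e^{-d^2/2\sigma_g^2}}
#' (Gaussian, default) or \eqn{w(d) = e^{-d/\sigma_g}} (exponential).
#' \code{w(0) = 1} and \code{w} is strictly decreasing in \code{d}.
#'
#' @param d distance (>= 0, vectorized).
#' @param sigma_g kernel width in lattice units (> 0).
#' @param kernel kernel shape.
#' @return Weight in (0, 1].
#' @export
#' @examples
#' spatial_weight(0.5, sigma_g = 0.5)  # exp(-1/2)
spatial_weight <- function(d, sigma_g = 0.5,
                           kernel = c("gaussian", "exponential")) {
  kernel <- match.arg(kernel)
  stopifnot(sigma_g > 0, all(d >= 0))
  if (kernel == "gaussian") exp(-d^2 / (2 * sigma_g^2))
  else exp(-d / sigma_g)
}

#' Intra-population coupling weight matrix
#'
#' Applies the spatial kernel to a lattice's distance matrix and zeroes
#' the diagonal (no self-coupling).
#'
#' @param lattice a [build_lattice()] object.
#' @param params a [coupling_params()] object.
#' @return n x n weight matrix.
#' @export
coupling_matrix <- function(lattice, params) {
  stopifnot(inherits(lattice, "lattice"), inherits(params, "coupling_params"))
  W <- spatial_weight(lattice$distances, params$sigma_g, params$kernel)
  diag(W) <- 0
  W
}

#' Synaptic coupling current
#'
#' Distance-weighted excitatory synaptic current onto each neuron:
#' \deqn{I^{syn}_j = \frac{\bar g_s}{c_n\, n_{norm}} \sum_{k}
#'   W_{jk}\, s_k\, (v_s - v_j).}
#' \code{weights} must have a zero diagonal (or be a row excluding the
#' neuron itself) so the sum runs over \eqn{k \ne j}.  In the full network
#' the normalization includes the population size (\code{n_norm = N});
#' the default \code{n_norm = 1} gives the bare per-pair current.
#'
#' @param v postsynaptic membrane potential(s), length m.
#' @param gates presynaptic gate values in [0, 1], length n.
#' @param weights m x n weight matrix (or length-n vector for m = 1).
#' @param params a [coupling_params()] object.
#' @param n_norm population-size normalization factor.
#' @return Synaptic current, length m.
#' @export
#' @examples
#' cp <- coupling_params("morris_lecar", c_n = 1)
#' synaptic_current(0, gates = 1, weights = 1, cp)  # 0.4 * (-0.85 - 0)
synaptic_current <- function(v, gates, weights, params, n_norm = 1) {
  stopifnot(inherits(params, "coupling_params"), n_norm > 0)
  if (any(gates < -1e-12 | gates > 1 + 1e-12))
    stop("'gates' must lie in [0, 1]")
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = length(v),
                                               ncol = length(gates),
                                               byrow = length(v) == 1)
  if (ncol(weights) != length(gates))
    stop("dimension mismatch between 'gates' and 'weights'")
  if (nrow(weights) != length(v))
    stop("dimension mismatch between 'v' and 'weights'")
  drive <- as.vector(weights %*% gates)
  params$g_bar_s / (resolve_c_n(params, weights) * n_norm) *
    drive * (params$v_rev_syn - v)
}

resolve_c_n <- function(params, weights) {
  if (identical(params$c_n, "auto")) mean(rowSums(weights)) else params$c_n
}

#' Feedforward coupling between two populations
#'
#' Random Gaussian synaptic strengths from every pacemaker neuron to every
#' driven neuron.  The mean weight is matched to the mean intra-pacemaker
#' coupling weight (strong driving); the spread is a fraction
#' \code{rel_sd} of the mean, and draws are clamped at zero to keep all
#' connections excitatory.  The coupling is strictly feedforward
#' (pacemaker to driven only).
#'
#' @param n_from,n_to pacemaker and driven population sizes.
#' @param mean_weight target mean weight; typically
#'   \code{mean(W[upper/lower])} of the pacemaker's [coupling_matrix()].
#' @param rel_sd relative standard deviation of the Gaussian draw.
#' @param seed optional RNG seed.
#' @return An object of class \code{interpop_coupling}: list with
#'   \code{weight_matrix} (n_to x n_from), \code{mean_weight},
#'   \code{rel_sd}, \code{seed}.
#' @export
interpop_coupling <- function(n_from, n_to, mean_weight, rel_sd = 0.25,
                              seed = NULL) {
  stopifnot(n_from > 0, n_to > 0, mean_weight > 0, rel_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(pmax(rnorm(n_to * n_from, mean_weight, rel_sd * mean_weight), 0),
              n_to, n_from)
  structure(list(weight_matrix = A, mean_weight = mean_weight,
                 rel_sd = rel_sd, seed = seed),
            class = "interpop_coupling")
}

#' Feedforward synaptic current from the pacemaker population
#'
#' Same functional form as [synaptic_current()] with the Gaussian-random
#' feedforward weight matrix in place of the distance kernel.
#'
#' @param v driven-population membrane potentials.
#' @param pacemaker_gates pacemaker gate values in [0, 1].
#' @param coupling an [interpop_coupling()] object.
#' @param params the pacemaker's [coupling_params()] object.
#' @param n_norm population-size normalization factor.
#' @return Current onto each driven neuron.
#' @export
interpop_current <- function(v, pacemaker_gates, coupling, params,
                             n_norm = 1) {
  stopifnot(inherits(coupling, "interpop_coupling"))
  A <- coupling$weight_matrix
  if (ncol(A) != length(pacemaker_gates) || nrow(A) != length(v))
    stop("dimension mismatch between populations and coupling matrix")
  synaptic_current(v, pacemaker_gates, A, params, n_norm = n_norm)
}
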