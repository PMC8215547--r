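# The biophysical "living" layer as a feedforward network: input neurons
# driven by calibrated single-spike pulses, sparse excitatory alpha synapses
# onto hidden Pinsky-Rinzel neurons, binary readout by spike detection.

#' Construct a biophysical network
#'
#' A feedforward input-to-hidden network of Pinsky-Rinzel neurons. Each
#' active input neuron receives its calibrated 5 ms somatic pulse at t = 0
#' and delivers one alpha-synapse event per connection; hidden outputs are
#' binary (any somatic spike within the observation window). Only primary,
#' monosynaptically evoked spikes exist in this topology (the early cut-off
#' assumption that makes a randomly connected culture observable as a
#' feedforward network).
#'
#' @param input_params list of [pr_neuron_params()], one per input neuron
#' @param hidden_params list of [pr_neuron_params()], one per hidden neuron
#' @param mask binary connectivity matrix (n_in x n_hidden)
#' @param gsyn matrix of synaptic conductances (uS) on masked entries
#' @param tau,delay matrices (or scalars) of synapse kinetics (ms)
#' @param window observation window (ms)
#' @param threshold spike threshold (mV)
#' @param dt integration step (ms)
#' @return an object of class `biophys_network`
#' @export
biophys_network <- function(input_params, hidden_params, mask, gsyn,
                            tau, delay, window = .PR_WINDOW, threshold = 0,
                            dt = .PR_DT) {
  n_in <- length(input_params); n_hidden <- length(hidden_params)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == c(n_in, n_hidden)))
    stop("mask must be n_in x n_hidden")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  expand <- function(x) {
    if (length(x) == 1) matrix(x, n_in, n_hidden) else as.matrix(x)
  }
  gsyn <- expand(gsyn); tau <- expand(tau); delay <- expand(delay)
  if (any(gsyn[mask == 1] < 0)) stop("synaptic conductances must be >= 0")
  if (any(tau <= 0)) stop("synapse tau must be positive")
  if (window <= 0) stop("window must be positive")
  structure(list(input_params = input_params, hidden_params = hidden_params,
                 mask = mask, gsyn = gsyn, tau = tau, delay = delay,
                 window = window, threshold = threshold, dt = dt,
                 calibration = NULL),
            class = "biophys_network")
}

#' @export
print.biophys_network <- function(x, ...) {
  cat(sprintf("biophysical network: %d inputs -> %d hidden neurons\n",
              nrow(x$mask), ncol(x$mask)))
  cat(sprintf("  connectivity %.1f%%, window %g ms, dt %g ms, %s\n",
              100 * mean(x$mask), x$window, x$dt,
              if (is.null(x$calibration)) "inputs not calibrated"
              else "inputs calibrated"))
  invisible(x)
}

#' Calibrate the input neurons of a biophysical network
#'
#' Runs [calibrate_single_spike_current()] for every distinct input
#' parameter set and stores the evoked spike times, which fix the synaptic
#' event times seen by the hidden layer.
#'
#' @param net a [biophys_network()]
#' @param pulse_duration input pulse length (ms)
#' @return the network with a filled `calibration` field
#' @export
calibrate_network <- function(net, pulse_duration = 5) {
  cal <- lapply(net$input_params, calibrate_single_spike_current,
                pulse_duration = pulse_duration, dt = net$dt,
                window = net$window)
  net$calibration <- list(
    amplitude = vapply(cal, `[[`, numeric(1), "amplitude"),
    spike_time = vapply(cal, `[[`, numeric(1), "spike_time"))
  net
}

#' Binary forward pass through the biophysical layer
#'
#' For each binary input vector, every active input neuron fires its
#' calibrated single spike; each hidden neuron integrates the resulting
#' alpha-synapse events from its connected active inputs and reports whether
#' it spiked within the window.
#'
#' When every connection shares the same synapse kinetics, all inputs spike
#' at the same time, and all hidden neurons are identical (the variance-zero
#' configuration), the alpha conductances of simultaneous events add exactly,
#' so a hidden response depends only on the summed conductance; the
#' `"collapsed"` method then thresholds the summed conductance against a
#' bisection-calibrated firing threshold instead of integrating every
#' neuron. `"auto"` uses it when those conditions hold.
#'
#' @param x binary input vector (length n_in) or a n_images x n_in matrix
#' @param net a calibrated [biophys_network()]
#' @param method `"auto"`, `"full"` (always integrate) or `"collapsed"`
#' @return binary hidden vector, or a n_images x n_hidden matrix if `x` is a
#'   matrix
#' @export
biophysical_forward <- function(x, net, method = c("auto", "full",
                                                   "collapsed")) {
  method <- match.arg(method)
  if (is.null(net$calibration))
    stop("input neurons are not calibrated; run calibrate_network() first")
  if (method != "full") {
    uniform <- .net_is_uniform(net)
    if (method == "collapsed" && !uniform)
      stop("collapsed method requires a variance-zero network")
    if (uniform) return(.forward_collapsed(x, net))
  }
  .forward_full(x, net)
}

.net_is_uniform <- function(net) {
  on_mask <- net$mask == 1
  length(unique(net$tau[on_mask])) == 1 &&
    length(unique(net$delay[on_mask])) == 1 &&
    length(unique(vapply(net$input_params, .param_key, "", dt = net$dt))) == 1 &&
    length(unique(vapply(net$hidden_params, .param_key, "", dt = net$dt))) == 1
}

# minimal total synaptic conductance (uS) of one merged alpha event that
# fires the post-neuron; bisection, cached
.firing_gsyn <- function(post, onset, tau, dt, window, threshold) {
  key <- paste("gstar", .param_key(post, dt), onset, tau, window, threshold,
               sep = "|")
  if (!is.null(.lnn_cache[[key]])) return(.lnn_cache[[key]])
  prm <- .pr_param_vector(post)
  prm[11] <- threshold - post$E_L
  st0 <- pr_resting_state(post, dt)
  fires <- function(g) pr_fires_cpp(prm, st0, dt, window,
                                    matrix(c(onset, .dend_gdens(g, post),
                                             tau), 1, 3), .PR_REFRACTORY)
  lo <- 1e-5; hi <- 1e-5
  while (!fires(hi)) {
    hi <- hi * 2
    if (hi > 10) stop("post-neuron cannot be fired by synaptic drive")
  }
  if (fires(lo)) lo <- 0
  while ((hi - lo) > 1e-9 + 1e-7 * hi) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  .lnn_cache[[key]] <- (lo + hi) / 2
  .lnn_cache[[key]]
}

.forward_collapsed <- function(x, net) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (!all(X %in% c(0, 1))) stop("inputs must be binary")
  on_mask <- net$mask == 1
  onset <- net$calibration$spike_time[1] + net$delay[on_mask][1]
  gstar <- .firing_gsyn(net$hidden_params[[1]], onset, net$tau[on_mask][1],
                        net$dt, net$window, net$threshold)
  G <- X %*% (net$gsyn * net$mask)
  H <- 1L * (G > gstar)
  if (is.matrix(x)) H else as.vector(H)
}

.forward_full <- function(x, net) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != nrow(net$mask))
    stop("input length does not match the number of input neurons")
  if (!all(X %in% c(0, 1))) stop("inputs must be binary")
  n_hidden <- ncol(net$mask)
  conn <- lapply(seq_len(n_hidden), function(j) which(net$mask[, j] == 1) - 1L)
  # per-connection conductance densities over each post-neuron's dendrite
  G <- net$gsyn * net$mask
  for (j in seq_len(n_hidden))
    G[, j] <- .dend_gdens(G[, j], net$hidden_params[[j]])
  PRM <- do.call(rbind, lapply(net$hidden_params, .pr_param_vector))
  # spike threshold in the shifted frame (default 0 mV absolute)
  PRM[, 11] <- net$threshold -
    vapply(net$hidden_params, `[[`, numeric(1), "E_L")
  S0 <- do.call(rbind, lapply(net$hidden_params, pr_resting_state,
                              dt = net$dt))
  H <- biophys_hidden_cpp(
    matrix(as.integer(X), nrow(X), ncol(X)), conn, G, net$tau, net$delay,
    net$calibration$spike_time, PRM, S0, net$dt, net$window, .PR_REFRACTORY)
  if (is.matrix(x)) H else as.vector(H)
}
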