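# Simulation of single two-compartment neurons: alpha synapses, traces,
# spike detection, and calibration of the single-spike input pulse that
# stands in for the light-evoked (ChR2) current.

#' Alpha-function synaptic conductance
#'
#' `g(t) = gsyn * u * exp(1 - u)` with `u = (t - spike_time - delay)/tau`;
#' zero before the delayed onset and peaking at `gsyn` when `u = 1`.
#'
#' @param t time (ms); may be a vector
#' @param spike_time pre-synaptic spike time (ms)
#' @param syn an [alpha_synapse_params()] object
#' @return conductance (uS), same length as `t`
#' @export
alpha_conductance <- function(t, spike_time, syn) {
  if (!inherits(syn, "alpha_synapse_params"))
    syn <- do.call(alpha_synapse_params, syn)
  u <- (t - spike_time - syn$delay) / syn$tau
  ifelse(u > 0, syn$gsyn * u * exp(1 - u), 0)
}

#' Accumulated synaptic current
#'
#' Sums the alpha-conductance contributions of a list of synaptic events and
#' converts to current with driving force `(E_syn - Vd)`, so that excitatory
#' events (with `Vd` below `E_syn`) give a positive, depolarizing current.
#'
#' @param Vd dendritic membrane potential (mV)
#' @param t time (ms)
#' @param events list of `list(spike_time =, syn =)` entries
#' @param E_syn synaptic reversal potential (mV, default 0)
#' @return current (nA)
#' @export
synaptic_current <- function(Vd, t, events, E_syn = .PR_ESYN_MV) {
  if (length(events) == 0) return(0)
  g <- sum(vapply(events, function(e)
    alpha_conductance(t, e$spike_time, e$syn), numeric(1)))
  g * (E_syn - Vd)
}

.events_matrix <- function(events, params) {
  if (length(events) == 0) return(matrix(numeric(0), 0, 3))
  do.call(rbind, lapply(events, function(e) {
    syn <- e$syn
    c(e$spike_time + syn$delay, .dend_gdens(syn$gsyn, params), syn$tau)
  }))
}

#' Simulate a Pinsky-Rinzel neuron
#'
#' Integrates the two-compartment model over `t_total` ms from its resting
#' state (or a supplied state), with an optional rectangular somatic current
#' pulse and an optional list of synaptic events onto the dendrite.
#'
#' @param params a [pr_neuron_params()] object
#' @param t_total simulated time (ms)
#' @param I_amp,I_onset,I_dur somatic pulse amplitude (nA), onset and
#'   duration (ms)
#' @param events list of `list(spike_time =, syn =)` synaptic events
#' @param state0 optional initial state (shifted convention); defaults to the
#'   settled resting state
#' @param dt integration step (ms)
#' @param return_trace record the full voltage traces?
#' @return list with `count`, `first_spike`, `spike_times`, final `state`,
#'   and (if requested) `time`, `vs`, `vd` with voltages in absolute mV
#' @export
simulate_pr_neuron <- function(params, t_total = .PR_WINDOW, I_amp = 0,
                               I_onset = 0, I_dur = 0, events = list(),
                               state0 = NULL, dt = .PR_DT,
                               return_trace = TRUE) {
  if (!is.finite(dt) || dt <= 0 || dt > 0.1)
    stop("dt must be in (0, 0.1] ms")
  if (is.null(state0)) state0 <- pr_resting_state(params, dt)
  res <- pr_simulate_cpp(.pr_param_vector(params), state0, dt, t_total,
                         .soma_current_density(I_amp, params), I_onset, I_dur,
                         .events_matrix(events, params), .PR_REFRACTORY,
                         return_trace)
  if (return_trace) {
    res$vs <- res$vs + params$E_L
    res$vd <- res$vd + params$E_L
  }
  res
}

#' Advance a Pinsky-Rinzel neuron by one step (reference implementation)
#'
#' A pure-R Heun step of the coupled soma/dendrite equations with externally
#' supplied somatic and dendritic (synaptic) currents, used as the readable
#' reference against which the compiled integrator is checked.
#'
#' @param state named list or vector: `Vs`, `Vd` (absolute mV), `h`, `n`,
#'   `s`, `c`, `q` in `[0,1]`, `Ca >= 0`, and `t` (ms)
#' @param params a [pr_neuron_params()] object
#' @param I_s somatic injected current (nA)
#' @param I_syn dendritic synaptic current (nA, depolarizing positive)
#' @param dt step (ms), must be in (0, 0.1]
#' @return the advanced state (same layout, `t` advanced by `dt`)
#' @export
step_pr_neuron <- function(state, params, I_s = 0, I_syn = 0, dt = .PR_DT) {
  if (!is.finite(dt) || dt <= 0 || dt > 0.1)
    stop("dt must be in (0, 0.1] ms")
  st <- as.list(state)
  gates <- unlist(st[c("h", "n", "s", "c", "q")])
  if (any(gates < 0 | gates > 1)) stop("gating variables must be in [0,1]")
  if (st$Ca < 0) stop("Ca must be >= 0")
  is_dens <- .soma_current_density(I_s, params)
  isyn_dens <- I_syn * 1e-3 /
    ((1 - params$p) * pi * (params$diameter * 1e-4)^2)
  y <- c(st$Vs - params$E_L, st$Vd - params$E_L, st$h, st$n, st$s, st$c,
         st$q, st$Ca)
  k1 <- .pr_deriv_r(y, params, is_dens, isyn_dens)
  y1 <- .clamp_state(y + dt * k1)
  k2 <- .pr_deriv_r(y1, params, is_dens, isyn_dens)
  y2 <- .clamp_state(y + dt * (k1 + k2) / 2)
  if (abs(y2[1]) > 500 || abs(y2[2]) > 500)
    stop(sprintf("pr integration diverged at t = %g ms", st$t + dt))
  list(Vs = y2[1] + params$E_L, Vd = y2[2] + params$E_L, h = y2[3],
       n = y2[4], s = y2[5], c = y2[6], q = y2[7], Ca = y2[8],
       t = st$t + dt)
}

.clamp_state <- function(y) {
  y[3:7] <- pmin(pmax(y[3:7], 0), 1)
  y[8] <- max(y[8], 0)
  y
}

# rate functions, shifted convention (leak reversal at 0)
.vtrap <- function(x, k) ifelse(abs(x / k) < 1e-6,
                                k * (1 - x / (2 * k)),
                                x / (exp(x / k) - 1))

.pr_deriv_r <- function(y, params, is_dens, isyn_dens) {
  Vs <- y[1]; Vd <- y[2]; h <- y[3]; n <- y[4]; s <- y[5]; cc <- y[6]
  q <- y[7]; Ca <- y[8]
  VNa <- 120; VCa <- 140; VK <- -15
  vm <- Vs - params$na_shift
  am <- 0.32 * .vtrap(13.1 - vm, 4); bm <- 0.28 * .vtrap(vm - 40.1, 5)
  minf <- am / (am + bm)
  ah <- 0.128 * exp((17 - Vs) / 18); bh <- 4 / (1 + exp((40 - Vs) / 5))
  an <- 0.016 * .vtrap(35.1 - Vs, 5); bn <- 0.25 * exp(0.5 - 0.025 * Vs)
  as_ <- 1.6 / (1 + exp(-0.072 * (Vd - 65)))
  bs <- 0.02 * .vtrap(Vd - 51.1, 5)
  ac <- if (Vd <= 50) exp((Vd - 10) / 11 - (Vd - 6.5) / 27) / 18.975 else
    2 * exp((6.5 - Vd) / 27)
  bc <- if (Vd <= 50) 2 * exp((6.5 - Vd) / 27) - ac else 0
  aq <- min(2e-5 * Ca, 0.01); bq <- 0.001
  chi <- min(Ca / 250, 1)
  ICa <- params$g_Ca * s^2 * (Vd - VCa)
  dVs <- (-params$g_L * Vs - params$g_Na * minf^2 * h * (Vs - VNa) -
            params$g_DR * n * (Vs - VK) +
            params$g_c * (Vd - Vs) / params$p + is_dens) / params$cm
  dVd <- (-params$g_L * Vd - ICa - params$g_AHP * q * (Vd - VK) -
            params$g_C * cc * chi * (Vd - VK) +
            params$g_c * (Vs - Vd) / (1 - params$p) + isyn_dens) / params$cm
  c(dVs, dVd,
    ah * (1 - h) - bh * h,
    an * (1 - n) - bn * n,
    as_ * (1 - s) - bs * s,
    ac * (1 - cc) - bc * cc,
    aq * (1 - q) - bq * q,
    -0.13 * ICa - 0.075 * Ca)
}

#' Detect spikes in a somatic voltage trace
#'
#' A spike is a strict upward crossing of the threshold, with a refractory
#' guard so one action potential is never counted twice.
#'
#' @param vs_trace somatic voltage trace (mV), sampled every `dt`
#' @param dt sample interval (ms)
#' @param threshold spike threshold (mV, default 0)
#' @param window observation window (ms); samples beyond it are ignored
#' @param refractory minimum separation between counted spikes (ms)
#' @return list with `binary` (0/1: any spike in the window), `count`, and
#'   `times` (ms of each counted crossing)
#' @export
detect_spikes <- function(vs_trace, dt, threshold = 0, window = .PR_WINDOW,
                          refractory = .PR_REFRACTORY) {
  if (length(vs_trace) < 2) stop("trace must contain at least two samples")
  n <- min(length(vs_trace), floor(window / dt) + 1)
  v <- vs_trace[seq_len(n)]
  cross <- which(v[-1] > threshold & v[-length(v)] <= threshold)
  times <- cross * dt    # time of the sample just after the crossing
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last > refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times <- times[keep]
  list(binary = as.integer(length(times) >= 1), count = length(times),
       times = times)
}

#' Calibrate the single-spike input pulse
#'
#' Finds the smallest amplitude of a rectangular somatic current pulse (5 ms
#' by default) that makes the neuron fire exactly one spike within the
#' observation window. This calibrated pulse stands in for the light-evoked
#' (ChR2) current used to drive input neurons.
#'
#' @param params a [pr_neuron_params()] object
#' @param pulse_duration pulse length (ms)
#' @param bracket amplitude search bracket (nA)
#' @param tol bisection tolerance on the amplitude (nA)
#' @param dt,window integration step and observation window (ms)
#' @return list with `amplitude` (nA), `spike_time` (ms of the evoked spike)
#'   and `count` (always 1)
#' @export
calibrate_single_spike_current <- function(params, pulse_duration = 5,
                                           bracket = c(0.005, 20),
                                           tol = 1e-4, dt = .PR_DT,
                                           window = .PR_WINDOW) {
  key <- paste0("calib|", pulse_duration, "|", .param_key(params, dt))
  if (!is.null(.lnn_cache[[key]])) return(.lnn_cache[[key]])
  count_at <- function(a) {
    simulate_pr_neuron(params, t_total = window, I_amp = a, I_onset = 0,
                       I_dur = pulse_duration, dt = dt,
                       return_trace = FALSE)$count
  }
  if (count_at(bracket[1]) != 0)
    stop("calibration failure: lower bracket already evokes a spike")
  # spike count is not monotone in amplitude (bursting near rheobase,
  # depolarization block at strong drive): first locate the lowest firing
  # amplitude on a geometric grid, then bisect
  lo <- bracket[1]; hi <- NA
  a <- bracket[1]
  while (a < bracket[2]) {
    a <- min(a * 1.25, bracket[2])
    if (count_at(a) >= 1) { hi <- a; break }
    lo <- a
  }
  if (is.na(hi))
    stop("calibration failure: no spike in amplitude bracket")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count_at(mid) >= 1) hi <- mid else lo <- mid
  }
  if (count_at(hi) != 1) {
    # minimal firing amplitude evokes a burst; walk up to the single-spike
    # regime and bisect the burst/single boundary
    b_lo <- hi; b_hi <- NA
    a <- hi
    while (a < bracket[2]) {
      a <- min(a * 1.1, bracket[2])
      cnt <- count_at(a)
      if (cnt == 1) { b_hi <- a; break }
      if (cnt == 0)
        stop("calibration failure: response vanished before reaching the single-spike regime")
      b_lo <- a
    }
    if (is.na(b_hi))
      stop("calibration failure: no single-spike amplitude in bracket")
    while (b_hi - b_lo > tol) {
      mid <- (b_lo + b_hi) / 2
      if (count_at(mid) == 1) b_hi <- mid else b_lo <- mid
    }
    hi <- b_hi
  }
  sim <- simulate_pr_neuron(params, t_total = window, I_amp = hi,
                            I_onset = 0, I_dur = pulse_duration, dt = dt,
                            return_trace = FALSE)
  out <- list(amplitude = hi, spike_time = sim$first_spike, count = sim$count)
  .lnn_cache[[key]] <- out
  out
}

#' Spike count versus sustained injected current
#'
#' Characterization sweep: number of spikes in the observation window under a
#' sustained somatic current, for a grid of amplitudes.
#'
#' @param params a [pr_neuron_params()] object
#' @param amplitudes current amplitudes (nA)
#' @param dt,window integration step and observation window (ms)
#' @return data.frame with `amplitude_nA` and `count`
#' @export
characterize_fi <- function(params, amplitudes = seq(0, 0.3, by = 0.025),
                            dt = .PR_DT, window = .PR_WINDOW) {
  counts <- vapply(amplitudes, function(a)
    simulate_pr_neuron(params, t_total = window, I_amp = a, I_onset = 0,
                       I_dur = window, dt = dt,
                       return_trace = FALSE)$count, numeric(1))
  data.frame(amplitude_nA = amplitudes, count = counts)
}

#' Export a simulated trace as CSV
#'
#' @param sim result of [simulate_pr_neuron()] with traces
#' @param file output path
#' @return the path, invisibly
#' @export
export_trace <- function(sim, file) {
  if (is.null(sim$time)) stop("simulation was run without traces")
  write.csv(data.frame(time_ms = sim$time, vs_mV = sim$vs, vd_mV = sim$vd),
            file, row.names = FALSE)
  invisible(file)
}

#' Export spike rasters as JSON
#'
#' @param rasters list (one entry per neuron) of spike-time vectors (ms)
#' @param file output path
#' @return the path, invisibly
#' @export
export_raster <- function(rasters, file) {
  jsonlite::write_json(rasters, file, digits = NA)
  invisible(file)
}
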