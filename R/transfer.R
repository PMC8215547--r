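# The minPreNum bridging experiment: measure, on the biophysical layer, the
# minimum number of simultaneously activated pre-synaptic neurons needed to
# fire each fitted post-synaptic neuron, then convert the observed
# variability into the normal threshold and weight distributions used by the
# computational model.

.MINPRE_MAX <- 20

#' Run one minPreNum trial on the biophysical model
#'
#' Draws (with repetition) a sequence of pre-synaptic neurons and synapses,
#' grows the pre-synaptic set one neuron at a time, stimulates all members
#' simultaneously with their calibrated single-spike pulses, and returns the
#' smallest set size at which the post-synaptic neuron fires.
#'
#' @param post_params [pr_neuron_params()] of the post-synaptic neuron
#' @param neuron_pool list of candidate pre-synaptic [pr_neuron_params()]
#' @param synapse_pool list of candidate [alpha_synapse_params()]
#' @param max_k largest set size tried before censoring
#' @param dt,window integration step and observation window (ms)
#' @return the minPreNum (integer in 1..max_k), or `NA` if censored
#' @export
run_minprenum_trial <- function(post_params, neuron_pool = fitted_neurons(),
                                synapse_pool = fitted_synapses(),
                                max_k = .MINPRE_MAX, dt = .PR_DT,
                                window = .PR_WINDOW) {
  pre_n <- sample.int(length(neuron_pool), max_k, replace = TRUE)
  pre_s <- sample.int(length(synapse_pool), max_k, replace = TRUE)
  spike_t <- vapply(neuron_pool, function(p)
    calibrate_single_spike_current(p, dt = dt, window = window)$spike_time,
    numeric(1))
  prm <- .pr_param_vector(post_params)
  st0 <- pr_resting_state(post_params, dt)
  ev <- matrix(0, max_k, 3)
  for (j in seq_len(max_k)) {
    syn <- synapse_pool[[pre_s[j]]]
    ev[j, ] <- c(spike_t[pre_n[j]] + syn$delay,
                 .dend_gdens(syn$gsyn, post_params), syn$tau)
  }
  for (k in seq_len(max_k)) {
    if (pr_fires_cpp(prm, st0, dt, window, ev[seq_len(k), , drop = FALSE],
                     .PR_REFRACTORY))
      return(k)
  }
  NA_integer_
}

.new_curve <- function(label, values, max_k = .MINPRE_MAX) {
  counts <- tabulate(values[!is.na(values)], nbins = max_k)
  names(counts) <- as.character(seq_len(max_k))
  censored <- sum(is.na(values))
  unc <- values[!is.na(values)]
  structure(list(post_neuron_label = label, counts = counts,
                 censored = censored, n_trials = length(values),
                 expectation = if (length(unc)) mean(unc) else NA_real_),
            class = "minprenum_curve")
}

#' @export
print.minprenum_curve <- function(x, ...) {
  cat(sprintf("minPreNum curve (post-neuron %s): %d trials, %d censored, E = %.2f\n",
              x$post_neuron_label, x$n_trials, x$censored, x$expectation))
  invisible(x)
}

#' The minPreNum experiment over the nine fitted post-synaptic neurons
#'
#' Repeats [run_minprenum_trial()] `n_trials` times, cycling the
#' post-synaptic neuron sequentially through the fitted cells, and returns
#' one minPreNum histogram per post-neuron.
#'
#' @param n_trials total number of trials (cycled over the post-neurons)
#' @param neuron_pool,synapse_pool candidate pre-synaptic pools
#' @param max_k censoring bound on the set size
#' @param dt,window integration step and observation window (ms)
#' @return list of `minprenum_curve` objects, one per pool neuron
#' @export
minprenum_experiment <- function(n_trials = 1000,
                                 neuron_pool = fitted_neurons(),
                                 synapse_pool = fitted_synapses(),
                                 max_k = .MINPRE_MAX, dt = .PR_DT,
                                 window = .PR_WINDOW) {
  stopifnot(n_trials >= 1)
  n_post <- length(neuron_pool)
  vals <- replicate(n_post, integer(0), simplify = FALSE)
  for (tr in seq_len(n_trials)) {
    post <- ((tr - 1) %% n_post) + 1
    mp <- run_minprenum_trial(neuron_pool[[post]], neuron_pool, synapse_pool,
                              max_k = max_k, dt = dt, window = window)
    vals[[post]] <- c(vals[[post]], mp)
  }
  lapply(seq_len(n_post), function(i)
    .new_curve(neuron_pool[[i]]$label, vals[[i]], max_k))
}

.curve_expectations <- function(curves) {
  ex <- vapply(curves, `[[`, numeric(1), "expectation")
  if (anyNA(ex))
    stop("estimation error: some curves have no uncensored trials")
  ex
}

# population (n-denominator) standard deviation
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Derive the threshold distribution from minPreNum expectations
#'
#' The per-neuron expected minPreNum, scaled by the mean maximal synaptic
#' conductance, estimates each neuron's firing threshold in weight units;
#' mean and standard deviation across the nine neurons give the normal
#' threshold distribution of the computational model.
#'
#' @param curves list of `minprenum_curve` objects
#' @param mean_gsyn mean maximal synapse conductance (uS) used as the weight
#'   scale; defaults to the mean of the fitted synapse table
#' @return a [gaussian_spec()] with units `"threshold"`
#' @export
estimate_threshold_dist <- function(curves, mean_gsyn = mean_fitted_gsyn()) {
  ex <- .curve_expectations(curves)
  gaussian_spec(mean(ex) * mean_gsyn, .pop_sd(ex) * mean_gsyn, "threshold")
}

#' Peak-align and average minPreNum curves
#'
#' Normalizes each histogram, shifts it so its mode (smallest count on ties)
#' sits at a common origin, averages bin-wise over the aligned support, and
#' renormalizes.
#'
#' @param curves list of `minprenum_curve` objects
#' @return list with `offsets` (bin positions relative to the peak),
#'   `density` (averaged, renormalized histogram, zero tails trimmed) and
#'   `center` (mean of the individual curve modes, anchoring the averaged
#'   curve back on the absolute minPreNum axis)
#' @export
align_and_average <- function(curves) {
  aligned <- lapply(curves, function(cu) {
    cnt <- cu$counts
    if (sum(cnt) == 0) stop("cannot align a curve with no uncensored trials")
    dens <- cnt / sum(cnt)
    mode_at <- which.max(dens)   # ties: smallest count
    list(off = seq_along(dens) - mode_at, dens = dens, mode = mode_at)
  })
  lo <- min(vapply(aligned, function(a) min(a$off), numeric(1)))
  hi <- max(vapply(aligned, function(a) max(a$off), numeric(1)))
  offsets <- lo:hi
  acc <- matrix(0, length(curves), length(offsets))
  for (i in seq_along(aligned))
    acc[i, match(aligned[[i]]$off, offsets)] <- aligned[[i]]$dens
  avg <- colMeans(acc)
  keep <- range(which(avg > 0))
  offsets <- offsets[keep[1]:keep[2]]
  avg <- avg[keep[1]:keep[2]]
  list(offsets = offsets, density = avg / sum(avg),
       center = mean(vapply(aligned, `[[`, numeric(1), "mode")))
}

# non-negative normal draws by rejection (the no-negative-weight rule)
.rtrunc0 <- function(n, mean, sd) {
  if (sd == 0) {
    if (mean < 0) stop("degenerate weight distribution entirely below zero")
    return(rep(mean, n))
  }
  if (stats::pnorm(0, mean, sd, lower.tail = FALSE) < 1e-6)
    stop("weight distribution has essentially no mass above zero")
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' minPreNum experiment on the computational model
#'
#' Per trial, draws non-negative weights sequentially from the weight
#' distribution and reports the smallest count whose cumulative sum exceeds
#' the threshold (censored above `max_k`).
#'
#' @param vth firing threshold (> 0)
#' @param wspec a [gaussian_spec()] for the weights (truncated at zero)
#' @param n_trials number of trials
#' @param max_k censoring bound
#' @return a `minprenum_curve`
#' @export
computational_minprenum <- function(vth, wspec, n_trials = 1000,
                                    max_k = .MINPRE_MAX) {
  stopifnot(vth > 0)
  W <- matrix(.rtrunc0(n_trials * max_k, wspec$mean, wspec$sd),
              n_trials, max_k)
  cum <- t(apply(W, 1, cumsum))
  first <- apply(cum > vth, 1, function(z) if (any(z)) which(z)[1] else NA)
  .new_curve("computational", as.integer(first), max_k)
}

#' Fit the computational weight distribution to an averaged minPreNum curve
#'
#' Grid search over (mean, sd) of the weight distribution: for each grid
#' point the computational minPreNum experiment is simulated and compared,
#' by sum of squared differences on the absolute minPreNum axis, with the
#' averaged target curve re-anchored at the mean mode of the curves it was
#' averaged from (peak alignment alone would discard the location
#' information that identifies the weight mean).
#'
#' @param target output of [align_and_average()]
#' @param vth post-synaptic threshold used in the computational experiment
#' @param mean_grid,sd_grid candidate values (weight units)
#' @param n_trials trials per grid point
#' @param max_k censoring bound
#' @return list with `spec` (the best [gaussian_spec()]), `score` (its SSE)
#'   and `grid` (a data.frame of all grid points and scores)
#' @export
fit_weight_distribution <- function(target, vth = 0.0066,
                                    mean_grid = seq(4e-4, 16e-4, by = 1e-4),
                                    sd_grid = seq(0, 16e-4, by = 1e-4),
                                    n_trials = 1000, max_k = .MINPRE_MAX) {
  # target density on the absolute axis, anchored at the mean mode
  tg <- numeric(max_k)
  pos <- round(target$center) + target$offsets
  ok <- pos >= 1 & pos <= max_k
  tg[pos[ok]] <- target$density[ok]
  score_one <- function(mu, sg) {
    cu <- computational_minprenum(vth, gaussian_spec(mu, sg, "weight"),
                                  n_trials, max_k)
    if (sum(cu$counts) == 0) return(Inf)
    cm <- cu$counts / sum(cu$counts)
    sum((tg - cm)^2)
  }
  grid <- expand.grid(mean = mean_grid, sd = sd_grid)
  grid$score <- mapply(function(mu, sg) score_one(mu, sg),
                       grid$mean, grid$sd)
  best <- grid[which.min(grid$score), ]
  list(spec = gaussian_spec(best$mean, best$sd, "weight"),
       score = best$score, grid = grid)
}
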