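# Experiment orchestration: presets for the standard simulation
# configurations, the biophysical-vs-computational comparison, optimization
# sweeps, the variation study, and result reporting.

#' Experiment presets
#'
#' Returns the configuration of one of the standard experiment families:
#' \describe{
#'   \item{comparison_fix}{100-image comparison, variance-zero biological
#'     layer (one fitted cell and synapse), lr 1e-4 / 1e-2, adaptive
#'     pre-processing to Nin_b = 20.}
#'   \item{comparison_var}{as above with full neuron/synapse variation:
#'     Vth N(0.0066, 0.0019), initial weights N(0.0009, 0.0009).}
#'   \item{optimization}{1000-image optimization runs: lr 5e-6 / 0.008,
#'     hardware init N(0.0009, 0.03), estimator range (0, 0.0075),
#'     adaptive learning rate, Nin_b = 20.}
#'   \item{variation}{variation study: as optimization with Nin_b = 26.}
#' }
#' The training set equals the testing set in the comparison and
#' optimization presets (`train_eq_test`), matching the small-dataset
#' protocol these presets reproduce.
#'
#' @param name preset name
#' @return list of class `experiment_config`
#' @export
experiment_preset <- function(name = c("comparison_fix", "comparison_var",
                                       "optimization", "variation")) {
  name <- match.arg(name)
  base <- list(
    preset = name, n_in = 196, n_hidden = 100, n_out = 10, sparsity = 0.4,
    pool = pool_config(2, 2, 0), train_eq_test = TRUE,
    vth_spec = gaussian_spec(0.0066, 0.0019, "threshold"),
    w_spec = gaussian_spec(0.0009, 0.0009, "weight"),
    clamp_lo = 0.5, clamp_hi = 2, epochs = 100)
  cfg <- switch(name,
    comparison_fix = c(base, list(
      n_images = 100, target_nin_b = 20, fixed_cell = 1, fixed_synapse = 1,
      hw_spec = gaussian_spec(0.0009, 0.0009, "weight"),
      train = train_config(lr_bio = 1e-4, lr_hw = 1e-2, est_range = NULL,
                           epochs = 100))),
    comparison_var = c(base, list(
      n_images = 100, target_nin_b = 20,
      hw_spec = gaussian_spec(0.0009, 0.0009, "weight"),
      train = train_config(lr_bio = 1e-4, lr_hw = 1e-2, est_range = NULL,
                           epochs = 100))),
    optimization = c(base, list(
      n_images = 1000, target_nin_b = 20,
      hw_spec = gaussian_spec(0.0009, 0.03, "weight"),
      train = train_config(lr_bio = 5e-6, lr_hw = 0.1, est_range = c(0, 0.0075),
                           epochs = 100, adaptive_lr = TRUE,
                           lr_decay = 0.1))),
    variation = c(base, list(
      n_images = 1000, target_nin_b = 26,
      hw_spec = gaussian_spec(0.0009, 0.03, "weight"),
      train = train_config(lr_bio = 1e-5, lr_hw = 0.1, est_range = c(0, 0.0075),
                           epochs = 100, adaptive_lr = TRUE,
                           lr_decay = 0.1))))
  structure(cfg, class = "experiment_config")
}

#' Match the computational threshold to a biophysical neuron
#'
#' Finds the deterministic biophysical minPreNum k* of a post-synaptic
#' neuron driven by identical simultaneous synapses of weight `w`, and
#' returns the threshold `(k* - 0.5) w`, which gives the computational model
#' the same minPreNum.
#'
#' @param post_params post-synaptic [pr_neuron_params()]
#' @param syn an [alpha_synapse_params()] giving kinetics and weight
#' @param spike_time pre-synaptic spike time (ms)
#' @param max_k search bound
#' @param dt,window integration step and window
#' @return list with `vth` and `k`
#' @export
match_vth <- function(post_params, syn, spike_time, max_k = 60,
                      dt = .PR_DT, window = .PR_WINDOW) {
  prm <- .pr_param_vector(post_params)
  st0 <- pr_resting_state(post_params, dt)
  gd <- .dend_gdens(syn$gsyn, post_params)
  for (k in seq_len(max_k)) {
    ev <- matrix(c(spike_time + syn$delay, k * gd, syn$tau), 1, 3)
    if (pr_fires_cpp(prm, st0, dt, window, ev, .PR_REFRACTORY))
      return(list(vth = (k - 0.5) * syn$gsyn, k = k))
  }
  stop("post-neuron cannot be fired within the search bound")
}

# build matched computational layers + biophysical network for a comparison
.comparison_setup <- function(cfg, seed) {
  set.seed(seed)
  ds <- generate_synthetic_digits(cfg$n_images, seed = seed)
  pp <- preprocess_dataset(ds, adpp_config(cfg$target_nin_b), cfg$pool)
  neurons <- fitted_neurons(); synapses <- fitted_synapses()
  n_in <- cfg$n_in; n_hidden <- cfg$n_hidden
  mask <- matrix(rbinom(n_in * n_hidden, 1, cfg$sparsity), n_in, n_hidden)
  fixed <- !is.null(cfg$fixed_cell)
  if (fixed) {
    cell <- neurons[[cfg$fixed_cell]]
    syn <- synapses[[cfg$fixed_synapse]]
    input_params <- rep(list(cell), n_in)
    hidden_params <- rep(list(cell), n_hidden)
    W <- matrix(syn$gsyn, n_in, n_hidden) * mask
    tau <- syn$tau; delay <- syn$delay
    cal <- calibrate_single_spike_current(cell)
    vth <- rep(match_vth(cell, syn, cal$spike_time)$vth, n_hidden)
  } else {
    input_params <- neurons[sample.int(9, n_in, replace = TRUE)]
    hidden_params <- neurons[sample.int(9, n_hidden, replace = TRUE)]
    syn_draw <- synapses[sample.int(12, n_in * n_hidden, replace = TRUE)]
    W <- matrix(.rtrunc0(n_in * n_hidden, cfg$w_spec$mean, cfg$w_spec$sd),
                n_in, n_hidden) * mask
    tau <- matrix(vapply(syn_draw, `[[`, numeric(1), "tau"), n_in, n_hidden)
    delay <- matrix(vapply(syn_draw, `[[`, numeric(1), "delay"),
                    n_in, n_hidden)
    vth <- .rtrunc0(n_hidden, cfg$vth_spec$mean, cfg$vth_spec$sd)
  }
  hw <- matrix(rnorm(n_hidden * cfg$n_out, cfg$hw_spec$mean,
                     cfg$hw_spec$sd), n_hidden, cfg$n_out)
  layers <- structure(list(
    bio = list(mask = mask, W = W, W0 = W, vth = vth,
               clamp_lo = cfg$clamp_lo, clamp_hi = cfg$clamp_hi),
    hw = list(W = hw)), class = "lnn_layers")
  net <- biophys_network(input_params, hidden_params, mask, gsyn = W,
                         tau = tau, delay = delay)
  net <- calibrate_network(net)
  list(pp = pp, layers = layers, net = net)
}

#' Compare the biophysical and computational backends
#'
#' Runs the identical training loop twice from identical initialization:
#' once with the threshold-layer forward pass (computational) and once with
#' the hidden layer simulated biophysically (the computational weights map
#' one-to-one onto synaptic conductances). Reports per-epoch accuracies of
#' both backends and their maximum absolute difference.
#'
#' @param cfg an [experiment_preset()] (one of the comparison presets)
#' @param seed RNG seed; the same seed drives both backends
#' @param epochs overrides the preset epoch count
#' @param method forward method for the biophysical backend (see
#'   [biophysical_forward()])
#' @return list of class `comparison_result`: `computational` and
#'   `biophysical` history data.frames, `final_diff`, `max_diff`
#' @export
run_comparison <- function(cfg = experiment_preset("comparison_fix"),
                           seed = 1, epochs = NULL,
                           method = c("auto", "full", "collapsed")) {
  method <- match.arg(method)
  tcfg <- cfg$train
  if (!is.null(epochs)) tcfg$epochs <- epochs
  setup <- .comparison_setup(cfg, seed)
  pp <- setup$pp
  set.seed(seed + 1)
  comp <- train_network(pp$X, pp$y, setup$layers, tcfg)
  set.seed(seed + 1)
  bio <- train_network(pp$X, pp$y, setup$layers, tcfg,
                       hidden_fn = function(Xb, layers) {
                         net <- setup$net
                         net$gsyn <- layers$bio$W
                         biophysical_forward(Xb, net, method = method)
                       })
  dif <- abs(comp$history$train_acc - bio$history$train_acc)
  structure(list(computational = comp$history, biophysical = bio$history,
                 final_diff = dif[length(dif)], max_diff = max(dif),
                 seed = seed),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  nc <- nrow(x$computational)
  cat(sprintf("backend comparison (%d epochs, seed %d)\n", nc, x$seed))
  cat(sprintf("  final train acc: computational %.3f, biophysical %.3f\n",
              x$computational$train_acc[nc], x$biophysical$train_acc[nc]))
  cat(sprintf("  max per-epoch |difference| %.3f\n", x$max_diff))
  invisible(x)
}

# one computational training run for a sweep/variation cell
.single_run <- function(cfg, seed, epochs = NULL) {
  set.seed(seed)
  ds <- generate_synthetic_digits(cfg$n_images, seed = seed)
  pp <- preprocess_dataset(ds, adpp_config(cfg$target_nin_b), cfg$pool)
  layers <- init_layers(cfg$n_in, cfg$n_hidden, cfg$n_out, cfg$sparsity,
                        cfg$vth_spec, cfg$w_spec, cfg$hw_spec,
                        cfg$clamp_lo, cfg$clamp_hi)
  tcfg <- cfg$train
  if (!is.null(epochs)) tcfg$epochs <- epochs
  res <- train_network(pp$X, pp$y, layers, tcfg)
  hist <- res$history
  n <- nrow(hist)
  b <- res$layers$bio
  meanW <- mean(b$W[b$mask == 1])
  data.frame(seed = seed,
             train_acc = hist$train_acc[n], test_acc = hist$test_acc[n],
             nf_hidden = hist$nf_hidden[n],
             f = f_statistic(mean(b$mask), pp$achieved, meanW,
                             mean(b$vth)))
}

#' Sweep one configuration axis
#'
#' Trains the computational model once per value of the chosen axis, all
#' else fixed, under a common seed policy, recording final accuracy, hidden
#' firing fraction and the f statistic.
#'
#' @param cfg base [experiment_preset()]
#' @param axis one of "sparsity", "nin_b", "init_w", "est_range",
#'   "vth_scale"
#' @param values vector of axis values (for "init_w" a vector of means with
#'   sd = mean; for "est_range" a list of ranges; for "vth_scale"
#'   multiplicative factors on the threshold distribution)
#' @param seed common RNG seed
#' @param epochs overrides the preset epoch count
#' @return `result_table` data.frame with one row per value
#' @export
run_sweep <- function(cfg = experiment_preset("optimization"),
                      axis = c("sparsity", "nin_b", "init_w", "est_range",
                               "vth_scale"),
                      values, seed = 1, epochs = NULL) {
  axis <- match.arg(axis)
  stopifnot(length(values) >= 1)
  rows <- lapply(seq_along(values), function(i) {
    v <- if (is.list(values)) values[[i]] else values[i]
    cfg_i <- cfg
    switch(axis,
           sparsity = { cfg_i$sparsity <- v },
           nin_b = { cfg_i$target_nin_b <- v },
           init_w = { cfg_i$w_spec <- gaussian_spec(v, v, "weight") },
           est_range = { cfg_i$train$est_range <- v },
           vth_scale = { cfg_i$vth_spec <-
             gaussian_spec(cfg$vth_spec$mean * v, cfg$vth_spec$sd * v,
                           "threshold") })
    out <- .single_run(cfg_i, seed, epochs)
    out$axis <- axis
    out$value <- if (is.list(values)) paste(v, collapse = ":") else v
    out
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("result_table", class(tab))
  tab
}

#' Variation study
#'
#' One-axis-at-a-time grids over threshold variation, weight variation,
#' weight-clamp ranges and hidden-layer sizes, each cell aggregated over
#' several seeds.
#'
#' @param cfg base [experiment_preset()]
#' @param vth_stds,w_stds,clamp_ranges,hidden_sizes grids (clamp ranges as a
#'   list of `c(lo, hi)` multiplicative bounds)
#' @param n_seeds seeds per cell
#' @param epochs overrides the preset epoch count
#' @return `result_table` data.frame with mean and sd of final test accuracy
#'   per cell
#' @export
run_variation_study <- function(cfg = experiment_preset("variation"),
                                vth_stds = NULL, w_stds = NULL,
                                clamp_ranges = NULL, hidden_sizes = NULL,
                                n_seeds = 3, epochs = NULL) {
  cells <- list()
  add <- function(axis, value, mod) {
    cells[[length(cells) + 1]] <<- list(axis = axis, value = value,
                                        mod = mod)
  }
  for (v in vth_stds)
    add("vth_std", v, local({ vv <- v; function(cf) {
      cf$vth_spec <- gaussian_spec(cf$vth_spec$mean, vv, "threshold"); cf }}))
  for (v in w_stds)
    add("w_std", v, local({ vv <- v; function(cf) {
      cf$w_spec <- gaussian_spec(cf$w_spec$mean, vv, "weight"); cf }}))
  for (v in clamp_ranges %||% list())
    add("clamp", paste(v, collapse = ":"), local({ vv <- v; function(cf) {
      cf$clamp_lo <- vv[1]; cf$clamp_hi <- vv[2]; cf }}))
  for (v in hidden_sizes)
    add("n_hidden", v, local({ vv <- v; function(cf) {
      cf$n_hidden <- vv; cf }}))
  rows <- lapply(cells, function(cell) {
    accs <- vapply(seq_len(n_seeds), function(s)
      .single_run(cell$mod(cfg), seed = s, epochs = epochs)$test_acc,
      numeric(1))
    data.frame(axis = cell$axis, value = cell$value,
               mean_acc = mean(accs), sd_acc = stats::sd(accs),
               n_seeds = n_seeds)
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("result_table", class(tab))
  tab
}

# stable config hash (md5 of the version-2 serialization)
.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(cfg, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Write experiment results to disk
#'
#' Writes each table as CSV and the whole collection as one JSON document;
#' I/O failures propagate.
#'
#' @param tables named list of data.frames (e.g. sweep results, training
#'   histories)
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
report_results <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "results.json")
  jsonlite::write_json(tables, jp, digits = NA, dataframe = "rows")
  invisible(c(paths, jp))
}
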