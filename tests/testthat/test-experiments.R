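# Experiment orchestration: presets, backend comparison, sweeps, the
# variation study, and reporting.

test_that("every standard preset is expressible through the config", {
  for (nm in c("comparison_fix", "comparison_var", "optimization",
               "variation")) {
    cfg <- experiment_preset(nm)
    expect_s3_class(cfg, "experiment_config")
    expect_equal(cfg$n_in, 196)
    expect_equal(cfg$n_out, 10)
    expect_equal(cfg$sparsity, 0.4)
    expect_s3_class(cfg$train, "train_config")
    expect_true(cfg$train_eq_test)
    expect_equal(compressed_size(28, cfg$pool)^2, cfg$n_in)
  }
  expect_equal(experiment_preset("optimization")$train$est_range,
               c(0, 0.0075))
  expect_equal(experiment_preset("variation")$target_nin_b, 26)
  expect_equal(experiment_preset("comparison_fix")$train$lr_bio, 1e-4)
})

test_that("threshold matching reproduces the biophysical minPreNum", {
  cell <- cells()[[1]]
  syn <- syns()[[1]]
  cal <- calibrate_single_spike_current(cell)
  m <- match_vth(cell, syn, cal$spike_time)
  # computational minPreNum at that threshold equals k for equal weights
  expect_equal(floor(m$vth / syn$gsyn) + 1, m$k)
  # and the biophysical neuron indeed fires at k but not k - 1
  gd <- lnnlab:::.dend_gdens(syn$gsyn, cell)
  prm <- lnnlab:::.pr_param_vector(cell)
  st0 <- pr_resting_state(cell)
  fires_at <- function(k) lnnlab:::pr_fires_cpp(
    prm, st0, 0.025, 200,
    matrix(c(cal$spike_time + syn$delay, k * gd, syn$tau), 1, 3), 1)
  expect_true(fires_at(m$k))
  expect_false(fires_at(m$k - 1))
})

test_that("the comparison run is deterministic per seed", {
  cfg <- experiment_preset("comparison_fix")
  a <- run_comparison(cfg, seed = 5, epochs = 6)
  b <- run_comparison(cfg, seed = 5, epochs = 6)
  expect_identical(a$computational, b$computational)
  expect_identical(a$biophysical, b$biophysical)
})

test_that("backends closely match on the variance-zero comparison", {
  res <- run_comparison(experiment_preset("comparison_fix"), seed = 1,
                        epochs = 25)
  expect_lte(res$final_diff, 0.05)
})

test_that("backends stay close under full neuron and synapse variation", {
  cfg <- experiment_preset("comparison_var")
  cfg$n_images <- 30
  cfg$n_hidden <- 20
  res <- run_comparison(cfg, seed = 2, epochs = 3)
  # small run: only sanity-level agreement is asserted
  expect_lte(res$final_diff, 0.35)
  expect_true(all(res$biophysical$nf_hidden >= 0 &
                    res$biophysical$nf_hidden <= 1))
})

test_that("a one-value sweep equals a single run", {
  cfg <- experiment_preset("optimization")
  cfg$n_images <- 120
  tab <- run_sweep(cfg, axis = "sparsity", values = 0.4, seed = 3,
                   epochs = 5)
  single <- lnnlab:::.single_run(cfg, seed = 3, epochs = 5)
  expect_equal(tab$train_acc, single$train_acc)
  expect_equal(tab$nf_hidden, single$nf_hidden)
  expect_equal(nrow(tab), 1)
})

test_that("hidden firing grows with sparsity along a sweep", {
  cfg <- experiment_preset("optimization")
  cfg$n_images <- 120
  tab <- run_sweep(cfg, axis = "sparsity", values = c(0.1, 0.4, 0.8),
                   seed = 4, epochs = 4)
  expect_true(all(diff(tab$nf_hidden) > 0))
  # and the f statistic grows along with it
  expect_true(all(diff(tab$f) > 0))
})

test_that("variation study covers clamp and threshold grids", {
  cfg <- experiment_preset("variation")
  cfg$n_images <- 120
  tab <- run_variation_study(cfg, vth_stds = c(0, 0.0019),
                             clamp_ranges = list(c(1, 1), c(0.5, 2)),
                             n_seeds = 2, epochs = 6)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$mean_acc >= 0 & tab$mean_acc <= 1))
  # a frozen biological layer (clamp 1x-1x) still beats chance: the
  # hardware layer alone is a linear readout of random binary features
  frozen <- tab$mean_acc[tab$axis == "clamp" & tab$value == "1:1"]
  expect_gt(frozen, 0.15)
})

test_that("zero-variance thresholds reproduce the deterministic baseline", {
  cfg <- experiment_preset("variation")
  cfg$n_images <- 80
  cfg$vth_spec <- gaussian_spec(0.0066, 0, "threshold")
  a <- lnnlab:::.single_run(cfg, seed = 6, epochs = 4)
  b <- lnnlab:::.single_run(cfg, seed = 6, epochs = 4)
  expect_identical(a, b)
})

test_that("results report round-trips through CSV and JSON", {
  tab <- data.frame(axis = "sparsity", value = c(0.2, 0.4),
                    train_acc = c(0.5, 0.6))
  dir <- tempfile()
  paths <- report_results(list(sweep = tab), dir)
  back <- read.csv(file.path(dir, "sweep.csv"))
  expect_equal(back$train_acc, tab$train_acc)
  expect_true(file.exists(file.path(dir, "results.json")))
  # empty table still produces valid files
  report_results(list(empty = data.frame()), dir)
  expect_true(file.exists(file.path(dir, "empty.csv")))
})

test_that("config hashes are stable across identical configs", {
  cfg1 <- experiment_preset("optimization")
  cfg2 <- experiment_preset("optimization")
  expect_identical(lnnlab:::.config_hash(cfg1), lnnlab:::.config_hash(cfg2))
  cfg2$sparsity <- 0.2
  expect_false(identical(lnnlab:::.config_hash(cfg1),
                         lnnlab:::.config_hash(cfg2)))
})
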