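# Model transfer: the minPreNum experiment and the derivation of the
# threshold and weight distributions.

test_that("inflated synapses give minPreNum 1, vanishing ones censor", {
  post <- cells()[[1]]
  big <- lapply(syns(), function(s)
    alpha_synapse_params(s$gsyn * 100, s$tau, s$delay, s$label))
  tiny <- lapply(syns(), function(s)
    alpha_synapse_params(s$gsyn * 1e-4, s$tau, s$delay, s$label))
  set.seed(1)
  for (i in 1:3)
    expect_equal(run_minprenum_trial(post, cells(), big), 1L)
  for (i in 1:3)
    expect_true(is.na(run_minprenum_trial(post, cells(), tiny)))
})

test_that("trials cycle sequentially over the post-neurons", {
  set.seed(2)
  big <- lapply(syns(), function(s)
    alpha_synapse_params(s$gsyn * 100, s$tau, s$delay, s$label))
  curves <- minprenum_experiment(n_trials = 9, synapse_pool = big)
  expect_length(curves, 9)
  expect_true(all(vapply(curves, `[[`, numeric(1), "n_trials") == 1))
  # histogram sums to trial count
  for (cu in curves)
    expect_equal(sum(cu$counts) + cu$censored, cu$n_trials)
})

test_that("minPreNum histograms are consistent with their expectations", {
  curves <- minpre_curves()
  for (cu in curves) {
    expect_equal(sum(cu$counts) + cu$censored, cu$n_trials)
    if (sum(cu$counts) > 0) {
      ex <- sum(as.numeric(names(cu$counts)) * cu$counts) / sum(cu$counts)
      expect_equal(cu$expectation, ex)
      expect_gte(ex, 1); expect_lte(ex, 20)
    }
  }
})

test_that("threshold estimation is the exact linear transform", {
  # nine delta curves with known expectations
  ks <- c(5, 6, 7, 8, 8, 9, 10, 11, 12)
  curves <- lapply(ks, delta_curve)
  pop_sd <- sqrt(mean((ks - mean(ks))^2))
  est <- estimate_threshold_dist(curves, mean_gsyn = 0.0008)
  expect_equal(est$mean, mean(ks) * 0.0008)
  expect_equal(est$sd, pop_sd * 0.0008)
  # identity scaling returns the raw statistics
  est1 <- estimate_threshold_dist(curves, mean_gsyn = 1)
  expect_equal(est1$mean, mean(ks))
  # exact linearity in mean_gsyn
  est2 <- estimate_threshold_dist(curves, mean_gsyn = 0.0016)
  expect_equal(est2$mean, 2 * est$mean)
  expect_equal(est2$sd, 2 * est$sd)
  # identical expectations give sd zero
  expect_equal(estimate_threshold_dist(lapply(rep(7, 9), delta_curve))$sd, 0)
  # the printed example: expectations averaging 8.2 with sd 2.4 scale to
  # the N(0.0066, 0.0019) threshold distribution at mean gsyn 0.0008
  expect_equal(round(8.2 * 0.0008, 4), 0.0066)
  expect_equal(round(2.4 * 0.0008, 4), 0.0019)
})

test_that("peak alignment centers and averages histograms", {
  c1 <- delta_curve(5); c2 <- delta_curve(11)
  al <- align_and_average(list(c1, c2))
  expect_equal(sum(al$density), 1)
  expect_equal(al$density[al$offsets == 0], 1)  # single delta at origin
  # identical curves come back unchanged (re-centered)
  curves <- minpre_curves()
  one <- align_and_average(list(curves[[1]]))
  dens <- curves[[1]]$counts / sum(curves[[1]]$counts)
  expect_equal(sort(one$density[one$density > 0]),
               sort(unname(dens[dens > 0])))
  # invariance to a constant shift of every curve
  shift_curve <- function(cu, d) {
    cnt <- rep(0, 20)
    idx <- seq_along(cu$counts) + d
    keep <- idx >= 1 & idx <= 20
    cnt[idx[keep]] <- cu$counts[keep]
    names(cnt) <- as.character(1:20)
    cu$counts <- cnt
    cu
  }
  a <- align_and_average(list(delta_curve(4), delta_curve(9)))
  b <- align_and_average(list(shift_curve(delta_curve(4), 3),
                              shift_curve(delta_curve(9), 3)))
  expect_equal(a$density, b$density)
})

test_that("computational minPreNum matches closed forms and a naive oracle", {
  # zero variance: deterministic floor(vth/mu) + 1 under strict inequality
  cu <- computational_minprenum(0.0066, gaussian_spec(9e-4, 0), 50)
  expect_equal(unname(which(cu$counts > 0)), floor(0.0066 / 9e-4) + 1)
  # mean far above the threshold: always 1
  cu2 <- computational_minprenum(1e-4, gaussian_spec(0.05, 1e-5), 50)
  expect_equal(unname(cu2$counts[["1"]]), 50)
  # stochastic case against an independent per-trial loop
  naive <- function(vth, mu, sg, n) {
    out <- integer(n)
    for (i in seq_len(n)) {
      tot <- 0; out[i] <- NA
      for (k in 1:20) {
        w <- rnorm(1, mu, sg)
        while (w < 0) w <- rnorm(1, mu, sg)
        tot <- tot + w
        if (tot > vth) { out[i] <- k; break }
      }
    }
    out
  }
  set.seed(99)
  ref <- tabulate(naive(0.0066, 9e-4, 9e-4, 4000), 20) / 4000
  set.seed(100)
  cu3 <- computational_minprenum(0.0066, gaussian_spec(9e-4, 9e-4), 4000)
  got <- cu3$counts / sum(cu3$counts)
  expect_lt(sum(abs(ref - got)) / 2, 0.05)  # total variation distance
})

test_that("weight-distribution fitting recovers planted parameters", {
  set.seed(42)
  planted <- gaussian_spec(9e-4, 6e-4, "weight")
  target_curve <- computational_minprenum(0.0066, planted, 4000)
  target <- align_and_average(list(target_curve))
  set.seed(43)
  fit <- fit_weight_distribution(target, vth = 0.0066,
                                 mean_grid = seq(5e-4, 13e-4, by = 1e-4),
                                 sd_grid = seq(0, 12e-4, by = 2e-4),
                                 n_trials = 1000)
  expect_lte(abs(fit$spec$mean - planted$mean), 1.5e-4)  # one grid step
  expect_lte(abs(fit$spec$sd - planted$sd), 2.5e-4)
  # a degenerate delta target at bin k selects a zero-variance weight
  # distribution whose deterministic minPreNum is k
  dl <- list(offsets = 0, density = 1, center = 7)
  fit2 <- fit_weight_distribution(dl, vth = 0.0066,
                                  mean_grid = seq(5e-4, 13e-4, by = 1e-4),
                                  sd_grid = c(0, 2e-4, 4e-4),
                                  n_trials = 200)
  expect_equal(fit2$spec$sd, 0)
  expect_equal(floor(0.0066 / fit2$spec$mean) + 1, 7)
})

test_that("weight draws honour the non-negativity rule", {
  set.seed(5)
  w <- lnnlab:::.rtrunc0(5000, 2e-4, 9e-4)
  expect_true(all(w >= 0))
  expect_error(lnnlab:::.rtrunc0(10, -1, 0), "below zero")
})
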