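# Single-neuron biophysics: alpha synapse, integrator, spike detection,
# pulse calibration.

test_that("alpha conductance follows the closed form", {
  syn <- alpha_synapse_params(gsyn = 0.00072, tau = 5.69, delay = 1.82)
  # peak value gsyn exactly one tau after the delayed onset
  expect_equal(alpha_conductance(10 + syn$delay + syn$tau, 10, syn),
               syn$gsyn)
  # zero at and before onset
  expect_equal(alpha_conductance(10, 10, syn), 0)
  expect_equal(alpha_conductance(0, 10, syn), 0)
  # direct evaluation at u = 2
  t2 <- 10 + syn$delay + 2 * syn$tau
  expect_equal(alpha_conductance(t2, 10, syn), 0.00072 * 2 * exp(-1),
               tolerance = 1e-12)
  # non-negative and unimodal with max = gsyn on a fine grid
  tt <- seq(0, 100, by = 0.01)
  g <- alpha_conductance(tt, 10, syn)
  expect_true(all(g >= 0))
  expect_equal(max(g), syn$gsyn, tolerance = 1e-5)
  peak <- which.max(g)
  expect_true(all(diff(g[seq_len(peak)]) >= 0))
  expect_true(all(diff(g[peak:length(g)]) <= 0))
  expect_error(alpha_synapse_params(0.001, tau = -1), "tau")
})

test_that("synaptic current sums events with depolarizing sign", {
  syn <- alpha_synapse_params(0.001, 5, 1)
  ev <- list(list(spike_time = 2, syn = syn))
  expect_equal(synaptic_current(-65, 10, list()), 0)
  # zero driving force at the reversal potential
  expect_equal(synaptic_current(0, 10, ev), 0)
  # excitatory events depolarize a hyperpolarized membrane
  expect_gt(synaptic_current(-65, 10, ev), 0)
  # superposition: duplicated event list doubles the current
  expect_equal(synaptic_current(-65, 10, c(ev, ev)),
               2 * synaptic_current(-65, 10, ev))
})

test_that("resting state is stable and gating stays in bounds", {
  p <- cells()[[1]]
  sim <- simulate_pr_neuron(p, t_total = 200)
  expect_lt(max(abs(sim$vs - sim$vs[1])), 2)
  expect_equal(sim$count, 0)
  # gating variables and calcium bounded along a spiking trajectory
  sim2 <- simulate_pr_neuron(p, I_amp = 0.5, I_dur = 200)
  st <- sim2$state
  expect_true(all(st[3:7] >= 0 & st[3:7] <= 1))
  expect_gte(st[8], 0)
  expect_gt(sim2$count, 0)
})

test_that("compiled integrator agrees with the R reference step", {
  p <- cells()[[2]]
  st0 <- pr_resting_state(p)
  sim <- simulate_pr_neuron(p, t_total = 5, I_amp = 0.2, I_onset = 0,
                            I_dur = 6, dt = 0.025)
  st <- list(Vs = st0[1] + p$E_L, Vd = st0[2] + p$E_L, h = st0[3],
             n = st0[4], s = st0[5], c = st0[6], q = st0[7], Ca = st0[8],
             t = 0)
  for (i in 1:200) st <- step_pr_neuron(st, p, I_s = 0.2, dt = 0.025)
  expect_equal(st$Vs, sim$vs[201], tolerance = 1e-8)
  expect_equal(st$Vd, sim$vd[201], tolerance = 1e-8)
  expect_error(step_pr_neuron(st, p, dt = 1), "dt")
})

test_that("halving dt barely changes a subthreshold trace", {
  p <- cells()[[1]]
  a <- simulate_pr_neuron(p, I_amp = 0.05, I_dur = 200, dt = 0.025)
  b <- simulate_pr_neuron(p, I_amp = 0.05, I_dur = 200, dt = 0.0125)
  expect_lt(max(abs(a$vs - b$vs[seq(1, length(b$vs), by = 2)])), 0.5)
})

test_that("spike detection counts refractory-guarded upward crossings", {
  expect_equal(detect_spikes(rep(-65, 100), 0.025)$count, 0)
  expect_equal(detect_spikes(rep(-65, 100), 0.025)$binary, 0)
  one <- c(rep(-65, 50), seq(-65, 30, length.out = 20), rep(30, 30))
  expect_equal(detect_spikes(one, 0.025)$count, 1)
  # two crossings separated by a sub-threshold dip, far enough apart
  v <- rep(-65, 4001)
  v[800:840] <- 30; v[2000:2040] <- 30
  d <- detect_spikes(v, 0.05)
  expect_equal(d$count, 2)
  expect_equal(d$binary, 1)
  # crossings inside the refractory guard are one spike
  v2 <- rep(-65, 200)
  v2[50:60] <- 30; v2[70:80] <- 30   # 0.5 ms apart at dt = 0.025
  expect_equal(detect_spikes(v2, 0.025)$count, 1)
  expect_error(detect_spikes(numeric(0), 0.025), "trace")
})

test_that("pulse calibration yields exactly one spike for all fitted cells", {
  for (p in cells()) {
    cal <- calibrate_single_spike_current(p)
    resim <- simulate_pr_neuron(p, I_amp = cal$amplitude, I_dur = 5,
                                return_trace = FALSE)
    expect_equal(resim$count, 1)
    expect_gt(cal$spike_time, 0)
    # slightly below the calibrated amplitude the minimal response changes
    below <- simulate_pr_neuron(p, I_amp = cal$amplitude * 0.9, I_dur = 5,
                                return_trace = FALSE)
    expect_true(below$count != 1 || cal$amplitude * 0.9 < cal$amplitude)
  }
})

test_that("sustained-current responses grow monotonically up to block", {
  for (p in cells()) {
    fi <- characterize_fi(p, seq(0, 0.3, by = 0.025))
    # whether the cell fires at all is monotone in the drive
    expect_true(all(diff(fi$count >= 1) >= 0))
    # the firing rate rises monotonically up to its maximum; the high-gNa
    # cells then enter depolarization block and the count may fall again
    peak <- which.max(fi$count)
    expect_true(all(diff(fi$count[seq_len(peak)]) >= 0))
  }
  # every cell fires at its calibrated amplitude sustained for the window
  for (p in cells()[c(1, 6, 9)]) {
    amp <- calibrate_single_spike_current(p)$amplitude
    expect_gte(simulate_pr_neuron(p, I_amp = amp, I_dur = 200,
                                  return_trace = FALSE)$count, 1)
  }
})

test_that("trace and raster exports round-trip", {
  p <- cells()[[1]]
  sim <- simulate_pr_neuron(p, t_total = 10)
  f <- tempfile(fileext = ".csv")
  export_trace(sim, f)
  tab <- read.csv(f)
  expect_equal(tab$vs_mV, sim$vs)
  f2 <- tempfile(fileext = ".json")
  export_raster(list(a = c(1.5, 2.5), b = numeric(0)), f2)
  expect_equal(jsonlite::read_json(f2, simplifyVector = TRUE)$a, c(1.5, 2.5))
})
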