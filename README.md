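# lnnlab

Simulation and training tools for **hybrid bio-silicon neural networks**:
classifiers whose first layer is a living culture of dissociated cortical
neurons (random sparse excitatory connections, large neuron-to-neuron and
synapse-to-synapse variability, weights confined to 0.5–2× their initial
strength) and whose second layer is ordinary silicon. The package is for
computational neuroscientists and neuromorphic-algorithm designers who want
to measure how those biological constraints affect inference *before*
committing to wet-lab experiments.

It implements the full pipeline:

1. **Biophysical layer** — two-compartment Pinsky–Rinzel neurons (somatic
   Na/K-DR/leak, dendritic Ca/K-C/K-AHP/leak, coupling conductance `g_c`,
   somatic area fraction `p`) driven by calibrated 5 ms current pulses and
   alpha-function synapses `g(t) = g_syn · u·e^(1−u)`,
   `u = (t − t_spike − delay)/τ`. Nine fitted neuron parameter sets and
   twelve fitted synapses ship as CSV fixtures. A compiled fixed-step
   integrator (dt = 0.025 ms) makes network-scale simulation practical.
2. **Variability transfer** — the *minPreNum* experiment: the minimum
   number of simultaneously activated pre-synaptic neurons that fires each
   post-synaptic cell. Its per-cell expectations, scaled by the mean
   synaptic conductance, give the threshold distribution; a grid fit of
   the peak-aligned averaged histogram gives the weight distribution
   N(mean, sd) of the fast computational model.
3. **Computational model + constrained training** — a sparse threshold
   layer (fire iff `x·W > V_th`, weights ≥ 0, clamped to `[0.5 W0, 2 W0]`)
   under a dense softmax readout, trained with cross-entropy through a
   windowed straight-through estimator (gradient passes only where the
   pre-activation lies in `(0, 0.0075)`).
4. **Adaptive pre-processing (Adpp)** — average-pool 28×28 images to 14×14
   and tune one global binarization threshold so the mean ink-pixel count
   `Nin_b` drives the statistic

   `f = (Sparsity × Nin_b × meanW) / V_th`

   toward 1, the point where ~50% of the hidden layer fires and learning
   capacity peaks.
5. **Experiments** — presets for the comparison / optimization /
   variation experiment families, a biophysical-vs-computational training comparison,
   one-axis sweeps, and a variation study, plus a synthetic digit
   generator so everything runs without downloads.

## Worked example

```r
library(lnnlab)

# one fitted cell: calibrate the single-spike input pulse
cell <- fitted_neurons()[[1]]
cal  <- calibrate_single_spike_current(cell)
#> calibrated pulse: 0.354 nA -> spike at 23.7 ms

# the minPreNum bridging experiment (small run; the acceptance script uses 999 trials)
set.seed(42)
curves <- minprenum_experiment(n_trials = 180)
round(vapply(curves, `[[`, numeric(1), "expectation"), 1)
#> [1]  9.8  9.5  8.3  7.3  7.6 16.0  7.0 10.8  9.1
estimate_threshold_dist(curves, mean_gsyn = 0.0008)
#> N(0.00758222, 0.0020693) [threshold]

# synthetic digits, pooled and binarized to a target input density
set.seed(1)
ds <- generate_synthetic_digits(300, seed = 1)
pp <- preprocess_dataset(ds, adpp_config(target_nin_b = 20))
#> binarization threshold 0.777 -> mean Nin_b 20.0

# train the constrained hybrid network
layers <- init_layers(196, 100)
fit <- train_network(pp$X, pp$y, layers, train_config(epochs = 40))
tail(fit$history[, c("epoch", "loss", "train_acc", "nf_hidden")], 1)
#>    epoch     loss train_acc nf_hidden
#> 40    40 1.699054      0.79    0.7261
```

The nine expectations are each cell's mean minimum pre-synaptic count
(cell 6, much leakier than the rest, needs about twice as many inputs);
scaling their mean by the 0.0008 µS mean conductance puts the hidden-layer
firing threshold near 0.0066–0.0076 weight units. After training,
`nf_hidden` is the fraction of hidden neurons firing per image — the
quantity the `f` statistic predicts (`f_statistic(0.4, 20, 9e-4, 0.0066)`
≈ 1.09).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/lnnlab.R transfer --n-trials 500 --seed 1 --out results/
Rscript inst/cli/lnnlab.R compare --preset comparison_fix --epochs 30 --out results/
```

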