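# Shared fixtures. Expensive objects are computed once per test run and
# cached here; everything is built in code (no binary fixtures).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

cells <- function() fixture("cells", fitted_neurons)
syns <- function() fixture("syns", fitted_synapses)

# the minPreNum experiment used by the transfer and acceptance tests
minpre_curves <- function() fixture("minpre", function() {
  set.seed(20260901)
  minprenum_experiment(n_trials = 540)
})

small_digits <- function() fixture("digits300", function()
  generate_synthetic_digits(300, seed = 77))

# delta-histogram curve with a known expectation, for estimator unit tests
delta_curve <- function(k, n = 50, label = "synthetic") {
  vals <- rep(k, n)
  lnnlab:::.new_curve(label, vals)
}
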