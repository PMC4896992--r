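# Shared small-scale fixtures, generated once per test run. Unit tests use a
# reduced sampling rate and channel count so each simulation takes ~1 s; the
# acceptance tests use the full default conditions.

small_cfg <- function(duration_s = 300, sample_rate_lfp = 256,
                      n_channels = 2, rng_seed = 42, ...) {
  sim_config(duration_s = duration_s, sample_rate_lfp = sample_rate_lfp,
             n_channels = n_channels, rng_seed = rng_seed, ...)
}

.fixtures <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixtures$sim)) .fixtures$sim <- simulate_lfp(small_cfg())
  .fixtures$sim
}

small_model <- function() {
  if (is.null(.fixtures$model)) {
    sim <- small_sim()
    .fixtures$model <- absc_train(sim$lfp, sim$truth)
  }
  .fixtures$model
}

small_seg <- function() {
  if (is.null(.fixtures$seg)) {
    sim <- small_sim()
    .fixtures$seg <- absc_classify(sim$lfp, small_model())
  }
  .fixtures$seg
}

# Band-power matrix whose single row yields a chosen coded vector under
# bounds UB = 0.3, LB = 0.15 in relative mode: built by spacing band powers.
toy_bounds <- function(ub = 1) {
  compute_bounds(matrix(ub, nrow = 1, ncol = 10), rounding_precision = 1)
}

# Independent periodogram band power: direct DFT of a whole interval,
# summing |X|^2 over bins in [lo, hi] Hz. Used as the oracle against the
# windowed pipeline and the simulator.
oracle_band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * rate / n
  sum(Mod(X[f >= lo & f <= hi])^2) / n
}
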