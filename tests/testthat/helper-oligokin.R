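# shared fixture builders; all randomness is locally seeded

random_params <- function() {
  # parameter regimes of the studied assays: M0 0.4-15 uM, k over ~5 decades
  oligomer_params(M0 = stats::runif(1, 0.4, 15),
                  n = stats::runif(1, 1.5, 4),
                  k = 10^stats::runif(1, -4, 1),
                  c = stats::runif(1, 10, 1000),
                  F0 = stats::runif(1, 0, 100))
}

noiseless_trace <- function(M0 = 3, n = 3, k = 0.05, c = 100, F0 = 10,
                            t_max = 10, n_pts = 200, pH = 7.4,
                            sample_id = "t1") {
  p <- oligomer_params(M0, n, k, c, F0)
  simulate_trace(p, seq(0, t_max, length.out = n_pts), noise_sd = 0,
                 pH = pH, sample_id = sample_id)
}

small_plate <- function(...) {
  plate_design(pH = c(5.0, 6.0, 7.0),
               concentrations = c(1, 2.5, 5),
               replicates = 1, interval = 0.1, duration = 20, ...)
}
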