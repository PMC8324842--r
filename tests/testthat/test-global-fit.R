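test_that("a noiseless trace is recovered to high precision", {
  tr <- noiseless_trace(M0 = 3, n = 3, k = 0.05, c = 100, F0 = 10)
  f <- fit_trace(tr, n = 3)
  expect_equal(f$params$k, 0.05, tolerance = 1e-4)
  expect_equal(f$params$c, 100, tolerance = 1e-4)
  expect_equal(f$params$F0, 10, tolerance = 1e-3)
})

test_that("noisy recovery stays within the reported uncertainty", {
  p <- oligomer_params(3, 3, 0.05, c = 100, F0 = 10)
  tr <- simulate_trace(p, seq(0, 10, length.out = 200),
                       noise_sd = 0.01 * 300, seed = 42)
  f <- fit_trace(tr, n = 3)
  expect_lt(abs(f$params$k - 0.05), 3 * f$se[["k"]])
})

test_that("a constant trace raises the no-signal flag", {
  tr <- kinetic_trace(seq(0, 10, 0.1), rep(100, 101), 3, 7.4)
  expect_error(fit_trace(tr), "no oligomerization signal")
})

test_that("global fit recovers per-group rate constants", {
  mk <- function(k, M0, id, pH)
    noiseless_trace(M0 = M0, k = k, c = 50, F0 = 5, pH = pH,
                    sample_id = id)
  traces <- c(lapply(c(1, 2, 4), function(m) mk(0.02, m, paste0("a", m), 5)),
              lapply(c(1, 2, 4), function(m) mk(0.7, m, paste0("b", m), 6)))
  g <- fit_global(traces, share_spec(fix_n = 3))
  expect_equal(sort(g$k$k), c(0.02, 0.7), tolerance = 1e-3)

  # with n free the shared order is identified too
  gn <- fit_global(traces, share_spec(fix_n = NULL))
  expect_equal(gn$n_hat, 3, tolerance = 1e-2)

  # a single trace through the global machinery equals fit_trace
  f1 <- fit_trace(traces[[1]], n = 3)
  g1 <- fit_global(traces[1], share_spec(fix_n = 3))
  expect_equal(g1$k$k[1], f1$params$k, tolerance = 1e-10)
  expect_equal(g1$nuisance$c[1], f1$params$c, tolerance = 1e-10)
})

test_that("reaction order is identifiable near the previously reported 3.3", {
  set.seed(55)
  traces <- lapply(c(1, 2.5, 5, 10), function(m)
    noiseless_trace(M0 = m, n = 3.3, k = 0.02, c = 80, F0 = 3,
                    sample_id = paste0("m", m)))
  g <- fit_global(traces, share_spec(fix_n = NULL))
  expect_lt(abs(g$n_hat - 3.3), 0.15)
})

test_that("noiseless recovery holds across the studied parameter regimes", {
  set.seed(66)
  for (i in 1:10) {
    k <- 10^stats::runif(1, -4, 1)
    M0s <- stats::runif(3, 0.4, 15)
    # sample out to several half-times of the slowest trace
    t_half <- 1 / (2 * k * min(M0s)^2)
    t_max <- min(max(3 * t_half, 1), 1e4)
    traces <- lapply(seq_along(M0s), function(j) {
      p <- oligomer_params(M0s[j], 3, k, c = 100, F0 = 0)
      simulate_trace(p, seq(0, t_max, length.out = 150),
                     sample_id = paste0("w", j))
    })
    g <- fit_global(traces, share_spec(fix_n = 3))
    expect_equal(g$k$k[1], k, tolerance = 1e-3)
  }
})

test_that("a group of pure-noise traces is flagged unidentifiable", {
  good <- noiseless_trace(k = 0.1, c = 100, sample_id = "good", pH = 5)
  flat <- with(list(), {
    set.seed(9)
    kinetic_trace(seq(0, 10, 0.1), rnorm(101, 100, 1), 3, 7,
                  sample_id = "flat")
  })
  expect_warning(g <- fit_global(list(good, flat), share_spec(fix_n = 3)),
                 regexp = NA)
  kf <- g$k[g$k$group == format(7, nsmall = 2), ]
  expect_false(kf$identifiable)
  expect_true(is.na(kf$k))
})

test_that("second-phase onset detection brackets the true lag", {
  p <- oligomer_params(3, 3, 0.1, c = 100, F0 = 10)
  tg <- seq(0, 12, 0.05)
  # no fibril phase: nothing to detect
  tr0 <- simulate_trace(p, tg, noise_sd = 3, seed = 5)
  expect_true(is.na(auto_truncate(tr0, n = 3)$onset))
  # logistic fibril component, lag 8 h, amplitude 5x the oligomer plateau
  for (s in 1:5) {
    tr <- simulate_biphasic_trace(
      p, tg, list(lag = 8, steepness = 0.2, amplitude = 5 * 300),
      noise_sd = 3, seed = s)
    onset <- auto_truncate(tr, n = 3)$onset
    expect_gte(onset, 7.5); expect_lte(onset, 9.0)
  }
})

test_that("detector inputs are validated", {
  p <- oligomer_params(3, 3, 0.1, c = 100, F0 = 10)
  short <- kinetic_trace(0:3, c(1, 2, 3, 4), 3, 7)
  expect_error(detect_second_phase_onset(short, p, run_len = 5),
               "shorter than run_len")
  tr <- noiseless_trace()
  expect_error(detect_second_phase_onset(tr, p, z_thresh = -1),
               "z_thresh")
})

test_that("truncation keeps the pre-onset grid and validates length", {
  tr <- noiseless_trace(t_max = 10, n_pts = 201)  # 0.05 h sampling
  expect_identical(truncate_to_oligomer_phase(tr, NA_real_), tr)
  cut <- truncate_to_oligomer_phase(tr, 8)
  expect_equal(length(cut$t), 160)
  expect_equal(cut$meta$truncated_at, 8)
  expect_error(truncate_to_oligomer_phase(tr, 0.1), "too short")
})

test_that("COC estimation is exact on collinear amplitudes", {
  est <- estimate_coc(c(2, 3, 4), c(1, 2, 3))
  expect_equal(est$coc, 1.0, tolerance = 1e-12)
  expect_equal(est$se, 0, tolerance = 1e-8)
  # amplitudes proportional to M0: the intercept is zero
  est0 <- estimate_coc(c(1, 2, 4), c(3, 6, 12))
  expect_equal(est0$coc, 0, tolerance = 1e-10)
  expect_error(estimate_coc(c(2, 3), c(0.5, 2), noise_floor = 1),
               "insufficient data")
  expect_error(estimate_coc(c(1, 2, 3), c(3, 2, 1)), "nonpositive")
})
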