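test_that("trace simulation is exact without noise and seeded with it", {
  p <- oligomer_params(2, 3, 0.05, c = 120, F0 = 8)
  tg <- seq(0, 20, 0.1)
  tr0 <- simulate_trace(p, tg)
  expect_identical(tr0$F, tht_signal(tg, p))
  a <- simulate_trace(p, tg, noise_sd = 2, seed = 31)
  b <- simulate_trace(p, tg, noise_sd = 2, seed = 31)
  expect_identical(a$F, b$F)
  expect_error(simulate_trace(p, tg, noise_sd = 1), "seed")
})

test_that("simulated noise has the requested scale", {
  p <- oligomer_params(2, 3, 0.05, c = 120, F0 = 8)
  tg <- seq(0, 100, length.out = 10000)
  tr <- simulate_trace(p, tg, noise_sd = 1, seed = 13)
  resid <- tr$F - tht_signal(tg, p)
  expect_gt(stats::sd(resid), 0.95)
  expect_lt(stats::sd(resid), 1.05)
})

test_that("plate simulation enumerates wells and carries provenance", {
  d <- plate_design(seed = 3)
  pl <- simulate_plate(d)
  expect_length(pl$traces, 7 * 4 * 2)
  expect_equal(nrow(pl$truth$wells), 56)
  # provenance reproduces every trace's generating model
  w <- pl$truth$wells[17, ]
  tr <- pl$traces[[17]]
  expect_equal(tr$M0, w$M0)
  expect_equal(tr$meta$true_params$k, w$k)
  # identical design + seed: bit-identical
  pl2 <- simulate_plate(d)
  expect_identical(pl$traces[[5]]$F, pl2$traces[[5]]$F)
})

test_that("a zero-slope design shares one rate constant across pH", {
  d <- plate_design(slope = 0, intercept = log10(0.02), c_jitter_sd = 0,
                    noise_frac = 0, replicates = 1,
                    concentrations = c(1, 5), interval = 0.2, seed = 1)
  pl <- simulate_plate(d)
  expect_equal(unname(diff(range(pl$truth$k_by_pH))), 0)
})

test_that("changing the seed changes only the noise component", {
  d1 <- plate_design(c_jitter_sd = 0, seed = 21, replicates = 1,
                     concentrations = c(1, 5), interval = 0.2)
  d2 <- plate_design(c_jitter_sd = 0, seed = 22, replicates = 1,
                     concentrations = c(1, 5), interval = 0.2)
  p1 <- simulate_plate(d1); p2 <- simulate_plate(d2)
  expect_identical(p1$truth$wells$k, p2$truth$wells$k)
  expect_identical(p1$truth$wells$c, p2$truth$wells$c)
  expect_false(identical(p1$traces[[1]]$F, p2$traces[[1]]$F))
  # the noiseless model component is unchanged
  m1 <- tht_signal(p1$traces[[1]]$t, p1$traces[[1]]$meta$true_params)
  m2 <- tht_signal(p2$traces[[1]]$t, p2$traces[[1]]$meta$true_params)
  expect_identical(m1, m2)
})

test_that("biphasic simulation degenerates to the pure oligomer trace", {
  p <- oligomer_params(3, 3, 0.1, c = 100, F0 = 10)
  tg <- seq(0, 12, 0.05)
  a <- simulate_biphasic_trace(p, tg, list(lag = 8, steepness = 0.2,
                                           amplitude = 0),
                               noise_sd = 3, seed = 4)
  b <- simulate_trace(p, tg, noise_sd = 3, seed = 4)
  expect_identical(a$F, b$F)
  # far before the lag the fibril component is negligible
  c_tr <- simulate_biphasic_trace(p, tg, list(lag = 8, steepness = 0.2,
                                              amplitude = 1500))
  early <- tg < 4
  expect_lt(max(abs(c_tr$F[early] - tht_signal(tg[early], p))), 1e-4 * 1500)
})

test_that("synthetic AFM images honour their construction", {
  # no particles, no noise, no tilt: identically zero
  z <- simulate_afm_image(c(16, 16), 2,
                          list(tilt = 0, line_offset_sd = 0,
                               roughness_sd = 0))
  expect_true(all(z$image$heights == 0))
  # one clean cap: apex exactly at the center pixel
  part <- data.frame(row = 32, col = 32, radius_nm = 12, apex_nm = 4)
  s <- simulate_afm_image(c(64, 64), 2,
                          list(tilt = 0, line_offset_sd = 0,
                               roughness_sd = 0), particles = part)
  expect_equal(max(s$image$heights), 4)
  expect_equal(which.max(s$image$heights),
               which(s$truth_heights == max(s$truth_heights)))
  expect_error(simulate_afm_image(c(32, 32), 2,
                                  particles = data.frame(row = 2, col = 2,
                                                         radius_nm = 12,
                                                         apex_nm = 4)),
               "outside")
  # preset ordering: clusters are far taller than small oligomers
  ol <- simulate_afm_field(4, "small_oligomer", c(96, 96), 2, seed = 8)
  cl <- simulate_afm_field(4, "cluster", c(256, 256), 4, seed = 8)
  med_ol <- stats::median(ol$truth_heights[ol$truth_mask > 0])
  med_cl <- stats::median(cl$truth_heights[cl$truth_mask > 0])
  expect_gt(med_cl, med_ol)
})
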