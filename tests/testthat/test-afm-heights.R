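clean_cap_image <- function(noise = 0.1, seed = 3, apex = 4) {
  part <- data.frame(row = 32, col = 32, radius_nm = 12, apex_nm = apex)
  simulate_afm_image(c(64, 64), 2,
                     list(tilt = c(0.01, 0), line_offset_sd = noise,
                          roughness_sd = noise),
                     particles = part, seed = seed)
}

test_that("scan-line flattening removes a tilted plane exactly", {
  s <- simulate_afm_image(c(64, 64), 2,
                          list(tilt = c(0.01, 0.02), line_offset_sd = 0,
                               roughness_sd = 0))
  flat <- flatten_scanlines(s$image, order = 1)
  expect_lt(max(abs(flat$heights)), 1e-9)
})

test_that("per-line constant offsets vanish at order 0", {
  set.seed(12)
  offs <- rnorm(32, 0, 5)
  h <- matrix(rep(offs, 32), 32, 32)
  flat <- flatten_scanlines(height_map(h, 2), order = 0)
  meds <- apply(flat$heights, 1, stats::median)
  expect_lt(max(abs(meds)), 1e-9)
})

test_that("flattening preserves particle apex heights", {
  s <- clean_cap_image(noise = 0.1, seed = 3)
  flat <- flatten_scanlines(s$image)
  # apex preserved to within the background noise scale
  expect_lt(abs(max(flat$heights) - 4), 3 * 0.1 * sqrt(2))
})

test_that("flattening is idempotent on flat images", {
  s <- clean_cap_image(noise = 0.05, seed = 7)
  f1 <- flatten_scanlines(s$image)
  f2 <- flatten_scanlines(f1)
  expect_lt(max(abs(f2$heights - f1$heights)), 1e-9)
})

test_that("segmentation finds isolated particles and ignores noise", {
  s <- clean_cap_image(noise = 0.1, seed = 3)
  flat <- flatten_scanlines(s$image)
  lab <- segment_particles(flat)
  expect_equal(max(lab), 1)
  expect_gt(lab[which.max(flat$heights)], 0)

  # two well-separated caps give two components
  parts <- data.frame(row = c(20, 100), col = c(20, 100),
                      radius_nm = 10, apex_nm = 4)
  s2 <- simulate_afm_image(c(120, 120), 2,
                           list(tilt = 0, line_offset_sd = 0.05,
                                roughness_sd = 0.1),
                           particles = parts, seed = 5)
  lab2 <- segment_particles(flatten_scanlines(s2$image))
  expect_equal(max(lab2), 2)

  # pure-noise images almost never yield components
  hits <- vapply(1:30, function(s) {
    ns <- simulate_afm_image(c(64, 64), 2,
                             list(tilt = 0, line_offset_sd = 0,
                                  roughness_sd = 0.1), seed = 600 + s)
    max(segment_particles(ns$image))
  }, 0L)
  expect_gte(mean(hits == 0), 0.95)
})

test_that("ACWE and plain-threshold segmentation agree on clean images", {
  part <- data.frame(row = 32, col = 32, radius_nm = 12, apex_nm = 4)
  s <- simulate_afm_image(c(64, 64), 2,
                          list(tilt = 0, line_offset_sd = 0,
                               roughness_sd = 0), particles = part)
  a <- segment_particles(s$image, method = "acwe")
  t <- segment_particles(s$image, method = "threshold")
  # identical component structure: same count, each containing the apex
  expect_equal(max(a), max(t))
  apex <- which.max(s$image$heights)
  expect_equal(a[apex] > 0, t[apex] > 0)
  # the ACWE region is contained in the threshold region (boundary
  # equilibrium sits at the inter-region midpoint height)
  expect_true(all(t[a > 0] > 0))
})

test_that("height distributions summarize masked pixels", {
  h <- matrix(0, 16, 16)
  h[5:8, 5:8] <- 4
  img <- height_map(h, 2)
  d <- height_distribution(img, h > 0)
  expect_equal(d$median, 4)
  expect_equal(d$q75 - d$q25, 0)
  expect_equal(d$n_pixels, 16L)
  expect_error(height_distribution(img, h > 10), "empty mask")
})

test_that("measured medians match the generator's analytic oracle", {
  s <- clean_cap_image(noise = 0.1, seed = 21)
  flat <- flatten_scanlines(s$image)
  measured <- height_distribution(flat, s$truth_mask)
  oracle <- height_distribution(height_map(s$truth_heights, 2),
                                s$truth_mask)
  # agreement within pixelization + noise on the per-pixel sample
  expect_lt(abs(measured$median - oracle$median), 0.15)
  # masked heights never exceed the planted apex + 3 noise sd
  expect_lt(max(flat$heights[s$truth_mask > 0]), 4 + 3 * 0.15)
})

test_that("cluster images are far taller than small-oligomer images", {
  ol <- simulate_afm_field(4, "small_oligomer", c(96, 96), 2, seed = 14)
  cl <- simulate_afm_field(3, "cluster", c(256, 256), 4, seed = 15)
  m_ol <- height_distribution(flatten_scanlines(ol$image), ol$truth_mask)
  m_cl <- height_distribution(flatten_scanlines(cl$image), cl$truth_mask)
  expect_gt(m_cl$median, m_ol$median)
})

test_that("height maps round-trip through text and TIFF files", {
  s <- clean_cap_image(noise = 0.05, seed = 2)
  txt <- tempfile(fileext = ".txt")
  write.table(s$image$heights, txt, row.names = FALSE, col.names = FALSE)
  r <- read_height_map(txt, pixel_size = 2)
  expect_equal(r$heights, s$image$heights, tolerance = 1e-12)
  tif <- tempfile(fileext = ".tif")
  # store as scaled 16-bit intensities with 0.01 nm per unit
  scaled <- (s$image$heights - min(s$image$heights)) / 0.01
  tiff::writeTIFF(round(scaled) / 2^16, tif, bits.per.sample = 16)
  r2 <- read_height_map(tif, pixel_size = 2, height_scale = 0.01)
  expect_equal(max(r2$heights) - min(r2$heights),
               max(s$image$heights) - min(s$image$heights),
               tolerance = 0.02)
})

test_that("the file-level AFM pipeline produces tidy tables", {
  s <- clean_cap_image(noise = 0.1, seed = 3)
  d <- tempfile(); dir.create(d)
  write.table(s$image$heights, file.path(d, "img1.txt"),
              row.names = FALSE, col.names = FALSE)
  res <- afm_pipeline(file.path(d, "img1.txt"), pixel_size = 2)
  expect_equal(res$summary$n_particles, 1L)
  expect_equal(nrow(res$heights), res$summary$n_pixels)
  expect_true(all(c("image_id", "particle_id", "height_nm")
                  %in% names(res$heights)))
  expect_gt(res$summary$median, 0)
})
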