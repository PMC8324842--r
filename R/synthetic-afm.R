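#' Particle presets for the AFM generator
#'
#' `"small_oligomer"`: spherical-cap particles of ~4 nm apex height
#' (dried-state oligomers); `"cluster"`: large assemblies of ~100 nm apex
#' height.
#'
#' @param preset preset name.
#' @return List with `apex_nm` and `radius_nm`.
#' @export
afm_particle_preset <- function(preset = c("small_oligomer", "cluster")) {
  preset <- match.arg(preset)
  switch(preset,
         small_oligomer = list(apex_nm = 4, radius_nm = 10),
         cluster = list(apex_nm = 100, radius_nm = 150))
}

# spherical-cap height profile: cap of apex height h and base radius a is
# the top of a sphere of radius R = (a^2 + h^2) / (2h)
cap_profile <- function(r, apex, radius) {
  R <- (radius^2 + apex^2) / (2 * apex)
  z <- rep(0, length(r))
  inside <- r <= radius
  z[inside] <- sqrt(pmax(R^2 - r[inside]^2, 0)) - (R - apex)
  z
}

#' Simulate an AFM height map with known ground truth
#'
#' Builds spherical-cap particles on a tilted background with per-scan-line
#' offsets and Gaussian roughness — the artefact structure that scan-line
#' flattening removes. Returns the analytic ground truth (label mask and
#' noise-free particle heights) alongside, so segmentation and
#' height-measurement oracles never re-derive geometry.
#'
#' @param shape image size, px (rows, cols).
#' @param pixel_size nm per pixel.
#' @param background list: `tilt` (nm/px; length 1 or 2 for x/y),
#'   `line_offset_sd` (nm, per-scan-line DC offset), `roughness_sd` (nm,
#'   i.i.d. pixel noise).
#' @param particles data frame with columns `row`, `col` (px centers),
#'   `radius_nm`, `apex_nm`; every particle must lie fully inside the
#'   image and have radius > pixel_size.
#' @param seed RNG seed; required when the background is stochastic.
#' @return List with `image` (a [height_map()]), `truth_mask` (integer
#'   labels, one per particle) and `truth_heights` (noise-free particle
#'   height surface, nm).
#' @export
simulate_afm_image <- function(shape = c(128, 128), pixel_size = 2,
                               background = list(tilt = c(0.01, 0.005),
                                                 line_offset_sd = 0.1,
                                                 roughness_sd = 0.1),
                               particles = NULL, seed = NULL) {
  nr <- shape[1]; nc <- shape[2]
  tilt <- rep(background$tilt %||% 0, length.out = 2)
  lo_sd <- background$line_offset_sd %||% 0
  ro_sd <- background$roughness_sd %||% 0

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  truth <- matrix(0, nr, nc)
  mask <- matrix(0L, nr, nc)
  if (!is.null(particles) && nrow(particles) > 0) {
    for (i in seq_len(nrow(particles))) {
      p <- particles[i, ]
      r_px <- p$radius_nm / pixel_size
      if (p$radius_nm <= pixel_size)
        stop("particle radius must exceed the pixel size", call. = FALSE)
      if (p$row - r_px < 1 || p$row + r_px > nr ||
          p$col - r_px < 1 || p$col + r_px > nc)
        stop("particle ", i, " extends outside the image", call. = FALSE)
      r_nm <- sqrt((rows - p$row)^2 + (cols - p$col)^2) * pixel_size
      z <- cap_profile(r_nm, p$apex_nm, p$radius_nm)
      truth <- pmax(truth, z)
      mask[z > 0] <- i
    }
  }
  bg <- tilt[1] * cols + tilt[2] * rows
  noise <- matrix(0, nr, nc)
  if ((lo_sd > 0 || ro_sd > 0) && is.null(seed))
    stop("a seed is required for stochastic background", call. = FALSE)
  if (lo_sd > 0 || ro_sd > 0) {
    noise <- with_seed(seed, function() {
      line_off <- if (lo_sd > 0) stats::rnorm(nr, 0, lo_sd) else numeric(nr)
      rough <- if (ro_sd > 0) matrix(stats::rnorm(nr * nc, 0, ro_sd), nr, nc)
               else matrix(0, nr, nc)
      rough + line_off
    })
  }
  list(image = height_map(truth + bg + noise, pixel_size),
       truth_mask = mask,
       truth_heights = truth)
}

#' Simulate a field of randomly placed preset particles
#'
#' Scatters `n_particles` non-overlapping spherical caps of one preset
#' across the image by seeded rejection sampling, on the standard noisy
#' tilted background.
#'
#' @param n_particles number of particles.
#' @param preset particle preset name (see [afm_particle_preset()]).
#' @param shape image size, px.
#' @param pixel_size nm per pixel.
#' @param background background spec as in [simulate_afm_image()].
#' @param seed RNG seed (mandatory).
#' @return As [simulate_afm_image()], plus `particles` (the placement
#'   table).
#' @export
simulate_afm_field <- function(n_particles = 10, preset = "small_oligomer",
                               shape = c(128, 128), pixel_size = 2,
                               background = list(tilt = c(0.01, 0.005),
                                                 line_offset_sd = 0.1,
                                                 roughness_sd = 0.1),
                               seed = 1L) {
  spec <- afm_particle_preset(preset)
  r_px <- spec$radius_nm / pixel_size
  margin <- ceiling(r_px) + 2
  if (2 * margin >= min(shape))
    stop("image too small for this preset", call. = FALSE)
  placements <- with_seed(seed, function() {
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(pts) < n_particles && tries < 10000) {
      cand <- c(stats::runif(1, margin, shape[1] - margin),
                stats::runif(1, margin, shape[2] - margin))
      if (nrow(pts) == 0 ||
          all(sqrt(rowSums(sweep(pts, 2, cand)^2)) > 2.5 * r_px))
        pts <- rbind(pts, cand)
      tries <- tries + 1
    }
    pts
  })
  if (nrow(placements) < n_particles)
    stop("could not place ", n_particles, " non-overlapping particles",
         call. = FALSE)
  particles <- data.frame(row = placements[, 1], col = placements[, 2],
                          radius_nm = spec$radius_nm,
                          apex_nm = spec$apex_nm)
  out <- simulate_afm_image(shape, pixel_size, background, particles,
                            seed = seed + 1L)
  out$particles <- particles
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
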