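# Run fn with a local, restored RNG state seeded by `seed`.
with_seed <- function(seed, fn) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  fn()
}

#' Simulate one ThT kinetic trace
#'
#' Forward model plus i.i.d. Gaussian measurement noise. With
#' `noise_sd = 0` the trace equals [tht_signal()] on the grid exactly;
#' identical seeds give bit-identical traces.
#'
#' @param p an [oligomer_params()] object (true parameters).
#' @param t_grid sampling times, hours.
#' @param noise_sd Gaussian noise standard deviation, a.u.
#' @param seed RNG seed; required whenever `noise_sd > 0`.
#' @param pH pH recorded in the trace metadata.
#' @param sample_id,plate_id,replicate identifiers.
#' @return A [kinetic_trace()].
#' @export
simulate_trace <- function(p, t_grid, noise_sd = 0, seed = NULL,
                           pH = 7.4, sample_id = "sim", plate_id = "sim",
                           replicate = 1L) {
  stopifnot(inherits(p, "oligomer_params"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required for stochastic output", call. = FALSE)
  signal <- tht_signal(t_grid, p)
  F <- if (noise_sd > 0)
    with_seed(seed, function() signal + stats::rnorm(length(t_grid), 0, noise_sd))
  else signal
  kinetic_trace(t_grid, F, p$M0, pH, sample_id, plate_id, replicate,
                meta = list(true_params = p, noise_sd = noise_sd))
}

#' Simulate a biphasic trace (oligomer phase + fibril second phase)
#'
#' Adds a phenomenological logistic fibril component to the oligomerization
#' signal: the lag parameter marks the onset of detectable fibril signal
#' (the sigmoid's 1% point), with the midpoint at
#' `lag + steepness * log(99)`. In nucleated polymerization the lag time is
#' the delay before detectable growth, so the generator anchors the
#' component there rather than at the sigmoid midpoint. With
#' `amplitude = 0` the output is identical to [simulate_trace()] for the
#' same seed.
#'
#' @inheritParams simulate_trace
#' @param fibril list with `lag` (h, >= 0), `steepness` (h, > 0) and
#'   `amplitude` (a.u., >= 0).
#' @return A [kinetic_trace()]; the true fibril spec is kept in `meta`.
#' @export
simulate_biphasic_trace <- function(p, t_grid, fibril, noise_sd = 0,
                                    seed = NULL, pH = 7.4,
                                    sample_id = "sim-biphasic",
                                    plate_id = "sim", replicate = 1L) {
  stopifnot(inherits(p, "oligomer_params"))
  stopifnot(is.list(fibril), all(c("lag", "steepness", "amplitude")
                                 %in% names(fibril)))
  if (fibril$lag < 0) stop("lag must be >= 0", call. = FALSE)
  if (fibril$steepness <= 0) stop("steepness must be > 0", call. = FALSE)
  if (fibril$amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required for stochastic output", call. = FALSE)
  midpoint <- fibril$lag + fibril$steepness * log(99)
  signal <- tht_signal(t_grid, p) +
    fibril$amplitude * stats::plogis((t_grid - midpoint) / fibril$steepness)
  F <- if (noise_sd > 0)
    with_seed(seed, function() signal + stats::rnorm(length(t_grid), 0, noise_sd))
  else signal
  kinetic_trace(t_grid, F, p$M0, pH, sample_id, plate_id, replicate,
                meta = list(true_params = p, fibril = fibril,
                            noise_sd = noise_sd))
}

#' Design of a synthetic kinetics plate
#'
#' Describes a full pH x concentration x replicate plate with a log-linear
#' rate law log10 k = intercept + slope * pH, pH-dependent ThT brightness,
#' per-well brightness jitter, and an optional stochastic-lag fibril second
#' phase. Defaults mirror the studied conditions: pH 4.8-7.6, 0.65-5 uM,
#' slope -1.56 decades per pH unit, 1% amplitude noise, brightness halving
#' per pH unit below 6.
#'
#' @param pH pH values of the plate.
#' @param concentrations protein concentrations per pH, uM.
#' @param replicates replicate wells per condition.
#' @param interval sampling interval, h.
#' @param duration assay duration, h.
#' @param slope,intercept log-linear rate law: log10 k = intercept +
#'   slope * pH (k in uM^(1-n) h^-1).
#' @param n reaction order of the generating model.
#' @param base_brightness fluorescence per uM of oligomer at neutral pH,
#'   a.u./uM.
#' @param brightness_fun per-pH brightness multiplier; default halves per
#'   pH unit below 6 (ThT emission drops at acidic pH; the quantitative
#'   dependence is not established, so this is a configurable placeholder).
#' @param c_jitter_sd lognormal sd of the per-well brightness jitter.
#' @param noise_frac noise sd as a fraction of the well's plateau amplitude
#'   (c * M0).
#' @param fibril list: `enabled`, `lag_mean`, `lag_sd` (h), `steepness`
#'   (h), `amplitude_mult` (fibril amplitude as a multiple of the oligomer
#'   plateau).
#' @param seed RNG seed; mandatory for any stochastic output.
#' @return An object of class `plate_design`.
#' @export
plate_design <- function(pH = c(4.8, 5.6, 6.0, 6.4, 6.8, 7.2, 7.6),
                         concentrations = c(0.65, 1.25, 2.5, 5),
                         replicates = 2,
                         interval = 0.05, duration = 40,
                         slope = -1.56, intercept = 7.9,
                         n = 3,
                         base_brightness = 1000,
                         brightness_fun = function(pH) pmin(1, 2^(pH - 6)),
                         c_jitter_sd = 0.05,
                         noise_frac = 0.01,
                         fibril = list(enabled = FALSE, lag_mean = 8,
                                       lag_sd = 0.5, steepness = 0.2,
                                       amplitude_mult = 5),
                         seed = 1L) {
  if (any(concentrations <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (interval <= 0 || duration <= 0)
    stop("interval and duration must be > 0", call. = FALSE)
  if (noise_frac < 0) stop("noise_frac must be >= 0", call. = FALSE)
  if (c_jitter_sd < 0) stop("c_jitter_sd must be >= 0", call. = FALSE)
  stochastic <- noise_frac > 0 || c_jitter_sd > 0 || isTRUE(fibril$enabled)
  if (stochastic && is.null(seed))
    stop("a seed is mandatory for stochastic output", call. = FALSE)
  structure(list(pH = pH, concentrations = concentrations,
                 replicates = replicates, interval = interval,
                 duration = duration, slope = slope, intercept = intercept,
                 n = n, base_brightness = base_brightness,
                 brightness_fun = brightness_fun,
                 c_jitter_sd = c_jitter_sd, noise_frac = noise_frac,
                 fibril = fibril, seed = seed),
            class = "plate_design")
}

#' Simulate a full kinetics plate
#'
#' One trace per (pH, concentration, replicate). Rate constants follow the
#' design's log-linear law k(pH) = 10^(intercept + slope * pH); per-well
#' brightness is base x pH multiplier x lognormal jitter. Full provenance
#' (every well's true parameters, the true k per pH, the design slope) is
#' returned so downstream recovery tests never re-derive ground truth.
#'
#' @param design a [plate_design()].
#' @return List with `traces` (list of [kinetic_trace()]), `truth` (list:
#'   `k_by_pH`, `slope`, `intercept`, `wells` data frame of per-well true
#'   parameters) and the `design`.
#' @export
simulate_plate <- function(design) {
  stopifnot(inherits(design, "plate_design"))
  d <- design
  t_grid <- seq(0, d$duration, by = d$interval)
  k_by_pH <- 10^(d$intercept + d$slope * d$pH)
  names(k_by_pH) <- format_ph(d$pH)
  grid <- expand.grid(rep = seq_len(d$replicates),
                      M0 = d$concentrations, pH = d$pH,
                      KEEP.OUT.ATTRS = FALSE)
  with_seed(d$seed, function() {
    # truth first, then noise: the stochastic truth (jitter, lags) and the
    # measurement noise come from one seeded stream in a fixed order
    jit <- if (d$c_jitter_sd > 0)
      exp(stats::rnorm(nrow(grid), 0, d$c_jitter_sd)) else rep(1, nrow(grid))
    lags <- if (isTRUE(d$fibril$enabled))
      pmax(0, stats::rnorm(nrow(grid), d$fibril$lag_mean, d$fibril$lag_sd))
    else rep(NA_real_, nrow(grid))
    wells <- data.frame(sample_id = sprintf("pH%s_c%g_r%d",
                                            format_ph(grid$pH), grid$M0,
                                            grid$rep),
                        pH = grid$pH, M0 = grid$M0, replicate = grid$rep,
                        k = unname(k_by_pH[format_ph(grid$pH)]),
                        c = d$base_brightness * d$brightness_fun(grid$pH) * jit,
                        F0 = 0, fibril_lag = lags,
                        stringsAsFactors = FALSE)
    traces <- vector("list", nrow(wells))
    for (i in seq_len(nrow(wells))) {
      w <- wells[i, ]
      p <- oligomer_params(M0 = w$M0, n = d$n, k = w$k, c = w$c, F0 = w$F0)
      signal <- tht_signal(t_grid, p)
      if (isTRUE(d$fibril$enabled)) {
        mid <- w$fibril_lag + d$fibril$steepness * log(99)
        signal <- signal + d$fibril$amplitude_mult * w$c * w$M0 *
          stats::plogis((t_grid - mid) / d$fibril$steepness)
      }
      noise_sd <- d$noise_frac * w$c * w$M0
      F <- signal + if (noise_sd > 0)
        stats::rnorm(length(t_grid), 0, noise_sd) else 0
      traces[[i]] <- kinetic_trace(t_grid, F, w$M0, w$pH,
                                   sample_id = w$sample_id,
                                   plate_id = "synthetic-plate",
                                   replicate = w$replicate,
                                   meta = list(true_params = p,
                                               noise_sd = noise_sd,
                                               fibril_lag = w$fibril_lag))
    }
    list(traces = traces,
         truth = list(k_by_pH = k_by_pH, slope = d$slope,
                      intercept = d$intercept, wells = wells),
         design = d)
  })
}

format_ph <- function(pH) formatC(pH, format = "f", digits = 2)
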