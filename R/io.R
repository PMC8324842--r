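TRACE_COLUMNS <- c("sample_id", "plate_id", "replicate", "pH", "M0_uM",
                   "time_h", "fluorescence_au")

#' Read kinetic traces from a long-format CSV
#'
#' Fixed dialect: comma-separated, '.' decimal separator, UTF-8, mandatory
#' header with columns `sample_id, plate_id, replicate, pH, M0_uM, time_h,
#' fluorescence_au`. Rows are sorted by time within each sample; duplicate
#' (sample, time) rows and non-numeric cells are rejected with
#' line-numbered errors.
#'
#' @param path CSV file path.
#' @return A list of [kinetic_trace()] objects.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  missing_cols <- setdiff(TRACE_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0)
    stop("empty trace file: ", path, call. = FALSE)
  lines <- seq_len(nrow(df)) + 1L  # header is line 1
  for (col in c("pH", "M0_uM", "time_h", "fluorescence_au")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad) > 0)
      stop("non-numeric value in column '", col, "' at line ",
           lines[bad[1]], " of ", path, call. = FALSE)
    df[[col]] <- vals
  }
  dup <- duplicated(df[, c("sample_id", "time_h")])
  if (any(dup))
    stop("duplicated time point for sample '", df$sample_id[which(dup)[1]],
         "' at line ", lines[which(dup)[1]], " of ", path, call. = FALSE)
  traces <- lapply(split(seq_len(nrow(df)), df$sample_id), function(idx) {
    sub <- df[idx, ]
    ord <- order(sub$time_h)
    sub <- sub[ord, ]
    kinetic_trace(sub$time_h, sub$fluorescence_au,
                  M0 = sub$M0_uM[1], pH = sub$pH[1],
                  sample_id = sub$sample_id[1],
                  plate_id = sub$plate_id[1],
                  replicate = sub$replicate[1])
  })
  unname(traces[unique(df$sample_id)])
}

#' Write kinetic traces to a long-format CSV
#'
#' Inverse of [read_traces()]; the round trip is lossless for the trace
#' data and condition metadata.
#'
#' @param traces list of [kinetic_trace()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "kinetic_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr)
    data.frame(sample_id = tr$sample_id, plate_id = tr$plate_id,
               replicate = tr$replicate, pH = tr$pH, M0_uM = tr$M0,
               time_h = tr$t, fluorescence_au = tr$F))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  # output location is not part of the analysis configuration: reruns into
  # a different directory must produce identical artifacts
  config$out_dir <- NULL
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected
#' (fail-fast). Can be loaded from a YAML file via [read_run_config()].
#'
#' @param traces path to the input trace CSV.
#' @param out_dir output directory for `fit.json` and `trend.json`.
#' @param fix_n fixed shared reaction order (default 3) or `NULL` for a
#'   free order.
#' @param group_by rate-constant grouping key (default `"pH"`).
#' @param fit_F0 fit per-sample baselines (default `TRUE`).
#' @param weighting `"none"` or `"inv_amplitude"`.
#' @param truncation `"auto"` (detect and cut the fibril phase per trace)
#'   or `"none"`.
#' @param trend_weighting pH-trend regression weighting: `"none"`
#'   (default, mirrors an unweighted published analysis) or `"inv_var"`
#'   (1/SE^2 of log10 k from the global fit; appropriate when per-pH
#'   uncertainties differ strongly).
#' @param ph_pairs list of length-2 pH vectors for fold-change reports.
#' @param seed RNG seed recorded with the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(traces, out_dir, fix_n = 3, group_by = "pH",
                       fit_F0 = TRUE, weighting = "none",
                       truncation = c("auto", "none"),
                       trend_weighting = c("none", "inv_var"),
                       ph_pairs = list(c(7.3, 4.8)), seed = 1L) {
  truncation <- match.arg(truncation)
  trend_weighting <- match.arg(trend_weighting)
  structure(list(traces = traces, out_dir = out_dir, fix_n = fix_n,
                 group_by = group_by, fit_F0 = fit_F0,
                 weighting = weighting, truncation = truncation,
                 trend_weighting = trend_weighting,
                 ph_pairs = ph_pairs, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys must match the [run_config()] arguments
#'   exactly — unknown keys are rejected.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

#' Run the kinetics analysis pipeline
#'
#' Composes the trace-level workflow: read traces, truncate each to its
#' oligomerization phase (automatic second-phase detection), fit the
#' one-step model globally with the configured sharing structure, regress
#' log10 k on pH, and derive fold-change factors. Writes `fit.json` and
#' `trend.json` into the output directory; every artifact embeds the
#' config hash and package version, and the run is deterministic for fixed
#' inputs and seed.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return List with `fit` (a `global_fit`), `trend` (a `ph_trend`),
#'   `folds`, `onsets`, and the artifact `paths`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  traces <- read_traces(config$traces)
  if (length(traces) == 0)
    stop("stage read_traces: no traces in ", config$traces, call. = FALSE)

  onsets <- rep(NA_real_, length(traces))
  if (config$truncation == "auto") {
    for (i in seq_along(traces)) {
      tr <- traces[[i]]
      if (has_no_signal(tr)) next
      res <- tryCatch(
        auto_truncate(tr, n = config$fix_n %||% 3,
                      fit_F0 = config$fit_F0),
        error = function(e)
          stop("stage truncate [", tr$sample_id, "]: ",
               conditionMessage(e), call. = FALSE))
      traces[[i]] <- res$trace
      onsets[i] <- res$onset
    }
  }

  share <- share_spec(fix_n = config$fix_n, group_by = config$group_by,
                      fit_F0 = config$fit_F0, weighting = config$weighting)
  fit <- tryCatch(fit_global(traces, share),
                  error = function(e)
                    stop("stage fit_global: ", conditionMessage(e),
                         call. = FALSE))

  kt <- fit$k[fit$k$identifiable & is.finite(fit$k$k), ]
  trend <- NULL; folds <- NULL
  if (config$group_by == "pH" && nrow(kt) >= 2) {
    w <- if (config$trend_weighting == "inv_var" && all(kt$se > 0))
      (kt$k * log(10))^2 / kt$se^2 else NULL
    trend <- tryCatch(fit_log_linear(as.numeric(kt$group), kt$k,
                                     weights = w),
                      error = function(e)
                        stop("stage ph_trend: ", conditionMessage(e),
                             call. = FALSE))
    folds <- list(per_ph_unit = fold_per_ph_unit(trend))
    for (pair in config$ph_pairs)
      folds[[sprintf("pH%.2f_vs_pH%.2f", pair[1], pair[2])]] <-
        fold_between(trend, pair[1], pair[2])
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(package_version = as.character(utils::packageVersion("oligokin")),
                config_hash = config_hash(unclass(config)),
                seed = config$seed)
  fit_path <- file.path(config$out_dir, "fit.json")
  jsonlite::write_json(
    list(meta = stamp,
         share = unclass(share),
         n = list(estimate = fit$n_hat,
                  se = fit$n_se, fixed = fit$n_fixed),
         rate_constants = fit$k,
         nuisance = fit$nuisance,
         rss = fit$rss, dof = fit$dof,
         truncation = data.frame(
           sample_id = vapply(traces, `[[`, "", "sample_id"),
           onset_h = onsets),
         convergence = fit$convergence[c("iterations", "status",
                                         "converged")]),
    fit_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  trend_path <- NULL
  if (!is.null(trend)) {
    trend_path <- file.path(config$out_dir, "trend.json")
    jsonlite::write_json(
      list(meta = stamp,
           slope = trend$slope, slope_se = trend$slope_se,
           intercept = trend$intercept,
           intercept_se = trend$intercept_se,
           r_squared = trend$r_squared,
           points = trend$points,
           folds = folds),
      trend_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(fit = fit, trend = trend, folds = folds, onsets = onsets,
                 paths = c(fit = fit_path, trend = trend_path)))
}
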