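#' Parameter-sharing specification for global fits
#'
#' Describes the hierarchical structure of a global fit: one reaction order
#' shared by every trace (fixed or free), one oligomerization rate constant
#' per group of traces (grouped by a metadata key, by default pH), and
#' per-sample nuisance parameters (proportionality constant c and baseline
#' F0).
#'
#' @param fix_n fixed shared reaction order (> 1), or `NULL` to fit n as a
#'   free shared parameter.
#' @param group_by metadata key whose distinct values each receive one rate
#'   constant (default `"pH"`).
#' @param fit_F0 fit a per-sample fluorescence baseline (`TRUE`, default)
#'   or freeze F0 = 0.
#' @param weighting residual weighting: `"none"` (default) or
#'   `"inv_amplitude"` (per-trace 1/amplitude weights).
#' @return An object of class `share_spec`.
#' @export
share_spec <- function(fix_n = 3, group_by = "pH", fit_F0 = TRUE,
                       weighting = c("none", "inv_amplitude")) {
  weighting <- match.arg(weighting)
  if (!is.null(fix_n)) {
    if (!is.numeric(fix_n) || !is.finite(fix_n) || fix_n <= 1)
      stop("a fixed reaction order must be > 1", call. = FALSE)
  }
  structure(list(fix_n = fix_n, group_by = group_by, fit_F0 = fit_F0,
                 weighting = weighting),
            class = "share_spec")
}

trace_group <- function(trace, group_by) {
  if (group_by == "pH") return(format_ph(trace$pH))
  if (!is.null(trace[[group_by]])) return(as.character(trace[[group_by]]))
  if (!is.null(trace$meta[[group_by]]))
    return(as.character(trace$meta[[group_by]]))
  stop("trace '", trace$sample_id, "' has no metadata key '", group_by, "'",
       call. = FALSE)
}

# Robust screen for traces whose fluorescence rise is indistinguishable
# from noise. A trace carries signal if either (a) its running-median
# amplitude clearly exceeds the point-noise scale (catches fast,
# step-like rises), or (b) the time-fluorescence correlation is far
# beyond what i.i.d. noise produces (z ~ N(0,1) under the null; catches
# slow, weak but consistent rises).
has_no_signal <- function(trace) {
  F <- trace$F
  if (stats::sd(F) == 0) return(TRUE)
  w <- min(51, length(F)); if (w %% 2 == 0) w <- w - 1
  sm <- if (w >= 3) stats::runmed(F, w) else F
  amp <- max(sm) - min(sm)
  noise <- stats::mad(diff(F)) / sqrt(2)
  if (amp > 6 * noise) return(FALSE)
  z <- abs(stats::cor(trace$t, F)) * sqrt(length(F))
  !is.finite(z) || z < 6
}

# Deterministic, scale-aware starting value for k from the observed
# half-rise time via the n = 3 half-time formula t_half = 1/(2 k M0^2).
init_k <- function(trace) {
  F <- trace$F
  w <- min(21, length(F)); if (w %% 2 == 0) w <- w - 1
  sm <- if (w >= 3) stats::runmed(F, w) else F
  F0 <- stats::median(F[seq_len(min(3, length(F)))])
  amp <- max(sm) - F0
  half <- F0 + amp / 2
  idx <- which(sm >= half)
  t_half <- if (length(idx) == 0) trace$t[length(trace$t)]
            else max(trace$t[idx[1]], diff(trace$t[1:2]) / 2)
  1 / (2 * t_half * trace$M0^2)
}

# Per-trace linear solve of the nuisance parameters (c, F0) given the
# oligomer-mass profile x(t): variable projection of the separable model
# F = F0 + c * x. Rank-aware; c is clipped at 0 (positivity).
solve_nuisance <- function(F, x, fit_F0) {
  if (fit_F0) {
    X <- cbind(1, x)
    qrX <- qr(X)
    cf <- unname(qr.coef(qrX, F))
    cf[is.na(cf)] <- 0
    F0 <- cf[1]; cc <- cf[2]
    if (cc < 0) { cc <- 0; F0 <- mean(F) }
  } else {
    sx <- sum(x * x)
    cc <- if (sx > 0) sum(x * F) / sx else 0
    if (cc < 0) cc <- 0
    F0 <- 0
  }
  list(c = cc, F0 = F0, resid = F - F0 - cc * x)
}

#' Global hierarchical fit of many kinetic traces
#'
#' Joint least squares over all traces with the sharing structure of
#' `share`: a shared reaction order n (fixed or free), one oligomerization
#' rate constant k per group (default: per pH), and per-sample nuisance
#' parameters (c, F0). Internally the rate constants are optimized on the
#' log10 scale (positivity) by trust-region Levenberg-Marquardt, with the
#' linear nuisance parameters profiled out per trace (variable projection);
#' asymptotic standard errors come from the full-model Jacobian at the
#' optimum. Deterministic given data, bounds and initialization policy.
#'
#' @param traces list of [kinetic_trace()] objects (at least one per
#'   group), already truncated to the oligomerization phase (see
#'   [truncate_to_oligomer_phase()] / [auto_truncate()]) unless the caller
#'   accepts full traces.
#' @param share a [share_spec()].
#' @param n_starts number of deterministic multi-starts over n when n is
#'   free (ignored for fixed n).
#' @param log10k_halfwidth box half-width (decades) around the initial
#'   log10 k guesses.
#' @return An object of class `global_fit`: `n_hat`, `n_se`, `k` (data
#'   frame: group, k, se, n_traces, identifiable), `nuisance` (data frame:
#'   sample_id, c, F0, no_signal), `rss`, `dof`, `residuals` (named list),
#'   `convergence`, `share`.
#' @export
fit_global <- function(traces, share = share_spec(), n_starts = 5,
                       log10k_halfwidth = 6) {
  if (inherits(traces, "kinetic_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1, inherits(share, "share_spec"))
  lapply(traces, check_fit_trace)

  ids <- vapply(traces, function(tr) tr$sample_id, "")
  if (anyDuplicated(ids))
    stop("duplicate sample_id among traces: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  groups <- vapply(traces, trace_group, "", group_by = share$group_by)
  no_sig <- vapply(traces, has_no_signal, TRUE)

  grp_levels <- unique(groups)
  grp_dead <- vapply(grp_levels,
                     function(g) all(no_sig[groups == g]), TRUE)
  active_grp <- grp_levels[!grp_dead]
  if (length(active_grp) == 0)
    stop("no oligomerization signal in any group: nothing to fit",
         call. = FALSE)
  use <- groups %in% active_grp
  fit_traces <- traces[use]
  fit_groups <- groups[use]

  wts <- rep(1, length(fit_traces))
  if (share$weighting == "inv_amplitude")
    wts <- vapply(fit_traces,
                  function(tr) 1 / max(max(tr$F) - min(tr$F), 1e-12), 0)

  # initial log10 k per active group: median of per-trace half-rise guesses
  k0 <- vapply(active_grp, function(g) {
    cand <- vapply(fit_traces[fit_groups == g], init_k, 0)
    stats::median(cand)
  }, 0)
  lk0 <- log10(pmax(k0, 1e-300))
  free_n <- is.null(share$fix_n)

  residual_fun <- function(theta) {
    n <- if (free_n) theta[1] else share$fix_n
    lk <- if (free_n) theta[-1] else theta
    unlist(lapply(seq_along(fit_traces), function(i) {
      tr <- fit_traces[[i]]
      k <- 10^lk[match(fit_groups[i], active_grp)]
      x <- tr$M0 - mono_closed_form(tr$t, tr$M0, n, k)
      solve_nuisance(tr$F, x, share$fit_F0)$resid * wts[i]
    }), use.names = FALSE)
  }

  lower <- lk0 - log10k_halfwidth
  upper <- lk0 + log10k_halfwidth
  ctrl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12,
                                     ptol = 1e-10)
  run_lm <- function(theta0, lo, hi) {
    minpack.lm::nls.lm(par = theta0, fn = residual_fun,
                       lower = lo, upper = hi, control = ctrl)
  }

  if (free_n) {
    n_grid <- seq(2, 4, length.out = max(1, n_starts))
    fits <- lapply(n_grid, function(n0)
      run_lm(c(n0, lk0), c(1 + 1e-6, lower), c(10, upper)))
    best <- fits[[which.min(vapply(fits, function(f) f$deviance, 0))]]
  } else {
    best <- run_lm(lk0, lower, upper)
  }
  if (best$info == 0 || best$info > 5)
    stop("global fit did not converge (", best$message, ")", call. = FALSE)
  converged <- best$info %in% 1:4

  n_hat <- if (free_n) unname(best$par[1]) else share$fix_n
  lk_hat <- unname(if (free_n) best$par[-1] else best$par)
  k_hat <- 10^lk_hat
  names(k_hat) <- active_grp

  # reassemble nuisance parameters and residuals at the optimum
  nuis <- vector("list", length(fit_traces))
  resids <- vector("list", length(fit_traces))
  xs <- vector("list", length(fit_traces))
  for (i in seq_along(fit_traces)) {
    tr <- fit_traces[[i]]
    k <- k_hat[[match(fit_groups[i], active_grp)]]
    x <- tr$M0 - mono_closed_form(tr$t, tr$M0, n_hat, k)
    s <- solve_nuisance(tr$F, x, share$fit_F0)
    nuis[[i]] <- c(c = s$c, F0 = s$F0)
    resids[[i]] <- s$resid
    xs[[i]] <- x
  }

  # full-model Jacobian at the optimum (natural parameter scale):
  # columns [n (if free) | k per group | per-trace c (, F0)]
  n_rows <- sum(vapply(fit_traces, function(tr) length(tr$t), 0L))
  p_per_trace <- if (share$fit_F0) 2L else 1L
  p_total <- (if (free_n) 1L else 0L) + length(active_grp) +
    p_per_trace * length(fit_traces)
  J <- matrix(0, n_rows, p_total)
  colnames(J) <- c(if (free_n) "n",
                   paste0("k[", active_grp, "]"),
                   unlist(lapply(fit_traces, function(tr)
                     if (share$fit_F0)
                       paste0(c("c[", "F0["), tr$sample_id, "]")
                     else paste0("c[", tr$sample_id, "]"))))
  off_k <- if (free_n) 1L else 0L
  row0 <- 0L
  dn <- 1e-6 * max(1, n_hat)
  for (i in seq_along(fit_traces)) {
    tr <- fit_traces[[i]]
    gi <- match(fit_groups[i], active_grp)
    k <- k_hat[[gi]]
    rows <- row0 + seq_along(tr$t)
    m <- mono_closed_form(tr$t, tr$M0, n_hat, k)
    cc <- nuis[[i]][["c"]]
    # dF/dk = c * n * t * m^n  (from dm/dk = -n t A^(n/(1-n)) = -n t m^n)
    J[rows, off_k + gi] <- wts[i] * cc * n_hat * tr$t * m^n_hat
    ci <- off_k + length(active_grp) + p_per_trace * (i - 1L) + 1L
    J[rows, ci] <- wts[i] * xs[[i]]
    if (share$fit_F0) J[rows, ci + 1L] <- wts[i]
    if (free_n) {
      m_hi <- mono_closed_form(tr$t, tr$M0, n_hat + dn, k)
      m_lo <- mono_closed_form(tr$t, tr$M0, n_hat - dn, k)
      J[rows, 1L] <- wts[i] * cc * (m_lo - m_hi) / (2 * dn)
    }
    row0 <- row0 + length(tr$t)
  }

  rss <- sum(unlist(resids)^2)
  dof <- n_rows - p_total
  # Heteroscedasticity-robust (sandwich) covariance: plate noise scales
  # with each well's amplitude, so per-trace residual variances replace a
  # pooled sigma^2. cov = A^-1 B A^-1 with A = J'J and
  # B = sum_i sigma_i^2 J_i'J_i.
  sigma2_i <- vapply(seq_along(fit_traces), function(i) {
    ni <- length(resids[[i]])
    sum(resids[[i]]^2) / max(ni - p_per_trace - 1L, 1L)
  }, 0)
  row_s <- sqrt(rep(sigma2_i,
                    vapply(fit_traces, function(tr) length(tr$t), 0L)))
  A <- crossprod(J)
  B <- crossprod(J * row_s)
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  rank_deficient <- FALSE
  if (is.null(Ainv)) {
    sv <- svd(A)
    tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
    pos <- sv$d > tol
    rank_deficient <- any(!pos)
    if (rank_deficient) {
      null_w <- rowSums(abs(sv$v[, !pos, drop = FALSE]))
      culprits <- colnames(J)[null_w > 0.1 * max(null_w)]
      warning("Jacobian is rank-deficient; parameters involved: ",
              paste(culprits, collapse = ", "), call. = FALSE)
    }
    Ainv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
  cov <- Ainv %*% B %*% Ainv
  ses <- sqrt(pmax(diag(cov), 0))

  k_se <- ses[off_k + seq_along(active_grp)]
  k_df <- data.frame(group = grp_levels,
                     k = unname(k_hat[grp_levels]),
                     se = unname(k_se[match(grp_levels, active_grp)]),
                     n_traces = as.integer(table(groups)[grp_levels]),
                     identifiable = !grp_dead,
                     stringsAsFactors = FALSE)
  rownames(k_df) <- NULL

  nuis_idx <- off_k + length(active_grp) +
    p_per_trace * (seq_along(fit_traces) - 1L) + 1L
  nuis_df <- data.frame(sample_id = vapply(fit_traces, `[[`, "", "sample_id"),
                        c = vapply(nuis, `[[`, 0, "c"),
                        c_se = ses[nuis_idx],
                        F0 = vapply(nuis, `[[`, 0, "F0"),
                        F0_se = if (share$fit_F0) ses[nuis_idx + 1L]
                                else 0,
                        no_signal = no_sig[use],
                        stringsAsFactors = FALSE)
  names(resids) <- nuis_df$sample_id

  structure(list(n_hat = n_hat,
                 n_se = if (free_n) ses[1] else 0,
                 n_fixed = !free_n,
                 k = k_df,
                 nuisance = nuis_df,
                 rss = rss, dof = dof,
                 residuals = resids,
                 convergence = list(iterations = best$niter,
                                    status = best$info,
                                    converged = converged,
                                    message = best$message,
                                    rank_deficient = rank_deficient),
                 share = share),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Global one-step oligomerization fit: n = %.4g%s, %d group(s)\n",
              x$n_hat, if (x$n_fixed) " (fixed)" else
                sprintf(" +/- %.2g", x$n_se), nrow(x$k)))
  print(x$k, row.names = FALSE)
  cat(sprintf("  RSS = %.6g on %d dof (%d traces); %s after %d iterations\n",
              x$rss, x$dof, nrow(x$nuisance),
              if (x$convergence$converged) "converged" else "NOT converged",
              x$convergence$iterations))
  invisible(x)
}

#' Fit a single kinetic trace
#'
#' Least-squares fit of the one-step oligomerization signal model to one
#' trace: estimates (k, c, F0) with n fixed (default 3) or free. Thin
#' single-trace interface over [fit_global()] (to which the global fit
#' reduces exactly for one trace). A trace whose amplitude is
#' indistinguishable from noise raises a "no oligomerization signal" error
#' rather than returning a spurious zero.
#'
#' @param trace a [kinetic_trace()], already truncated to the
#'   oligomerization phase (or the caller accepts the full trace).
#' @param n fixed reaction order (> 1) or `NULL` to fit n.
#' @param fit_F0 fit the baseline (default) or freeze F0 = 0.
#' @return An object of class `trace_fit`: `params` (an
#'   [oligomer_params()] at the estimates), `se` (named: k, c, F0, and n if
#'   free), `rss`, `dof`, `residuals`, `convergence`.
#' @export
fit_trace <- function(trace, n = 3, fit_F0 = TRUE) {
  check_fit_trace(trace)
  if (has_no_signal(trace))
    stop("no oligomerization signal: trace '", trace$sample_id,
         "' has amplitude indistinguishable from noise", call. = FALSE)
  gf <- fit_global(list(trace),
                   share_spec(fix_n = n, group_by = "pH", fit_F0 = fit_F0))
  p <- oligomer_params(M0 = trace$M0, n = gf$n_hat, k = gf$k$k[1],
                       c = gf$nuisance$c[1], F0 = gf$nuisance$F0[1])
  se <- c(k = gf$k$se[1], c = gf$nuisance$c_se[1],
          F0 = gf$nuisance$F0_se[1])
  structure(list(params = p,
                 se = c(if (!gf$n_fixed) c(n = gf$n_se), se),
                 rss = gf$rss, dof = gf$dof,
                 residuals = gf$residuals[[1]],
                 convergence = gf$convergence,
                 global = gf),
            class = "trace_fit")
}

#' @export
print.trace_fit <- function(x, ...) {
  cat("Single-trace oligomerization fit\n")
  print(x$params)
  cat(sprintf("  k SE = %.3g; RSS = %.6g on %d dof\n",
              x$se[["k"]], x$rss, x$dof))
  invisible(x)
}

#' Detect the onset of the fibril (second) phase
#'
#' Scans the residuals of an oligomer-phase fit for the earliest run of
#' `run_len` consecutive points exceeding `z_thresh` times the robust
#' (MAD-based) residual scale of the fit window. The nucleated fibril
#' growth phase appears as a systematic positive residual excursion after
#' its lag time; the returned onset is where that excursion first becomes
#' detectable.
#'
#' @param trace a [kinetic_trace()] (the full trace, not truncated).
#' @param fit a [trace_fit()] or [oligomer_params()] describing the
#'   oligomer-phase model for this trace.
#' @param z_thresh detection threshold in robust-sigma units (default 4).
#' @param run_len required consecutive exceedances (default 5, minimum 3).
#' @param window upper end of the fit window (h) used for the residual
#'   scale; default the whole trace.
#' @return Onset time (h), or `NA_real_` if no second phase is detected.
#' @export
detect_second_phase_onset <- function(trace, fit, z_thresh = 4,
                                      run_len = 5, window = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (!is.numeric(z_thresh) || z_thresh <= 0)
    stop("z_thresh must be > 0", call. = FALSE)
  if (run_len < 3) stop("run_len must be >= 3", call. = FALSE)
  if (length(trace$t) < run_len)
    stop("trace shorter than run_len", call. = FALSE)
  p <- if (inherits(fit, "trace_fit")) fit$params else fit
  stopifnot(inherits(p, "oligomer_params"))
  model <- tht_signal(trace$t, p)
  resid <- trace$F - model
  in_win <- if (is.null(window)) rep(TRUE, length(resid))
            else trace$t <= window
  scale <- stats::mad(resid[in_win])
  if (!is.finite(scale) || scale <= 0)
    scale <- 1e-12 * max(1, max(abs(trace$F)))
  runs <- rle(resid > z_thresh * scale)
  ends <- cumsum(runs$lengths)
  hit <- which(runs$values & runs$lengths >= run_len)
  if (length(hit) == 0) return(NA_real_)
  start <- ends[hit[1]] - runs$lengths[hit[1]] + 1L
  trace$t[start]
}

#' Truncate a trace to its oligomerization phase
#'
#' Returns the sub-trace with t < onset (the whole trace when the onset is
#' `NA`); the truncation time is recorded in the trace metadata.
#'
#' @param trace a [kinetic_trace()].
#' @param onset onset time (h) from [detect_second_phase_onset()], or `NA`.
#' @return A [kinetic_trace()].
#' @export
truncate_to_oligomer_phase <- function(trace, onset) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (is.na(onset)) return(trace)
  keep <- trace$t < onset
  if (sum(keep) < 4)
    stop("truncation at ", onset,
         " h leaves fewer than 4 points: trace too short", call. = FALSE)
  meta <- trace$meta
  meta$truncated_at <- onset
  kinetic_trace(trace$t[keep], trace$F[keep], trace$M0, trace$pH,
                trace$sample_id, trace$plate_id, trace$replicate, meta)
}

window_subtrace <- function(trace, w) {
  keep <- trace$t <= w
  kinetic_trace(trace$t[keep], trace$F[keep], trace$M0, trace$pH,
                trace$sample_id, trace$plate_id, trace$replicate,
                trace$meta)
}

#' Automatically truncate a trace to its oligomerization phase
#'
#' Two-stage procedure. First, the fit window is shrunk geometrically
#' until the one-step model fits it to within the point noise (robust
#' residual scale below `clean_factor` times the first-difference noise
#' estimate): a window still containing the fibril phase shows structured
#' misfit that would mask the detector. Second, fit / detect / truncate
#' iterates until the detected onset stabilizes. Traces without a second
#' phase are returned unchanged.
#'
#' @inheritParams fit_trace
#' @inheritParams detect_second_phase_onset
#' @param max_iter maximum fit/detect iterations per stage.
#' @param clean_factor a window counts as cleanly fitted when the robust
#'   scale of its fit residuals is below `clean_factor` times the
#'   point-noise estimate.
#' @return List with `trace` (truncated), `onset` (h or `NA`) and `fit`
#'   (the final [fit_trace()] on the retained window).
#' @export
auto_truncate <- function(trace, n = 3, z_thresh = 4, run_len = 5,
                          max_iter = 10, clean_factor = 3, fit_F0 = TRUE) {
  t_max <- trace$t[length(trace$t)]
  w <- t_max
  fit <- NULL
  # stage 1: find an initial window the oligomer model fits cleanly
  for (i in seq_len(max_iter)) {
    wtr <- window_subtrace(trace, w)
    fit <- fit_trace(wtr, n = n, fit_F0 = fit_F0)
    scale_fit <- stats::mad(fit$residuals)
    noise <- stats::mad(diff(wtr$F)) / sqrt(2)
    if (noise <= 0 || scale_fit <= clean_factor * noise) break
    w_new <- w * 0.7
    if (sum(trace$t <= w_new) < max(8, run_len)) break
    w <- w_new
  }
  # stage 2: iterate fit / detect / truncate until the onset stabilizes
  onset <- NA_real_
  for (i in seq_len(max_iter)) {
    new_onset <- detect_second_phase_onset(
      trace, fit, z_thresh = z_thresh, run_len = run_len, window = w)
    if (is.na(new_onset) || (!is.na(onset) && new_onset >= onset)) {
      if (!is.na(new_onset)) onset <- new_onset
      break
    }
    onset <- new_onset
    if (sum(trace$t < onset) < 4) break
    w <- onset
    fit <- fit_trace(truncate_to_oligomer_phase(trace, onset),
                     n = n, fit_F0 = fit_F0)
  }
  out <- if (is.na(onset)) trace
         else truncate_to_oligomer_phase(trace, onset)
  list(trace = out, onset = onset, fit = fit)
}

#' Estimate the critical oligomer concentration (COC)
#'
#' The fluorescence amplitude of the lag-free oligomerization phase scales
#' linearly with total protein concentration above the COC; extrapolating
#' the amplitude-versus-concentration line to zero amplitude estimates the
#' COC as its x-intercept. Ordinary least squares through the points above
#' the noise floor; the intercept SE follows by error propagation from the
#' slope/intercept covariance.
#'
#' @param M0 protein concentrations, uM.
#' @param amplitude matching oligomer-phase fluorescence amplitudes, a.u.
#' @param noise_floor amplitude noise floor, a.u.; points at or below it
#'   are excluded.
#' @return An object of class `coc_estimate`: `coc` (uM, clipped at 0),
#'   `se`, `slope`, `slope_se`, `points_used`, `noise_floor`.
#' @examples
#' estimate_coc(c(2, 3, 4), c(1, 2, 3))$coc  # exact x-intercept: 1
#' @export
estimate_coc <- function(M0, amplitude, noise_floor = 0) {
  if (length(M0) != length(amplitude))
    stop("M0 and amplitude lengths differ", call. = FALSE)
  use <- is.finite(M0) & is.finite(amplitude) & amplitude > noise_floor
  if (sum(use) < 2)
    stop("insufficient data: at least 2 points above the noise floor are ",
         "required", call. = FALSE)
  x <- M0[use]; y <- amplitude[use]
  fit <- stats::lm(y ~ x)
  b <- stats::coef(fit)
  if (!is.finite(b[2]) || b[2] <= 0)
    stop("fitted amplitude-vs-concentration slope is nonpositive: ",
         "no COC can be estimated", call. = FALSE)
  xint <- -b[1] / b[2]
  V <- suppressWarnings(stats::vcov(fit))  # exact lines are legitimate
  grad <- c(-1 / b[2], b[1] / b[2]^2)
  se <- sqrt(max(drop(t(grad) %*% V %*% grad), 0))
  structure(list(coc = max(0, unname(xint)), se = unname(se),
                 slope = unname(b[2]),
                 slope_se = sqrt(V[2, 2]),
                 points_used = sum(use), noise_floor = noise_floor,
                 fit = fit),
            class = "coc_estimate")
}

#' @export
print.coc_estimate <- function(x, ...) {
  cat(sprintf(
    "COC estimate: %.3g +/- %.2g uM (slope %.3g a.u./uM, %d points, floor %g)\n",
    x$coc, x$se, x$slope, x$points_used, x$noise_floor))
  invisible(x)
}
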