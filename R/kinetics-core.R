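#' Parameters of the one-step oligomerization model
#'
#' Bundles the parameters of the closed-form one-step oligomerization rate
#' law nM -> M_n together with the affine ThT signal mapping. Monomer mass
#' concentration decays as dm/dt = -n k m^n from m(0) = M0, so the oligomer
#' mass concentration is
#' \deqn{M_{A\beta O}(t) = M_0 - [M_0^{1-n} + (n-1) n k t]^{1/(1-n)}}
#' and the observed fluorescence is F(t) = F0 + c * M_AbO(t).
#'
#' @param M0 total protein concentration, uM (monomer equivalents). Must be
#'   positive.
#' @param n reaction order / oligomer size (dimensionless, real). The closed
#'   form requires n > 1; the model is strictly super-linear.
#' @param k oligomerization rate constant, uM^(1-n) h^-1. Non-negative.
#' @param c fluorescence proportionality constant, a.u. per uM of oligomer
#'   mass. Non-negative.
#' @param F0 fluorescence baseline, a.u.
#' @return An object of class `oligomer_params`.
#' @examples
#' p <- oligomer_params(M0 = 2, n = 3, k = 0.01)
#' monomer_remaining(12.5, p)  # the n = 3 half-time: 1/(2 k M0^2) = 12.5 h
#' @export
oligomer_params <- function(M0, n, k, c = 1, F0 = 0) {
  stopifnot(is.numeric(M0), is.numeric(n), is.numeric(k),
            is.numeric(c), is.numeric(F0))
  if (!is.finite(M0) || M0 <= 0)
    stop("M0 must be a finite positive concentration (uM)", call. = FALSE)
  if (!is.finite(n) || n <= 1)
    stop("unsupported reaction order: the closed-form model requires n > 1",
         call. = FALSE)
  if (!is.finite(k) || k < 0)
    stop("k must be a finite non-negative rate constant", call. = FALSE)
  if (!is.finite(c) || c < 0)
    stop("c must be a finite non-negative proportionality constant",
         call. = FALSE)
  if (!is.finite(F0))
    stop("F0 must be finite", call. = FALSE)
  structure(list(M0 = M0, n = n, k = k, c = c, F0 = F0),
            class = "oligomer_params")
}

#' @export
print.oligomer_params <- function(x, ...) {
  cat("One-step oligomerization model parameters\n")
  cat(sprintf("  M0 = %g uM, n = %g, k = %g uM^(1-n) h^-1\n",
              x$M0, x$n, x$k))
  cat(sprintf("  signal: F(t) = %g + %g * M_AbO(t)\n", x$F0, x$c))
  invisible(x)
}

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("times must be finite numeric values (hours)", call. = FALSE)
  if (any(t < 0))
    stop("negative time is outside the model domain", call. = FALSE)
  t
}

#' Remaining monomer concentration under the one-step model
#'
#' Evaluates the monomer complement of the closed-form solution,
#' m(t) = \[M0^(1-n) + (n-1) n k t\]^(1/(1-n)), the solution of
#' dm/dt = -n k m^n with m(0) = M0.
#'
#' @param t time(s), hours; non-negative.
#' @param p an [oligomer_params()] object.
#' @return Monomer concentration(s), uM; strictly decreasing in t when
#'   k > 0, constant at M0 when k = 0.
#' @export
monomer_remaining <- function(t, p) {
  stopifnot(inherits(p, "oligomer_params"))
  t <- check_time(t)
  mono_closed_form(t, p$M0, p$n, p$k)
}

# closed form without class overhead; used in fitting hot loops
mono_closed_form <- function(t, M0, n, k) {
  (M0^(1 - n) + (n - 1) * n * k * t)^(1 / (1 - n))
}

#' Oligomer mass concentration under the one-step model
#'
#' M_AbO(t) = M0 - m(t): zero at t = 0, nondecreasing, with asymptote M0.
#'
#' @inheritParams monomer_remaining
#' @return Oligomer mass concentration(s), uM.
#' @export
oligomer_mass <- function(t, p) {
  p$M0 - monomer_remaining(t, p)
}

#' ThT fluorescence predicted by the one-step model
#'
#' Affine signal model F(t) = F0 + c * M_AbO(t). The proportionality
#' constant c is sample-specific in plate data (ThT brightness varies with
#' pH and well); the baseline F0 absorbs the plate offset and may be frozen
#' to zero in fits.
#'
#' @inheritParams monomer_remaining
#' @return Fluorescence, a.u.
#' @export
tht_signal <- function(t, p) {
  p$F0 + p$c * oligomer_mass(t, p)
}

#' Numerically integrate the oligomerization rate law
#'
#' Independent oracle for the closed form: integrates dm/dt = -n k m^n from
#' m(0) = M0 with `deSolve` and returns the oligomer mass M0 - m on the
#' requested grid. Agreement with [oligomer_mass()] to within
#' `max(rtol, 1e-6)` relative is part of the package's validation contract.
#'
#' @param t_grid increasing time grid, hours, starting at 0 (a grid not
#'   containing 0 is integrated from 0 internally).
#' @param p an [oligomer_params()] object.
#' @param rtol relative integration tolerance, in (0, 1e-3].
#' @return Oligomer mass concentrations on `t_grid`, uM.
#' @export
integrate_rate_law <- function(t_grid, p, rtol = 1e-8) {
  stopifnot(inherits(p, "oligomer_params"))
  t_grid <- check_time(t_grid)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  if (!is.numeric(rtol) || rtol <= 0 || rtol > 1e-3)
    stop("rtol must lie in (0, 1e-3]", call. = FALSE)
  prepend <- t_grid[1] > 0
  times <- if (prepend) c(0, t_grid) else t_grid
  deriv <- function(t, y, parms) list(-parms$n * parms$k * y^parms$n)
  sol <- deSolve::ode(y = c(m = p$M0), times = times, func = deriv,
                      parms = list(n = p$n, k = p$k),
                      rtol = rtol, atol = rtol * p$M0 * 1e-3)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("numerical integration of the rate law failed (istate = ",
         diagn[1], ")", call. = FALSE)
  m <- sol[, "m"]
  if (any(!is.finite(m)))
    stop("numerical integration of the rate law produced non-finite values",
         call. = FALSE)
  if (prepend) m <- m[-1]
  p$M0 - m
}

#' A single well's kinetic trace
#'
#' Container for one ThT time course with its condition metadata. Times are
#' in hours with t = 0 at reaction start (buffer injection); any
#' pre-injection reads must be offset before construction.
#'
#' @param t sampling times, hours; strictly increasing, first value >= 0.
#' @param F fluorescence readings, a.u.; same length as `t`.
#' @param M0 total protein concentration of the well, uM.
#' @param pH buffer pH, in \[2, 12\].
#' @param sample_id,plate_id,replicate identifiers.
#' @param meta optional free-form metadata list.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(t, F, M0, pH,
                          sample_id = "sample", plate_id = "plate",
                          replicate = 1L, meta = list()) {
  if (!is.numeric(t) || !is.numeric(F))
    stop("t and F must be numeric", call. = FALSE)
  if (length(t) != length(F))
    stop("t and F must have the same length", call. = FALSE)
  if (length(t) < 1) stop("empty trace", call. = FALSE)
  if (any(!is.finite(t)) || any(!is.finite(F)))
    stop("non-finite values in trace", call. = FALSE)
  if (t[1] < 0) stop("t[1] must be >= 0", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("t must be strictly increasing", call. = FALSE)
  if (!is.finite(M0) || M0 <= 0) stop("M0 must be positive", call. = FALSE)
  if (!is.finite(pH) || pH < 2 || pH > 12)
    stop("pH must lie in [2, 12]", call. = FALSE)
  structure(list(t = t, F = F, M0 = M0, pH = pH,
                 sample_id = as.character(sample_id),
                 plate_id = as.character(plate_id),
                 replicate = replicate, meta = meta),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf(
    "Kinetic trace '%s' (plate %s, rep %s): %d points, %.2f-%.2f h, %g uM, pH %.2f\n",
    x$sample_id, x$plate_id, as.character(x$replicate), length(x$t),
    x$t[1], x$t[length(x$t)], x$M0, x$pH))
  if (!is.null(x$meta$truncated_at))
    cat(sprintf("  truncated to the oligomer phase at %.3f h\n",
                x$meta$truncated_at))
  invisible(x)
}

check_fit_trace <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (length(trace$t) < 4)
    stop("trace '", trace$sample_id,
         "' has fewer than 4 points; too short to fit", call. = FALSE)
  invisible(trace)
}
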