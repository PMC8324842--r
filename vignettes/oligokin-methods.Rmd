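---
title: "Methods: one-step oligomerization kinetics, pH trends, and AFM morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-step oligomerization kinetics, pH trends, and AFM morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligokin)
```

## The kinetic model

Metastable amyloid-beta oligomers (AbOs) form by a lag-free, effectively
one-step association of `n` monomer-equivalents, `nM -> M_n`. Writing
`m(t)` for the remaining monomer mass concentration, the rate law
`dm/dt = -n k m^n` with `m(0) = M0` has the closed-form solution

$$m(t) = \left[M_0^{1-n} + (n-1)\,n\,k\,t\right]^{1/(1-n)},
\qquad M_{A\beta O}(t) = M_0 - m(t),$$

valid for `n > 1`. The model deliberately excludes nucleation: the
oligomerization phase shows no lag, in contrast to the fibril phase that
may follow. Units are hours and micromolar throughout, so `k` carries
`uM^(1-n) h^-1`; these match plate-reader time axes and assay
concentrations, and no other unit convention is supported.

ThT fluorescence reports oligomer mass through an affine per-well map
`F(t) = F0 + c * M_AbO(t)`. The proportionality constant `c` is
well-specific (ThT brightness depends on pH and well conditions) and is
always a free nuisance parameter. The baseline `F0` is included even
though a pure proportionality would suffice in an idealized assay —
real plate data always carry an offset — and can be frozen to zero
(`fit_F0 = FALSE`) for pre-normalized traces. Whether the original
analyses included a baseline is not documented; fitting it is the safer
default and costs one degree of freedom per well.

`n = 1` (and below) is rejected rather than special-cased with the
exponential solution: the science of interest is strictly
super-linear self-association, and silently switching solution families
would mask unit or input errors. `n` is a real parameter; concentration
scans have previously supported `n ≈ 3.3`, and the canonical analysis
fixes `n = 3`.

An independent numerical oracle, `integrate_rate_law()`, integrates the
same ODE with `deSolve` and must agree with the closed form to 1e-6
relative; this equivalence is asserted over randomized parameter sets in
the test suite.

## Global fitting

`fit_global()` implements the hierarchical sharing structure of a
pH/concentration plate: one reaction order `n` for every trace (fixed by
default, optionally free), one rate constant `k` per group of traces
(grouped by pH by default), and `(c, F0)` per well.

Numerically the problem is separable: for fixed `(n, k)` the per-well
`(c, F0)` enter linearly and are profiled out by a rank-aware linear
least-squares solve per trace (variable projection), with `c` clipped at
zero. The outer optimization over `log10 k` per group (and `n` when
free) uses trust-region Levenberg-Marquardt (`minpack.lm`), with box
bounds spanning ±6 decades around the initial guesses, and convergence
tolerances `ftol = 1e-12`, `ptol = 1e-10`. Optimizing `log10 k` enforces
positivity and equalizes step scales across groups whose rate constants
span several decades. Initialization is deterministic and scale-aware:
`k` starts at `1/(2 t_half M0^2)` from the observed half-rise time (the
exact relation for `n = 3`), `c` at the amplitude over `M0`, `F0` at the
median of the first three points. Free-`n` fits run a small
deterministic multi-start over `n in [2, 4]`.

Standard errors come from the full-model Jacobian at the optimum,
assembled analytically (`dF/dk = c n t m^n`, `dF/dc = M_AbO`,
`dF/dF0 = 1`; the `n` column numerically). Because plate noise scales
with each well's fluorescence amplitude — wells differ ~20-fold in
amplitude across a pH series — a pooled-variance covariance would
understate the uncertainty of the rate constants; the package therefore
uses a heteroscedasticity-robust sandwich covariance with per-trace
residual variances. In plate simulations at 1% amplitude noise the
resulting 2-SE intervals cover the generating rate constants at close to
their nominal rate (the acceptance suite asserts >= 90% pooled
coverage), which a pooled-variance covariance does not achieve.

Residuals are unweighted by default, mirroring a plain least-squares
published analysis; optional per-trace `1/amplitude` weighting is
available (`share_spec(weighting = "inv_amplitude")`).

Traces whose rise is indistinguishable from noise are screened out
before fitting (and raise an explicit "no oligomerization signal" error
in single-trace fits): a trace counts as carrying signal if its
running-median amplitude clearly exceeds the point-noise scale
(step-like fast rises) or if its time-fluorescence correlation is far
beyond the i.i.d.-noise null (slow weak rises). A group consisting
entirely of such traces keeps its place in the result table but is
flagged unidentifiable rather than given a fabricated rate constant.
Jacobian rank deficiency (e.g. two nuisance parameters degenerate on a
plateau-only trace) triggers a pseudo-inverse fallback and a warning
naming the parameters involved.

## Second-phase detection and truncation

Above the critical concentration at near-neutral pH, a nucleated fibril
growth phase follows the oligomerization phase after a lag. Only the
initial phase is fitted mechanistically; the second phase is detected
and cut off.

`detect_second_phase_onset()` declares an onset at the earliest run of
`run_len` (default 5) consecutive residuals exceeding `z_thresh`
(default 4) times the MAD-based robust scale of the fit-window
residuals. The defaults trade sensitivity against false positives: with
4-sigma exceedances and a 5-point run requirement, noise-only traces
essentially never trigger (the acceptance suite bounds the
false-positive rate at 2% over 500 simulated traces).

`auto_truncate()` makes the detector usable without a hand-picked fit
window. A window still containing the fibril phase inflates the robust
residual scale and masks the excursion, so the window is first shrunk
geometrically (factor 0.7) until the one-step model fits it to within
three times the point-noise estimate; fit / detect / truncate then
iterates until the onset stabilizes. The original analyses fitted "the
initial phase" without documenting how it was delimited; this automatic
procedure is this package's construction, and an explicit fit window
remains available by truncating manually.

In the synthetic generator the fibril phase is a phenomenological
logistic. Its `lag` parameter marks the onset of detectable fibril
signal — the sigmoid's 1% point, with the midpoint at
`lag + steepness * ln(99)` — because in nucleated polymerization the
lag time denotes the delay before detectable growth, not the sigmoid
midpoint. A detector scanning for the signal's departure from baseline
can only ever recover the former; anchoring the parameter there makes
"detected onset ~ lag" the meaningful recovery statement that the tests
assert.

## pH trend and fold changes

`fit_log_linear()` regresses `log10 k` on pH by ordinary least squares;
base-10 logarithms are used throughout so that a slope `s` converts to
`10^|s|`-fold change per pH unit (`fold_per_ph_unit()`) and
`10^(|s| |pH_a - pH_b|)` between two pH values (`fold_between()`). The
regression is unweighted by default; `1/SD^2` weights are available and
are the appropriate choice when per-pH uncertainties differ strongly —
in plate fits the endpoint pH values carry both the largest leverage and
the largest `log10 k` errors, where an unweighted residual variance
understates the slope uncertainty. Folds are never rounded internally;
two-significant-figure rounding is presentation only.

No protonation-site (Hill/ionization) model is fitted: the package
reports the empirical log-linear trend only, over the pH range actually
fitted; `predict_k()` flags extrapolation outside that range rather
than refusing it.

## COC estimation

The critical oligomer concentration is estimated from the linear scaling
of oligomer-phase amplitude with total concentration: an ordinary
least-squares line through the points above a caller-supplied noise
floor, with the COC as its x-intercept (clipped at zero) and its SE by
error propagation from the slope/intercept covariance. At least two
points above the floor are required; a nonpositive slope is an explicit
no-COC diagnostic. On exactly collinear input the estimator is exact
with zero SE. Whether the published "around 1 uM" figure came from a
formal intercept fit or visual assessment is not documented; the
x-intercept definition is this package's concrete choice.

## AFM morphometry

`flatten_scanlines()` performs per-scan-line polynomial background
subtraction (default order 1, configurable 0-3; the original processing
does not document the order) with iterative particle masking: pixels
whose residual exceeds `sigma_mask` (default 2) robust scales are
excluded and the line refitted, `n_iter` (default 3) times — the
"first independently, then limited data range" two-pass scheme, with
the unquantified "limited data range" interpreted as this masked refit.
Flattening is exact on tilted planes and idempotent on flat images.

`segment_particles()` is a morphological active-contours-without-edges
(Chan-Vese) evolution on a binary level set: region force from the
two-region mean separation, curvature smoothing by the sup-inf/inf-sup
morphological operators over four line structuring elements,
initialization from a robust height threshold (`init_sigma`, default 3,
times the image MAD), fixed iteration budget, fully deterministic. A
plain-threshold fallback is provided; on clean images both find the same
particles, though the Chan-Vese boundary settles near the inter-region
midpoint height and therefore sits strictly inside the threshold
region on smooth-edged particles — component identity, not pixel
identity, is the invariant the tests assert. Components below
`min_area_px` (default 4) are discarded. Height distributions collect
every masked pixel's height; quartiles use the linear-interpolation
convention (type 7), stated because reported IQRs depend on it. No
tip-convolution correction is applied: dried-state raw heights are the
quantity of interest.

## Synthetic data: what it does and does not emulate

`simulate_plate()` generates the studied design by default: pH
{4.8, 5.6, 6.0, 6.4, 6.8, 7.2, 7.6} × {0.65, 1.25, 2.5, 5} uM × 2
replicates, sampled every 0.05 h for 40 h; `log10 k = 7.9 - 1.56 pH`,
placing half-times from minutes (acidic, high concentration) to beyond
the assay window (neutral, low concentration), which is the
identifiability regime the real plates present; ThT brightness halving
per pH unit below 6 (the acidic brightness drop is documented
qualitatively but not quantified — the multiplier is an explicit
placeholder); 5% lognormal per-well brightness jitter; Gaussian i.i.d.
noise with sd 1% of each well's plateau amplitude. The rate-law
intercept 7.9 was chosen once so that the generated plate spans
observable and step-like/slow traces the way the published traces do.
Per-well jitter and fibril lags are part of the stochastic truth drawn
from the design seed, and the full truth (every well's generating
parameters) is returned for recovery tests.

Not emulated: drift and photobleaching, ThT binding photophysics,
mechanistic fibril kinetics (the logistic second phase has shape realism
only, for detector tests), well-to-well temperature gradients, and any
COC mechanism (generated amplitudes are strictly proportional to
`c * M0`). Passing recovery tests on this generator therefore
demonstrates correctness of the estimation machinery under the model's
own assumptions plus realistic noise structure — not robustness to
model misspecification in real plates.

`simulate_afm_image()` builds spherical-cap particles (presets: ~4 nm
apex oligomers, ~100 nm apex clusters) on a tilted background with
per-scan-line offsets and Gaussian roughness, returning the analytic
mask and noise-free heights as ground truth. Real AFM artefacts not
emulated: tip convolution, feedback overshoot, thermal drift within a
line, and correlated line noise.

## Problem sizes and numerical tolerances used in validation

The test suite validates closed-form/ODE equivalence on 100 random
parameter sets (1e-6 relative), mass conservation and monotonicity on
1000 draws, plate recovery coverage on 100 simulated plates of 56 traces
each, onset detection on 20 biphasic traces plus 500 noise-only traces,
and AFM recall on 50 simulated 128×128 images with 6 planted particles
each. These sizes were chosen to give stable proportions (binomial sd
about 1-3%) while keeping the default suite fast enough to run
routinely.

## Known limitations

- Asymptotic (sandwich) standard errors; no bootstrap or posterior
  sampling. Coverage is validated by simulation at the design noise
  level, not guaranteed at much higher noise.
- The one-step model cannot describe secondary nucleation or
  fibril-oligomer competition; traces dominated by the fibril phase
  should be truncated or excluded.
- The automatic truncation assumes the oligomer phase precedes the
  fibril phase and that the latter is an upward excursion.
- Replicate-level error bars (mean ± SD of per-assay rate constants)
  require fitting assays separately; `fit_global()` pools replicates
  within a group when they share one `k`.
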