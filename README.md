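# oligokin

Kinetic analysis of pH-dependent amyloid-beta oligomer (AbO) formation.

Metastable AbOs — spherical/curvilinear, beta-sheet-rich assemblies
distinct from amyloid fibrils — form without a lag phase by an
effectively one-step association of `n` monomers, `nM -> M_n`. Monitored
by thioflavin-T (ThT) fluorescence in a plate reader, the oligomer mass
concentration follows the closed form

```
M_AbO(t) = M0 - [ M0^(1-n) + (n-1) n k t ]^(1/(1-n)),      n > 1
F(t)     = F0 + c * M_AbO(t)
```

with `M0` the total protein concentration (uM), `k` the oligomerization
rate constant (uM^(1-n) h^-1), `n` the reaction order / oligomer size,
and `(c, F0)` a per-well fluorescence calibration. Fitted globally
across a pH × concentration plate — one shared `n`, one `k` per pH,
`(c, F0)` per well — the rate constants follow a log-linear pH trend
whose slope converts directly into fold-change statements about
oligomerization at endo-lysosomal versus interstitial pH.

The package is aimed at biophysical chemists analysing amyloid
self-assembly plate assays. It provides:

- `monomer_remaining()`, `oligomer_mass()`, `tht_signal()` — the closed
  forms — and `integrate_rate_law()`, an independent ODE oracle;
- `fit_trace()` / `fit_global()` — separable (variable-projection)
  nonlinear least squares with the plate's parameter-sharing structure
  and heteroscedasticity-robust standard errors;
- `detect_second_phase_onset()` / `auto_truncate()` — detection and
  removal of the nucleated fibril growth phase that follows the
  oligomer phase after a lag;
- `estimate_coc()` — critical oligomer concentration by
  amplitude-versus-concentration extrapolation;
- `fit_log_linear()`, `fold_per_ph_unit()`, `fold_between()`,
  `predict_k()` — the pH trend and its derived fold factors;
- `flatten_scanlines()`, `segment_particles()`,
  `height_distribution()` — AFM topograph flattening (per-scan-line
  polynomials with particle masking), morphological Chan-Vese particle
  segmentation, and per-pixel height statistics;
- `build_dimab()`, `average_mass()`, `oligomer_stoichiometry()`,
  `mass_volume_convert()`, `vesicle_copy_number()` — the sequence-mass,
  stoichiometry and vesicle copy-number arithmetic behind oligomer mass
  interpretation;
- `plate_design()` / `simulate_plate()` / `simulate_biphasic_trace()` /
  `simulate_afm_image()` — ground-truthed synthetic data generators for
  validation;
- `read_traces()` / `write_traces()` / `run_pipeline()` — CSV I/O and
  the composed simulate → truncate → fit → trend workflow (a thin shell
  wrapper lives in `inst/scripts/run-pipeline.R`).

## Worked example

Simulate the studied plate design (pH 4.8–7.6, 0.65–5 uM, duplicate
wells, 1% noise), fit it globally with `n = 3`, and read off the pH
trend:

```r
library(oligokin)

plate <- simulate_plate(plate_design(seed = 42))
csv <- tempfile(fileext = ".csv")
write_traces(plate$traces, csv)

res <- run_pipeline(run_config(traces = csv, out_dir = tempdir(),
                               fix_n = 3, truncation = "none",
                               trend_weighting = "inv_var"))
res$fit
#> Global one-step oligomerization fit: n = 3 (fixed), 7 group(s)
#>  group            k           se n_traces identifiable
#>   4.80 2.5755346267 5.435186e-02        8         TRUE
#>   5.60 0.1464626467 1.785749e-03        8         TRUE
#>   6.00 0.0346652888 3.442065e-04        8         TRUE
#>   6.40 0.0082798821 6.924191e-05        8         TRUE
#>   6.80 0.0019737180 1.653966e-05        8         TRUE
#>   7.20 0.0004695101 6.616960e-06        8         TRUE
#>   7.60 0.0001109002 5.586795e-06        8         TRUE
#>   RSS = 3.15361e+07 on 44737 dof (56 traces); converged after 6 iterations
res$trend
#> pH trend of log10(k): slope -1.558 +/- 0.001 per pH unit (R^2 = 1.0000)
#>   36-fold change in k per pH unit
```

Each row is one pH group's oligomerization rate constant with its
standard error; the trend slope of −1.56 decades per pH unit means a
~36-fold acceleration of AbO formation per pH unit of acidification,
and `fold_between(res$trend, 7.3, 4.8)` (~7.9 × 10^3) the acceleration
between interstitial and endo-lysosomal pH. The generating design used
slope −1.56, so the pipeline recovers it within its reported
uncertainty.

Desk-scale arithmetic behind oligomer mass interpretation:

```r
estimate_coc(c(2, 3, 4, 5), c(1, 2, 3, 4))
#> COC estimate: 1 +/- 4.4e-17 uM (slope 1 a.u./uM, 4 points, floor 0)

build_dimab()
#> Peptide construct 'dimAb': 101 residues, 10.03 kDa (average mass)

oligomer_stoichiometry(62, build_dimab()$average_mass / 1000)$count
#> [1] 6        # a hexamer of tandem dimers = 12 Ab40 units

vesicle_copy_number(2.5, 0.3)
#> [1] 451.6606  # ~450 molecules per endosome
```

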