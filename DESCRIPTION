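Package: oligokin
Title: Kinetic Analysis of pH-Dependent Amyloid-Beta Oligomer Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing thioflavin-T (ThT) plate-reader kinetics of
    lag-free amyloid-beta oligomer (AbO) formation. Implements the closed-form
    one-step oligomerization model nM -> M_n, hierarchical (global)
    least-squares fitting of concentration- and pH-dependent trace families
    with a shared reaction order and per-pH rate constants, log-linear
    analysis of rate constants versus pH with derived fold-change factors,
    critical oligomer concentration (COC) estimation by amplitude
    extrapolation, detection and truncation of the nucleated fibril-growth
    second phase, AFM topograph flattening and particle-height morphometry,
    and the sequence-mass and vesicle copy-number arithmetic used to
    interpret oligomer stoichiometry. A synthetic-data module generates
    plate-reader datasets and AFM height maps with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    EBImage,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    knitr,
    rmarkdown
Config/testthat/edition: 3
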