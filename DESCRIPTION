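Package: serialbsi
Title: Boundary Shift Integral Atrophy Measurement and Serial MRI Study
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying longitudinal brain volume change from
    co-registered serial MRI and for studying how acquisition protocol affects
    such measurements. Implements the boundary shift integral (BSI) family of
    direct change measures (k-means normalised KN-BSI for whole brain, fixed
    intensity window for ventricles, double window for hippocampi) with
    differential bias correction; a linear mixed model for repeated measures of
    direct change with diagnosis-specific random slopes, signed visit effects
    and scan-type-specific residual variances, including the likelihood-ratio
    test for a protocol effect on measurement error; paired agreement
    statistics (paired t, Pitman-Morgan, Bland-Altman, McNemar, Cohen's kappa,
    covariate-adjusted differences with BCa bootstrap intervals); per-arm
    clinical-trial sample-size estimation with bootstrap intervals; and a
    synthetic-data module that generates serial MRI phantoms with known
    ground-truth volume change, scan-type-dependent noise, motion artifacts,
    simulated cohorts and paired quality-control outcomes, so the full pipeline
    runs end-to-end without any real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
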