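# serialbsi

Quantifying longitudinal brain volume change from serial MRI, and testing
whether a faster (parallel-imaging, "accelerated") acquisition protocol can
replace the standard one without degrading those measurements.

Serial T1-weighted MRI lets each participant act as their own control: the
ml-scale change of the whole brain, the lateral ventricles or the hippocampi
between two co-registered scans is a sensitive marker of neurodegeneration
and a common clinical-trial outcome in Alzheimer's disease. `serialbsi` is
aimed at imaging statisticians and trial methodologists who need this
measurement chain as tested, reusable code: the boundary shift integral
(BSI) family of direct change measures, the mixed model appropriate for
repeated *changes*, paired protocol-comparison statistics, and per-arm
sample-size estimation — plus a synthetic-data module (phantoms with exactly
known volume change, cohort and QC simulators) so the whole pipeline runs
and validates end to end with no access-controlled data.

## The measures and the model

**Boundary shift integral.** For normalised baseline and follow-up volumes
*B*, *F*, a boundary shell *R* and an intensity window (*I₁*, *I₂*):

    BSI = v / (I₂ − I₁) · Σ_{x ∈ R} [ clip(B(x), I₁, I₂) − clip(F(x), I₁, I₂) ]

with *v* the voxel volume in ml. Variants: `kn_bsi()` (whole brain; k-means
tissue centroids set the normalisation and window), `fixed_window_bsi()`
(ventricles; preset window on the CSF/tissue interface) and `hippo_bsi()` /
`double_window_bsi()` (hippocampi; CSF/GM plus GM/WM windows).
`differential_bias_correct()` removes the smooth multiplicative intensity
field difference between the two scans first.

**Repeated direct change measures.** A measured change *y* between visits
*j* < *k* of subject *i* on scan type *s* (0 = accelerated,
1 = non-accelerated) over *t* years is modelled as

    y = (β₀ + β₁·s + β₂·EMCI + β₃·LMCI + β₄·AD + b_i)·t − u_ij + u_ik + ε_s

with diagnosis-specific random slopes `b_i ~ N(0, σ²_b,dx)`, signed visit
effects `u ~ N(0, σ²_u)`, and residual variance σ²_ε,s that may differ by
scan type. `fit_change_lmm()` fits this by maximum likelihood;
`lrt_residual_variances()` is the 1-df likelihood-ratio test of whether the
measurement error differs between protocols.

**Trial sizing.** `sample_size_per_arm()` computes
`n = (u + v)² · 2σ² / (r·μ)²` per arm for a proportional rate reduction *r*
(u = 0.84 for 80% power, v = 1.96 for two-sided 5%), rounded up;
`bootstrap_sample_size_ci()` and `compare_protocol_sample_sizes()` add
subject-level bootstrap intervals.

## Worked example

Measure a phantom with exactly 2 ml of whole-brain loss at SNR 25, fit the
change model to a simulated 300-subject cohort, and size a trial:

```r
library(serialbsi)

# phantom pair with known truth, measured by KN-BSI
ph <- make_phantom_pair(phantom_spec(atrophy_ml = 2))
b  <- add_acquisition_noise(ph$baseline, noise_spec("accelerated", snr_center = 25, seed = 1))
f  <- add_acquisition_noise(ph$followup, noise_spec("accelerated", snr_center = 25, seed = 2))
kn_bsi(image_pair(b, f, ph$voxel_volume_ml), ph$masks$brain_base, ph$masks$brain_follow)
#> BSI: 2.0000 ml over 14939 boundary voxels
#>   window: [0.2833, 0.4499]

# cohort at whole-brain scale; residual SDs 1 (accelerated) vs 2 (non-accelerated)
rec <- simulate_cohort(cohort_spec(n_per_group = c(CN = 75, EMCI = 75, LMCI = 75, AD = 75), seed = 11))
lrt <- lrt_residual_variances(rec)
lrt$fit_separate
#> Direct-change LMM fit (1800 records, 300 subjects)
#>   log-likelihood: -4010.432  (converged: TRUE)
#>       estimate     se
#> beta0   5.4266 0.4427
#> beta1   0.1949 0.1039
#> beta2   1.7034 0.6054
#> beta3   4.9943 0.6778
#> beta4   9.3907 0.6644
#>   slope variance by diagnosis:
#>      CN    EMCI    LMCI      AD
#>  9.3609  7.5134 14.4781 13.1257
#>   visit variance: 2.4074
#>   residual variance: accelerated 0.9125, non-accelerated 3.9490
round(lrt$chi2_stat, 2); signif(lrt$p_value, 3)
#> [1] 171.41
#> [1] 3.64e-39

# per-arm size for a 25% reduction from an AD rate of 14.89 (SD 8.24) ml/yr
sample_size_per_arm(power_spec(mu = 14.89, sigma = 8.24))
#> $n_per_arm
#> [1] 77
#> $n_raw
#> [1] 76.83123
```

The BSI recovers the phantom's ground truth; the fit recovers the
generative parameters (β₀ = 5.8, offsets 1.7/5.0/9.1, residual variances 1
vs 4) within sampling error, and the LRT flags the protocol difference in
measurement error. The full synthetic study — phantoms, cohorts, fits,
paired statistics, QC comparison and sample-size table, with a seed manifest
and byte-identical reruns — is one call:

```r
run_synthetic_study(default_run_config(seed = 1), out_dir = "study")
```

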