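---
title: "Measuring serial brain volume change: models and methods in serialbsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring serial brain volume change: models and methods in serialbsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialbsi)
```

## What this package is for

Serial structural MRI lets each participant act as their own control: the
volume change of the whole brain, the lateral ventricles or the hippocampi
between two co-registered scans is a sensitive marker of neurodegeneration
and a common clinical-trial outcome. `serialbsi` implements the measurement
chain around the boundary shift integral (BSI) family of direct change
measures, the mixed model appropriate for repeated *changes* (rather than
repeated levels), the paired statistics used to compare two acquisition
protocols scanned back to back in the same session, and per-arm sample-size
estimation for a hypothetical treatment trial. Because real serial MRI data
of this kind are access-controlled, the package also ships a synthetic-data
module -- geometric phantoms with exactly known volume change and a cohort
simulator drawn from the same generative model the fitting code assumes --
so every stage can be exercised and validated end to end on a desktop.

## The boundary shift integral

Given baseline and follow-up volumes $B$ and $F$ on a common grid,
normalised to a shared intensity scale, and a shell $R$ around the structure
boundary, the clipped BSI is

$$\mathrm{BSI} = \frac{v}{I_2 - I_1}
  \sum_{x \in R} \big[\mathrm{clip}(B(x), I_1, I_2)
                    - \mathrm{clip}(F(x), I_1, I_2)\big],$$

where $v$ is the voxel volume in ml and $(I_1, I_2)$ an intensity window
spanning the tissue interface. A voxel whose intensity crosses the full
window contributes exactly one voxel volume, so the sum estimates the volume
swept by the moving boundary. The integral is antisymmetric in the two
timepoints and bounded by $v \cdot |R|$; both properties are exercised as
exact tests.

Three variants are composed from the same primitives:

* **KN-BSI** (`kn_bsi()`): for the whole brain. Tissue intensities for CSF,
  grey and white matter are estimated by a deterministic k-means within the
  union brain mask on each timepoint, both volumes are affinely rescaled so
  the CSF and WM centroids land on fixed targets (0.2 and 0.8 by default),
  and the window is centred between the normalised CSF and GM centroids with
  half-width 0.25 of their separation.
* **Fixed-window BSI** (`fixed_window_bsi()`): for the ventricles. After
  normalising CSF to 0 and WM to 1, a preset window of (0.25, 0.75) spans
  the CSF/tissue interface.
* **Double-window BSI** (`double_window_bsi()`, composed by `hippo_bsi()`):
  for the hippocampus, whose surface borders both CSF and white matter. The
  clipped integral is evaluated in a CSF/GM and a GM/WM window, each scaled
  by its own width, over the same boundary shell. Because hippocampal grey
  matter is *darker* than the surrounding white matter, loss at the GM/WM
  interface appears as an intensity increase; `hippo_bsi()` therefore
  reverses the sign of the GM/WM window term so that loss is reported
  positive, while `double_window_bsi()` itself keeps the plain sum (making
  its additivity with the single-window integral exact when change is
  confined to one window).

The exact window bounds and normalisation targets of in-house BSI
implementations are not published; the choices above are declared defaults
and every one of them is a function argument.

Sign convention throughout: brain and hippocampal results are *loss*
(positive = shrinkage); ventricular results are *expansion* (positive =
growth). Both fall out of the same formula because the ventricle is a dark
structure growing into bright tissue.

### k-means tissue centroids

`tissue_means_kmeans()` is a small, seed-free Lloyd iteration: centroids
start at 10%/50%/90% of the masked intensity *range*, boundary ties go to
the lower cluster, and iteration stops when the relative centroid change
drops below $10^{-6}$ (at most 300 iterations). Range-fraction
initialisation was chosen over intensity percentiles deliberately: within a
brain mask, white matter is the majority tissue, so the upper percentiles of
the intensity histogram coincide inside the WM mode and percentile-seeded
clusters merge CSF with GM while splitting WM. Range fractions are equally
deterministic and start one centroid near each tissue mode whenever the
three modes span the intensity range.

### Boundary shell and morphology

The shell is `dilate(union of masks) minus erode(intersection of masks)`,
one round of each by default, with 6-connected (face-neighbour) structuring;
outside the grid counts as background for both operations. Registration is
out of scope: a grid mismatch between the two volumes raises an error naming
both shapes rather than silently resampling. Voxel indices are 0-based in
the geometry arithmetic and masks are voxel-centre labellings.

### Differential bias correction

`differential_bias_correct()` estimates the smooth multiplicative intensity
field difference between the two scans as the Gaussian-low-pass-filtered
log-ratio within a mask and divides it out symmetrically (half applied to
each volume), so an identical pair is an exact fixed point. The smoothing is
a mask-weighted separable Gaussian (default FWHM 15 mm) followed by two
residual re-smoothing passes (van Cittert refinement): a single normalised
convolution is biased where the mask truncates the kernel, and each
refinement pass squares that error operator. The correction is approximately
idempotent within the mask.

## The phantom generator

`make_phantom_pair()` builds a three-tissue piecewise-constant head: a
spherical brain (radius 25 mm) with a 3 mm cortical GM shell and WM core, a
central CSF ventricle sphere (radius 8 mm), and two ellipsoidal GM
hippocampi (semiaxes 5 x 3.5 x 3 mm) embedded in the WM at +/-15 mm. The
default grid is 64^3 at 1 mm isotropic -- a desk-scale head, roughly
one-fifteenth of real brain volume, chosen so that a full
simulate-measure-fit study runs in minutes on one CPU.

Atrophy is realised on the voxel grid directly. To remove $m =
\mathrm{round}(\Delta_{ml}/v)$ voxels from a structure, the generator
thresholds the sorted voxel distances (or ellipsoidal quadratic forms) of
that structure; a small sub-voxel offset of the grid centre makes the
distances generically distinct, so exactly $m$ voxels change and the
realised, voxel-quantised change -- recorded as ground truth -- matches the
request to within one voxel volume. This is the property that makes the
phantom an *oracle*: the voxel-count difference of the masks is exact, with
no partial-volume ambiguity.

Acquisition noise (`add_acquisition_noise()`) is Rician by default
(magnitude MRI), with a Gaussian option for analytic checks; the local noise
SD is `signal / SNR`. The accelerated (parallel-imaging) protocol gets a
radial SNR profile that is highest at the head periphery near the receive
coils and decays toward the centre (default 2% per mm); the non-accelerated
protocol gets uniform SNR. The published protocols' actual SNR maps are not
available, so these defaults are stated placeholders, not estimates of any
scanner's physics.

Motion (`add_motion_artifact()`) is modelled as circular convolution with a
1-D Gaussian kernel along one axis (standing in for the phase-encode
direction, chosen from the seed) with width proportional to severity, plus a
low-amplitude ghost replica shifted by half the field of view; the mixing is
normalised so the image sum is conserved exactly. This is the simplest
mechanism that blurs boundary intensities, which is the failure mode that
matters for the BSI. The observed asymmetry between protocols -- longer
scans failing quality control for motion more often -- is emulated at the
*label* level by `simulate_qc_labels()` rather than by rendering motion into
every phantom: correlated within-subject pass/fail outcomes with specified
marginal failure probabilities and a Plackett odds-ratio dependence.

What the phantoms deliberately omit: cortical folding, partial-volume
gradients at tissue interfaces, k-space-accurate parallel-imaging
reconstruction, and scanner-manufacturer differences beyond the noise and
motion parameters. Passing the phantom-recovery tests therefore shows the
estimator chain is correct and unbiased under the stated noise model; it
does not certify accuracy on real anatomy.

## The model for repeated direct change measures

A direct change measure between visits $j < k$ is itself a difference, which
induces a specific covariance structure. For subject $i$ in diagnostic group
$dx$, scan type $s$ (0 = accelerated, 1 = non-accelerated) and interval
$t_{ijk}$ years:

$$y_{ijk} = (\beta_0 + \beta_1 s + \beta_2\,\mathrm{EMCI}
           + \beta_3\,\mathrm{LMCI} + \beta_4\,\mathrm{AD} + b_i)\,t_{ijk}
           - u_{ij} + u_{ik} + \varepsilon_{s,ijk},$$

with $b_i \sim N(0, \sigma^2_{b,dx})$ (between-subject heterogeneity in
rate, allowed to differ by diagnosis), $u_{ij} \sim N(0, \sigma^2_u)$ a
visit-specific deviation entering with signs $-1$ at the start visit and
$+1$ at the end visit (so a chain of changes telescopes), and a residual
whose variance may differ by scan type. The residual is the measurement
error of the direct change measurement itself, which is the one component a
faster acquisition could plausibly alter; all other components are
properties of the participant. Both scan types of a session share $b_i$ and
$u_{ij}$: the protocols are acquired back to back, so the participant's
state at a visit is common to both. (Whether the original analyses shared
these effects across protocols is not fully documented; the shared reading
follows from the model's indexing, and the assumption is exposed — fitting
scan types separately is a matter of filtering the records.)

`fit_change_lmm()` maximises the marginal Gaussian likelihood by ML (not
REML): the likelihood-ratio test compares models with identical fixed
effects differing only in variance structure, for which ML is the standard
choice. Variances are log-parametrised (positivity without constraints), the
fixed effects are profiled out by generalised least squares at each
candidate covariance, and the optimiser is quasi-Newton (BFGS with a
Nelder-Mead polish) from three starts: a method-of-moments guess and the
same scaled by 0.3 and 3. Subjects with identical design blocks share one
Cholesky factorisation per likelihood evaluation, which is what makes
hundreds of simulated fits cheap. Fixed-effect standard errors come from the
inverse GLS information at the optimum; which information convention stood
behind the original standard errors is unstated, and this one is declared.

`lrt_residual_variances()` fits the common- and separate-residual models and
refers $2(\ell_{sep} - \ell_{com})$ to $\chi^2_1$. No boundary correction is
needed: the null hypothesis $\sigma_{a,\varepsilon} =
\sigma_{na,\varepsilon}$ is interior to the parameter space. The common-model
optimum is handed to the separate fit as an additional start, so the nesting
inequality $\ell_{sep} \ge \ell_{com}$ holds numerically on every dataset.
`adjusted_group_rates()` turns the fixed effects into model-implied mean
annualised rates (controls/accelerated $= \beta_0$,
controls/non-accelerated $= \beta_0 + \beta_1$, and so on) with delta-method
standard errors.

## Paired statistics

For paired protocol comparisons the package provides the classical paired
$t$ (`paired_mean_test()`), the Pitman-Morgan test of equal variances in
paired samples (`pitman_variance_test()`: the correlation between pairwise
sums and differences is zero under equal variances; $r\sqrt{n-2}/\sqrt{1-r^2}$
is referred to $t_{n-2}$), Bland-Altman limits of agreement
(`limits_of_agreement()`: mean difference $\pm 1.96\,\mathrm{SD}$),
McNemar's test for paired proportions (`mcnemar_paired_proportions()`), and
Cohen's kappa (`cohen_kappa()`). McNemar defaults to the exact binomial form
-- twice the smaller tail of $\mathrm{Binomial}(b+c, \tfrac12)$, capped at 1
-- because it is safe at any discordant count; the $\chi^2$ forms (with and
without continuity correction) are available and are the calibrated choice
when discordant counts are large. All p-values are two-sided at
$\alpha = 0.05$.

`adjusted_group_difference()` estimates a covariate-adjusted group
difference by least squares (or a log odds ratio by logistic regression for
binary outcomes) with a bias-corrected and accelerated (BCa) bootstrap
interval, resampling subjects -- the exchangeable unit in a paired design.
The bias correction $z_0$ uses midrank handling of bootstrap ties so that a
symmetric bootstrap distribution centred on the estimate gives exactly the
percentile interval; the acceleration comes from jackknife skewness.

## Sample-size estimation

The per-arm size for detecting a proportional reduction $r$ in the mean
annualised rate $\mu$ with rate SD $\sigma$ is

$$n = \frac{(u + v)^2\,(\sigma_1^2 + \sigma_2^2)}{(\mu_1 - \mu_2)^2}
    = \frac{(u + v)^2 \cdot 2\sigma^2}{(r\mu)^2},$$

with $u = 0.84$ (80% power) and $v = 1.96$ (5% two-sided), treated and
placebo SDs assumed equal, and the result rounded *up* to the next whole
subject -- the only rounding consistent with reproducing published
sample-size tables from their printed rate summaries. The two-decimal $u,
v$ are stored as given to reproduce printed arithmetic; a high-precision
mode ($u = \Phi^{-1}(0.8)$, $v = \Phi^{-1}(0.975)$) is available.
`bootstrap_sample_size_ci()` resamples subjects' annualised rates and
reports the percentile interval of the recomputed sizes (BCa is reserved
for the covariate-adjusted comparisons, where it is the named method), and
`compare_protocol_sample_sizes()` bootstraps the paired difference between
protocols by resampling subjects jointly.

## The end-to-end study and reproducibility

`run_synthetic_study()` chains the stages -- phantom measurement for all
three structures under both protocols, cohort simulation per structure at
its own rate scale, mixed-model fits with the residual-variance LRT, paired
statistics, a QC comparison (McNemar on simulated labels plus a re-rating
kappa), and the sample-size table with bootstrap intervals -- writing NIfTI
phantoms, CSV tables and JSON reports plus a manifest with every stage seed
and a configuration hash. Every stage seed derives from the single
configuration seed by fixed offsets, and reruns with the same configuration
are byte-identical. The configuration is a nested YAML file; vectors in it
are order-based (diagnosis order CN, EMCI, LMCI, AD) so that it round-trips
through serialisation unchanged.

Default cohort parameters are set once at the scale of published annualised
rates: whole brain $\beta_0 = 5.8$ ml/yr with diagnosis offsets 1.7/5.0/9.1
(EMCI/LMCI/AD), slope SDs 3-4 ml/yr, visit-effect SD 1.5 ml and residual
SDs 1 vs 2 ml; ventricles and hippocampi scaled analogously (about 1.4 and
0.07 ml/yr for controls). Visits default to 0, 0.5 and 1 years with all
three visit pairs observed for both protocols.

## Problem sizes and numerical tolerances

The validation suite uses problem sizes chosen to make each check
statistically meaningful while keeping a full run desk-scale: 50 noise
realisations for phantom-truth recovery of the KN-BSI (relative bias and
RMSE) and the hippocampal double-window variant; 10 simulated cohorts of
300 subjects for parameter recovery of the change model; 200 null cohorts
of 150 subjects for the size of the residual-variance LRT; 2000 replicates
each for Pitman-Morgan and McNemar calibration; and an integrated
simulate-acquire-measure-fit run of 60 subjects. Optimiser convergence is a
relative likelihood change below $10^{-10}$; k-means converges at relative
centroid change $10^{-6}$; exactness properties (antisymmetry, the
single-voxel window crossing, zero on identical pairs) are asserted at
machine precision.

## Known limitations

* The phantom geometry is spherical/ellipsoidal with sharp interfaces; there
  is no partial volume, so window-placement errors that would matter on real
  gradual boundaries are under-penalised.
* The SNR and motion parameters of the two acquisition protocols are
  declared defaults, not measurements; conclusions about protocol
  differences from the synthetic study characterise the simulator, not any
  scanner.
* The mixed model assumes missing visit pairs are missing at random, linear
  subject trajectories, and Gaussian components throughout.
* Registration, segmentation and bias-field correction of real scans are out
  of scope: image pairs must arrive co-registered with masks, and grids must
  match exactly.
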