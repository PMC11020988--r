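---
title: "Methods: adaptive-threshold PET radiomics, reference uptake and outcome statistics"
author: "petromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive-threshold PET radiomics, reference uptake and outcome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petromics)
```

This vignette is the package's own account of its methods: the models and
conventions it implements, the parameters that matter, what the synthetic
generators do and do not emulate, and the numerical choices made where the
underlying protocol leaves room.

## The imaging model

An `SUVVolume` is a 3D grid of standardized uptake values (SUV: tissue tracer
concentration normalized by injected dose per body weight; unitless) with a
voxel spacing in mm and a world origin at the centre of the first voxel.
Clinical protocols in this family resample PET onto a common analysis grid
before feature extraction; `resampleVolume()` performs trilinear resampling,
and the package-wide default spacing is 4.07 × 4.07 × 2.5 mm. Resampling
preserves the physical extent of the volume to within one target voxel per
axis and clamps samples at the borders to the nearest voxel centre, so
constants and interior linear ramps are reproduced exactly (to round-off).

### Adaptive-threshold delineation

The tumor is delineated with the Nestle adaptive threshold

\[
T \;=\; w \cdot \overline{\mathrm{SUV}}\bigl(\{\,v \in \text{tumor}:
\mathrm{SUV}(v) > f \cdot \mathrm{SUV}_{\max}\,\}\bigr) \;+\;
\overline{\mathrm{SUV}}(\text{background}),
\]

with weight \(w = 0.30\) and core fraction \(f = 0.70\) by default. Two
aspects of this rule are under-determined and were resolved as follows:

* **The formula is self-referential** — the threshold defines the tumor that
  defines the core. `delineateTumor()` therefore iterates to a fixed point:
  the initial estimate is the connected component (26-connectivity by
  default) containing the seed at half the local maximum SUV (searched
  within 12 mm of the seed); each iteration measures the background, applies
  the formula, and re-extracts the seed component of voxels *strictly* above
  the new threshold, stopping when the mask repeats. Convergence on phantoms
  takes 2–3 iterations; `maxIterations = 1` reproduces a one-shot
  application, and hitting the cap flags the result rather than erroring.
  Both strict inequalities ("> 70 % of maximum", "SUV > threshold") follow
  the protocol's wording.
* **"Background" is not defined** by the protocol. The default is the mean
  SUV in a shell 8–16 mm from the current estimate (voxel-centre Euclidean
  distance), excluding any caller-supplied organ masks so that, e.g., an
  adjacent liver does not contaminate the background; alternatively an
  explicit background mask can be supplied (`backgroundMode =
  "explicit_mask"`). A local shell matches the intent of a case-by-case
  tumor/background contrast and makes the threshold affine in the background
  level, which the tests verify exactly.

Two useful invariants follow and are tested: scaling all intensities by
\(c > 0\) scales the converged threshold by \(c\) and leaves the converged
mask unchanged (shell geometry is intensity-independent), and raising \(w\)
never grows the converged mask.

### The ten first-order features

Six conventional features are computed on raw masked voxel values: maximum,
mean and median SUV; MTV (voxel count × voxel volume, cm³); TLG (MTV × mean
SUV, grams under the standard 1 g/cm³ density convention, so the TLG = MTV ×
mean SUV identity holds to 1e−9 relative by construction); and CoV (standard
deviation / mean — *population* SD by default, switchable to \(n-1\)).

Four features come from the SUV intensity histogram: the VOI range
\([\min, \max]\) is split into 64 equal-width bins (fixed bin *number*, the
documented default of the clinical software family this emulates; half-open
bins with the last closed, so a degenerate VOI puts all mass in bin 1), and

* entropy \(= -\sum_{p_i > 0} p_i \log_2 p_i\) (bits, ≤ 6 at 64 bins),
* uniformity \(= \sum p_i^2\) (1/64 at maximal entropy, 1 iff entropy 0),
* skewness and kurtosis as probability-weighted moments of the bin centres,
  kurtosis reported as *excess* (−3, switchable). A single-occupied-bin
  histogram has zero variance; skewness/kurtosis are then returned as 0 and
  flagged, rather than NaN.

Because binning is relative to the VOI's own range, the four histogram
features (and CoV) are invariant under positive rescaling of the SUVs while
max/mean/median/TLG scale linearly — a property suite checks both lists.

### Reference-organ uptake

Bone-marrow SUV is the unweighted mean of six per-vertebra measurements, each
the mean of voxels strictly above 75 % of that VOI's maximum. (Note the
strict rule cannot empty the core of any VOI with a positive maximum, since
\(\max > 0.75\max\); the all-voxel fallback exists only for the pathological
all-zero VOI and is flagged.) Liver and spleen SUVs are means over 3-cm and
2-cm spheres; sphere membership is by voxel-centre inclusion with no
partial-volume weighting, matching the voxel-counting MTV convention.
BLR = BM/liver and SLR = spleen/liver, both invariant under global intensity
scaling. Vertebral VOIs are caller-supplied (masks or sphere centres with a
1.5-cm default diameter — a size that fits a vertebral body at the analysis
spacing); excluding fractured or post-operative vertebrae is the caller's
responsibility.

## The synthetic generators

### Phantoms

`generatePhantom()` builds a body-like grid (default 48 × 48 × 40 voxels at
the analysis spacing, ~195 × 195 × 100 mm) holding a spherical tumor plus
liver, spleen and six stacked vertebrae, pairwise non-overlap validated by
name. The tumor is filled with a Gaussian random field: white noise smoothed
by FFT convolution with an isotropic Gaussian kernel (correlation length 8 mm
by default), then re-standardized so the region's mean and marginal SD equal
the requested values *exactly* — so a noiseless spec is exactly constant and
the true CoV is `tumorTextureSD / tumorMean` by construction. Organ regions
use uncorrelated noise: organ uptake is physiologically much more homogeneous
than tumor texture, and uncorrelated voxels make sub-VOI means converge at
the \(1/\sqrt{n}\) rate that the recovery tests assert. Global additive noise
is applied last and negative SUVs are clipped to 0 (SUV is non-negative by
definition). Defaults — background SUV 1.0 ± 0.1, tumor SUV 8 ± 2 (CoV
0.25), liver 2.1, spleen 1.7, vertebrae 1.8, noise SD 0.05 — sit in the
range a clinician would call typical for body FDG PET.

What phantoms do **not** model: scanner physics (scatter, attenuation,
partial-volume blur, reconstruction artifacts), anatomy beyond spheres, and
inter-lesion shape variability. Passing phantom tests therefore demonstrates
the *computational* correctness of delineation and features, not robustness
to clinical image quality.

### Cohorts

`generateCohort()` draws, per patient: ordinal IHC grades (CD4, CD8, CD163,
IL-6, MMP-11 ∈ {0,1,2}) from the emulated study's grade frequencies; clinical
covariates (age, sex, tumor location/size/grade, lymphovascular invasion,
TNM stage, CEA, adjuvant treatment) from its baseline distribution; and
log-normal imaging features whose medians are multiplied by a per-grade-step
factor for each (feature, marker) coupling — e.g. MTV falls by ×0.76 per CD4
grade, entropy and BM SUV rise by ×1.066 per CD163 grade, uniformity falls by
×0.86 per IL-6 grade. Log-normal medians-with-multiplicative-shifts is the
natural model for right-skewed quantities summarized as median (IQR). Two
features are *derived*, not sampled: TLG = MTV × mean SUV (so the identity
holds cohort-wide and its grade couplings are inherited) and BLR/SLR as
ratios of the sampled organ SUVs (so ratio invariants hold and BLR/SLR
inherit the BM/spleen couplings). Entropy is capped at 6 bits and uniformity
kept in [1/64, 1], the feasible range of a 64-bin histogram. Markers are
generated independently — no joint marker distribution is available to
emulate — so co-expression structure, if needed, must be supplied by the
user via a custom spec.

Survival is exponential proportional hazards: the log-hazard is
\(\beta_1 \mathbf{1}(\text{stage III–IV}) + \beta_2 (\mathrm{CoV} -
0.24)/0.10 + \beta_3 (\mathrm{SLR} - \mathrm{SLR}_0)\) with defaults
\(\beta_1 = \log 2.341\), \(\beta_2 = \log 0.484\), \(\beta_3 = \log
24.901\); centring CoV and SLR at their base medians makes
`baselineHazardRate` the hazard of a median stage I–II patient without
affecting the coefficients a Cox refit estimates. Censoring is uniform over
26.1–84.4 months (the emulated follow-up window). The default baseline,
0.00226/month, was solved numerically so that the marginal five-year RFS of
the default cohort is 73.8 %, which also yields an event fraction near one
quarter. This is a minimal generator: exponential baseline (no shape), no
competing risks, no informative censoring — sufficient for the Cox
assumptions it is meant to exercise, and its parameters are recovered to
within Monte-Carlo error by `coxFit()` (checked over 20 cohorts of
n = 2000, with ≥ 90 % Wald-CI coverage).

## The statistics chain

* **Kruskal–Wallis** (`kruskalWallisByGrade`) uses the tie-corrected H via
  `stats::kruskal.test`; the all-tied degenerate case is defined as H = 0,
  p = 1. **Dunn post-hoc** z-statistics use mean-rank differences with the
  tie-corrected variance; p-values are unadjusted by default (the emulated
  protocol states no adjustment) with Bonferroni/Holm available via
  `p.adjust` methods.
* **Mann–Whitney** reports U for the first factor level. With both groups
  ≤ 8 it enumerates the exact permutation distribution of U (valid with
  ties, so identical groups give p = 1 exactly — `wilcox.test` cannot do
  this with ties); otherwise it uses the tie-corrected normal approximation
  without continuity correction, cross-checked against `wilcox.test`.
* **Cox models** (`coxFit`) use `survival::coxph` with Efron tie handling.
  Covariates are divided by their reporting unit *inside* the fit (CoV and
  uniformity per 0.10, MTV per 10 cm³, TLG per 10 g, others per 1.0; CEA
  dichotomized at 5 ng/ml by `prepareCovariates`) so hazard ratios are per
  printed unit. Collinearity is rejected up front; a monotone partial
  likelihood (perfect separation) is converted from a warning into an error
  advising penalization. `univariateScreen` retains candidates with
  univariate p < α (default 0.05) in input order, the usual build rule for
  the multivariate model.
* **ROC cutoffs** (`rocCutoff`) scan all midpoints of consecutive sorted
  unique values in both orientations and maximize Youden's J, ties broken
  toward the lower cutoff. Youden's index is the standard criterion for
  single-cutoff dichotomization; the choice is recorded in the output, and
  the scan is verified against an O(n²) confusion-matrix enumeration and
  against pROC.
* **Kaplan–Meier / log-rank** (`kmLogrank`) wrap `survival::survfit` (plain
  Greenwood CIs) and `survdiff`, with a survival-at-t query (default 60
  months, the five-year mark). The stratified recurrence table
  (`recurrenceStratTable`) crosses stage I–II vs III–IV with three imaging
  groups — both favorable (CoV > 0.25 **and** SLR < 0.83), mixed, both
  unfavorable (CoV ≤ 0.25 **and** SLR ≥ 0.83) — reporting events/total and
  the percentage rate; cutoff membership is boundary-inclusive on the
  unfavorable side, and 0/0 cells report an undefined rate. The 0.25/0.83
  cutoffs are treated as fixed protocol inputs, whatever criterion
  originally produced them.
* **Missing data** are handled complete-case per analysis with exclusion
  counts attached to results.

## Numerical and reproducibility choices

Connected components and the background shell run in C++ (exact Euclidean
voxel-centre distances against the mask's 6-connected surface); both have
pure-R brute-force twins in the test suite. All generator randomness flows
through a single integer seed per spec, saved-and-restored around the global
RNG state, so identical specs give bit-identical volumes and row-identical
cohorts; the pipeline derives per-stage child seeds from one global seed by a
fixed affine map mod 2³¹−1, so stages can be re-run in isolation. Histogram
bin assignment uses `floor((x - min)/range * nBins)` clipped to the last bin;
values exactly at internal bin edges therefore belong to the upper bin, the
half-open convention stated in the documentation.

## Problem sizes used in the checks

The test-suite and acceptance runs use: phantoms of 48 × 48 × 40 voxels
(criteria needing many delineations use 30 phantoms), noiseless spheres with
radii 10–30 mm for volume-recovery checks, 200 random small VOIs for the
feature-oracle comparison, 100 random instances for the ROC brute-force
equivalence, cohorts of n = 5000 for distributional checks and n = 2000 × 20
replicates for hazard-ratio recovery, and n = 1000 × 60 replicates for the
screening power check. These sizes were chosen so each Monte-Carlo assertion
sits comfortably inside its stated tolerance.

## Known limitations

Delineation assumes a single connected lesion around the seed; multifocal
disease needs per-lesion seeds. The fixed-point iteration is not guaranteed
to converge for pathological intensity configurations (it is capped and
flagged). No PET physics is simulated, so absolute feature values on
phantoms are not calibrated against any scanner. The survival generator's
exponential baseline cannot emulate late-hazard shapes, and IHC markers are
sampled independently. Proportional-hazards diagnostics beyond the fit
itself, competing risks and multiple imputation are out of scope.
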