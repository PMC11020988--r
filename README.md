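# petromics

First-order FDG PET radiomics with reference-organ uptake and outcome
statistics, for oncology imaging studies that relate tumor metabolism to
tissue immunology and recurrence-free survival (RFS).

In colorectal cancer (and other solid tumors), the FDG uptake pattern of the
primary lesion reflects both tumor biology and the immune reaction in and
around the tumor, while uptake in the bone marrow and spleen tracks the
host's systemic inflammatory response. `petromics` implements the complete
quantitative chain used in such studies:

- **Tumor delineation** on SUV volumes with the Nestle adaptive threshold

  ```
  T = 0.3 x mean{ SUV > 0.7 x SUVmax within the tumor } + mean SUV(background)
  ```

  applied as a fixed-point iteration over seed-connected components, with the
  background measured in a configurable 8–16 mm shell around the current
  estimate.
- **Ten first-order features** per tumor: maximum/mean/median SUV, metabolic
  tumor volume (MTV, cm³), total lesion glycolysis (TLG = MTV × mean SUV, g),
  coefficient of variation (CoV = σ/μ), and the intensity-histogram features
  kurtosis, skewness, entropy (−Σ p log₂ p, bits) and uniformity (Σ p²) on a
  64-bin histogram over the VOI range.
- **Reference uptake**: per-vertebra bone-marrow SUV (mean of the core above
  75 % of the VOI maximum, averaged over six vertebrae), liver (3-cm sphere)
  and spleen (2-cm sphere) SUVs, and the bone-marrow-to-liver (BLR) and
  spleen-to-liver (SLR) ratios.
- **Cohort statistics**: Kruskal–Wallis with Dunn post-hoc across ordinal
  immunohistochemical grades (CD4/CD8/CD163/IL-6/MMP-11 ∈ {0,1,2}),
  Mann–Whitney by tumor grade, univariate screening feeding a multivariate
  Cox proportional-hazards model (Efron ties, hazard ratios per reporting
  unit), Youden-index ROC cutoffs, Kaplan–Meier curves with log-rank tests,
  and a TNM-stage × (CoV, SLR) recurrence stratification table.
- **Synthetic data**: PET phantoms (heterogeneous spherical tumor + liver,
  spleen, six vertebrae, with full ground truth) and patient cohorts whose
  feature–grade couplings and proportional-hazards structure are controlled,
  so the entire pipeline is testable without clinical data.

Volumes are S4 objects (`SUVVolume`, `VOIMask`) read and written as NIfTI-1;
cohorts are plain data frames read and written as CSV.

## Worked example

```r
library(petromics)

# a synthetic PET phantom with known ground truth
ph  <- generatePhantom(phantomSpec(seed = 7L))
del <- delineateTumor(ph$volume, c(60, 100, 50),
                      organMasks = ph$truth@organMasks)
del
#> TumorDelineation: threshold 4.244 (background 0.9987), 661 voxels, 2 iteration(s)

round(featureVector(tumorFeatures(ph$volume, del@mask)), 4)
#>    max_suv   mean_suv median_suv    mtv_cm3      tlg_g    cov_suv   kurtosis
#>    13.3195     8.0288     7.7623    27.3735   219.7757     0.2469    -0.4760
#>   skewness    entropy uniformity
#>     0.4195     5.7083     0.0215
```

The generator placed an 18.75-mm-radius tumor (analytic volume 27.61 cm³,
mean SUV 8, texture SD 2, hence true CoV 0.25): the converged threshold is
0.3·(core mean) + background ≈ 4.24, the measured MTV 27.37 cm³ is within one
voxel layer of truth, and the measured CoV 0.247 recovers the generator value.

```r
os <- defaultOrganSpecs()
referenceUptake(ph$volume,
                liverCenterMM  = c(140, 60, 50),
                spleenCenterMM = c(40, 60, 50),
                vertebralCentersMM = as.matrix(
                  os[grepl("vertebra", os$label), c("cx", "cy", "cz")]))
#> ReferenceUptake: BM 1.85, liver 2.09, spleen 1.7; BLR 0.883, SLR 0.814
```

On the cohort side, a synthetic cohort regenerates the assumed hazard
structure and the Cox fit recovers it:

```r
coh <- generateCohort(cohortSpec(nPatients = 500L, seed = 7L))
coxFit(coh, c("stage_iii_iv", "cov_suv", "slr"))[, c("term", "hazard_ratio", "p")]
#>          term hazard_ratio     p
#>  stage_iii_iv        1.573 0.010
#>       cov_suv        0.353 0.000   # per 0.10 increase
#>           slr       26.101 0.000   # per 1.0 increase

kruskalWallisByGrade(coh, "mtv_cm3", "cd4")
#> H = 27.16 on 2 df: MTV falls with CD4+ infiltration grade, as generated
```

`runPipeline(runConfig(...))` chains all stages (phantoms → delineation →
features → reference uptake → cohort statistics) into one seeded run that
writes `phantom_features.csv`, `cohort.csv`, `stats.json`, text tables for
the feature-by-grade, survival and recurrence-stratification summaries, KM
curves (PDF + step CSV) and a manifest. `inst/cli/petromics.R` is a thin
command-line wrapper over the same functions.

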