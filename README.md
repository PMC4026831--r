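# cmrfibrosis

Quantitative cardiovascular MR assessment of diffuse myocardial fibrosis,
as an end-to-end, fully testable R pipeline.

## What it does, and for whom

Diffuse interstitial fibrosis is invisible on late gadolinium enhancement
(LGE) imaging, which only shows *focal* scar against a nulled background.
The quantitative alternative is the myocardial **extracellular volume
fraction (ECV)**: gadolinium contrast distributes in extracellular water,
so at dynamic equilibrium the gadolinium-induced change in the myocardial
relaxation rate R1 = 1/T1 tracks the change in blood,

```
ΔR1_myo(t) = λ · ΔR1_blood(t)          (λ = partition coefficient)
ECV        = λ · (1 − Hct)
```

λ is estimated by least-squares regression of myocardial R1 on blood-pool
R1 over three MOLLI T1-mapping acquisitions (pre-contrast, ~8 min, ~20 min
after a 0.2 mmol/kg bolus), and the hematocrit correction converts blood to
plasma volume. The package is aimed at CMR methodologists and image-analysis
developers who need every stage of that chain — T1 fitting, LGE
thresholding, segmental analysis, cohort statistics — verifiable by
parameter recovery, without access to scanner data.

Modules:

* **Synthetic cohort generator** — short-axis annular phantom with known
  per-region λ, hematocrit, lesion geometry (core/border/remote classes),
  hypertrophic sectors and clinical covariates; renders MOLLI series and
  LGE images with Rician noise. Ground-truth ECV is pinned exactly
  (λ is derived per subject from the drawn hematocrit).
* **MOLLI relaxometry** — 3(3)3(3)5 scheme (11 images / 17 heart beats),
  magnitude inversion-recovery fit `|a − b·exp(−TI/T1*)|` with exhaustive
  polarity restoration, Look-Locker correction `T1 = T1*(b/a − 1)`,
  translation-only frame registration, per-pixel T1 maps with a
  (100, 4000) ms plausibility gate.
* **LGE segmentation** — max SI from a small lesion-core ROI; classes
  non-enhanced (<20% of max SI), intermediate (20–50%), enhanced (≥50%,
  FWHM convention); threshold transfer between slices; largest-component
  ROI extraction.
* **ECV estimation** — R1 conversion, OLS partition-coefficient fit with
  R² as an equilibrium diagnostic, hematocrit-corrected ECV per ROI.
* **AHA segments** — six mid-cavity 60° segments anchored at the anterior
  RV insertion, radial wall thickness, hypertrophy (≥15 mm), BSA-indexed
  LV mass.
* **Cohort statistics** — Student/Welch/Mann-Whitney comparisons, one-way
  ANOVA with Bonferroni pairwise correction, chi-square proportion tests,
  uni-/multivariate ECV regression.
* **Pipeline CLI** — `simulate / fit-t1 / segment-lge / ecv / segments /
  report / run` subcommands with YAML configuration, per-subject failure
  isolation and provenance headers on every output.

## Worked example

Simulate nine LGE-positive subjects whose lesion core / border / remote
ground-truth ECVs are 0.45 / 0.35 / 0.27, run the full measurement pipeline
(register → fit T1 → classify LGE → per-class ECV), and compare:

```r
library(cmrfibrosis)
r <- recover_lge_cohort(seed = 7, n = 9,
                        lesion_ecv = c(core = 0.45, border = 0.35,
                                       remote = 0.27))
round(r$mean_ecv, 4)
#>     enhanced intermediate non_enhanced
#>       0.4485       0.3484       0.2704
r$ordering_ok
#> [1] TRUE
```

The recovered class means sit within 0.002 of the ground truth and the
ordering enhanced > intermediate > non-enhanced holds in every subject —
i.e. the 20%/50% threshold classifier plus the T1→λ→ECV chain reproduces
the tissue contrast it was given. A single subject looks like this:

```r
tm <- tissue_model(lambda_remote = 0.26 / (1 - 0.42), hematocrit = 0.42)
s  <- generate_subject(phantom_geometry(), tm, seed = 1, snr = 50)
res <- analyze_subject(s)
res$ecv
#> ECV = 0.2609 (lambda 0.4498, Hct 0.420)
```

with the regression R² ≥ 0.999 confirming the dynamic-equilibrium
collinearity of the three time points.

Command-line equivalent:

```sh
Rscript inst/cli/cmrfibrosis.R run --config run.yaml --seed 3 --out out/
# out/: subjects/ (image bundles + truth sidecars), cohort.csv, results.csv,
#       report/{table1.csv, table2.csv, tests.json}, provenance.json, log.txt
```

## Design notes

See `vignettes/ecv-methods.Rmd` for the signal model, the
variable-projection IR fit, threshold boundary semantics, the synthetic
world's stated conditions and what a green recovery test does and does not
establish.
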