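---
title: "Quantifying diffuse myocardial fibrosis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying diffuse myocardial fibrosis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Focal myocardial scar is visible on late gadolinium enhancement (LGE) images
because it retains extracellular contrast agent, but *diffuse* interstitial
fibrosis shifts signal everywhere at once and leaves nothing to contrast
against. The quantitative way around this is the extracellular volume
fraction (ECV): gadolinium distributes passively in extracellular water, so
after the agent has equilibrated between blood plasma and interstitium, the
tissue relaxation-rate change tracks the blood relaxation-rate change in
proportion to the tissue's extracellular volume. Concretely, with
$R_1 = 1/T_1$,

$$\Delta R_{1,\mathrm{myo}}(t) = \lambda\, \Delta R_{1,\mathrm{blood}}(t),
\qquad \mathrm{ECV} = \lambda\,(1 - \mathrm{Hct}),$$

where $\lambda$ is the contrast partition coefficient, estimated here as the
slope of an ordinary least-squares regression (with intercept) of myocardial
$R_1$ on blood-pool $R_1$ across three acquisitions: pre-contrast, about 8
minutes, and about 20 minutes after a 0.2 mmol/kg bolus. The hematocrit
factor converts the blood distribution volume to the plasma volume the agent
actually occupies. The regression $R^2$ is carried through the pipeline as a
diagnostic: at dynamic equilibrium the three points must be collinear, and a
low $R^2$ means the equilibrium assumption failed, not that the fit
"succeeded less".

The regression deliberately includes an intercept and regresses raw $R_1$
values, not deltas: with three points and an intercept the slope is
insensitive to a shared offset in the native values, and it is the natural
reading of regressing "myocardial $R_1$ versus blood $R_1$".

## T1 mapping: MOLLI 3(3)3(3)5 and the Look-Locker correction

`build_scheme_335()` constructs the sampling scheme: three inversions
yielding 3, 3, and 5 single-shot images with 3 recovery beats after the
first two blocks — 11 images in 17 heart beats. Within a block, image $j$
(counting from 0) has effective inversion time $\mathrm{TI}_k + j \cdot RR$.
Base inversion times are not standardised in the protocol literature we
model; the defaults (100, 180, 260 ms at RR = 1000 ms) are typical and
configurable.

The per-pixel signal model is the three-parameter apparent-relaxation form
for magnitude-reconstructed data,

$$s(\mathrm{TI}) = \left| a - b\, e^{-\mathrm{TI}/T_1^*} \right|,
\qquad T_1 = T_1^{*}\,\left(\tfrac{b}{a} - 1\right),$$

the last identity being the Look-Locker correction ($b = 2a$, i.e. perfect
inversion with full recovery, makes it the identity). Two numerical choices
matter:

* **Polarity restoration.** Magnitude reconstruction discards the sign of
  samples before the null crossing. We restore it by exhaustive search over
  the polarity index $p \in \{0,\dots,5\}$ (number of earliest-TI samples
  negated), keeping the candidate with minimal residual; ties go to the
  smaller $p$. Six candidates is enough because the null crossing of any
  physiologic curve under this scheme falls within the first five sorted
  samples.
* **Variable projection instead of 3-parameter descent.** For fixed $T_1^*$
  the model is linear in $(a, b)$, so the fit reduces to a one-dimensional
  profiled least-squares problem. A log-spaced $T_1^*$ grid (60–6000 ms, 45
  points) brackets the optimum and a golden-section interval search refines
  it to machine-level precision (45 iterations shrink the bracket by
  $\approx 10^{-9}$). This is deterministic — no starting-point sensitivity,
  no convergence failures to handle — and vectorises across all pixels of a
  map, which is what makes per-pixel fitting feasible in pure R. Degenerate
  pixels (constant signal, $b \le a$) get an invalid flag, never an error.

Fitted T1 outside (100, 4000) ms is marked invalid; the gate excludes air
and fit failures while leaving all physiologic myocardial and blood values,
pre- or post-contrast, untouched. Respiratory motion is handled by
translation-only registration of each frame to the longest-TI frame
(most recovered contrast), maximising absolute correlation — absolute,
because early-TI frames are contrast-inverted at the correct alignment.
Through-plane motion is out of scope, mirroring what in-plane manual
correction can and cannot do.

## LGE thresholding

The classifier anchors on the maximum signal (max SI) inside a small ROI in
the lesion core and partitions the myocardium at 20% and 50% of that value.
The conventional statement of the rule uses strict inequalities on both
sides and leaves the boundary values themselves unassigned; we assign
$[0.20, 0.50)$ to the intermediate class and $\ge 0.50$ to the enhanced
class, because the full-width-half-maximum convention includes the
half-maximum. Per-class ROIs are the largest
8-connected component above a minimum area, which mirrors selecting a
maximal contiguous region and, as a side effect, discards isolated
noise-flipped pixels near the class thresholds. In synthetic mode the core
ROI is auto-placed as a 3×3 square at the lesion-core centroid (the
generator's stand-in for the operator's "small ROI"); max SI is the single
maximal pixel in that ROI, with the ROI-mean alternative available.

## The synthetic world

Every stage above is validated by parameter recovery on a synthetic
mid-ventricular short-axis phantom: an annular myocardium around a circular
blood pool, with optional hypertrophic (thickened-epicardium) sectors and
annular-sector lesions split into core and border classes. The stated
conditions are:

* **Cohort structure** 16 HCM / 14 controls, 9 LGE-positive HCM subjects.
* **Relaxation defaults** native T1 1000 ms (myocardium), 1540 ms (blood);
  relaxivity 4.0 s⁻¹mM⁻¹ — typical 1.5 T values.
* **Contrast kinetics** blood concentration after the bolus follows a
  bi-exponential washout, $C(t) = 2.0\,e^{-0.3 t} + 1.0\,e^{-0.02 t}$ mM
  (fast mixing + slow clearance), the simplest form consistent with a
  strictly decreasing blood $R_1$ between 8 and 20 minutes. Myocardial
  $\Delta R_1$ is $\lambda \Delta R_{1,\mathrm{blood}}$ *by construction* —
  the generator lives at dynamic equilibrium, so the regression model is
  exactly true and slope recovery is a sharp test.
* **ECV targeting** per-subject $\lambda$ is derived from the drawn
  hematocrit as $\lambda = \mathrm{ECV}_{\mathrm{target}}/(1-\mathrm{Hct})$,
  so ground-truth ECV is pinned exactly while hematocrit varies
  realistically (0.45 ± 0.04 HCM, 0.42 ± 0.02 controls, truncated to
  (0.2, 0.6)).
* **Noise** Gaussian noise on two quadrature channels, i.e. Rician
  magnitude noise, at SNR 50 relative to the equilibrium signal.
* **Rendering** the MOLLI series is rendered from the apparent
  $T_1^* = T_1/(b/a-1)$ with $b/a = 1.9$ (slightly imperfect inversion);
  the LGE image is $|1 - 2 e^{-\mathrm{TI}/T_1}|$ at the 10-minute
  ground-truth T1, with TI chosen to null remote myocardium — which lands
  at ≈250 ms for the default tissue, consistent with clinical practice.
* **Lesion design** a 40° transmural core flanked by two 20° border rims
  (radial span 15–85% of the wall), so each SI class has a contiguous
  ground-truth region; core/border/remote ECVs are set to the reference
  values 0.45 / 0.35 / 0.27 when emulating LGE-positive patients.

What the generator does **not** emulate — and what a green recovery test
therefore does not establish — includes SSFP readout perturbation of the
inversion recovery beyond the $T_1^*$ formulation, heart-rate variability,
partial-volume mixing at tissue boundaries (pixels are pure tissue),
surface-coil shading, through-plane motion, and any real-data deviation
from dynamic equilibrium. Recovery tests certify the measurement chain, not
the physics of an MRI scanner.

## Geometry conventions

Angles are measured counter-clockwise in image coordinates; the anterior RV
insertion anchors the AHA mid-cavity division into six 60° segments,
traversed septum-first: anteroseptal, inferoseptal, inferior, inferolateral,
anterolateral, anterior. Wall thickness is the mean radial
epicardium-endocardium distance along 1° rays from the cavity centroid —
the simplest convention, exact for the concentric phantom anatomy and
documented as a limitation for strongly irregular shapes (a centerline
method would differ there). Hypertrophy is wall thickness ≥ 15 mm,
inclusive. LV mass uses slice area × (thickness + gap) × 1.05 g/mL and is
indexed to body surface area, which is treated as m² throughout.

## Statistics

Group comparisons default to the pooled-variance Student's t-test
(two-sided), with Welch and Mann-Whitney variants available — clinical
analysis plans rarely pin down which non-parametric fallback they mean, so
the choice is exposed as an argument rather than hard-coded. One-way ANOVA carries
Bonferroni-adjusted pairwise pooled t-tests
($p_{\mathrm{adj}} = \min(1, p \cdot n_{\mathrm{pairs}})$). Proportions use
the Pearson chi-square without continuity correction by default (flag
available); printed two-sided p-values from small 2×2 tables are sensitive
to exactly this choice, which is why reference p-values of that kind are
not used as recovery targets. Univariate screening admits predictors with
p < 0.05 into the multivariate linear model; a design condition number
above 10⁸ raises a collinearity flag.

## Serialization and reproducibility

Subject bundles are written as plain-text image stacks (`.tsv.gz` with a
dims header) plus a JSON sidecar carrying inversion times, time points,
hematocrit and ground truth; a NIfTI writer would be the natural choice but
no NIfTI package is available in the supported R environment, so the layout
is kept and the container substituted. Cohort generation is a pure function
of (config, seed): per-subject seeds are derived deterministically from the
cohort seed, and every pipeline output carries a provenance header
(package version, seed, config digest). The down-scaled phantom used in the
test suite (48-pixel grid, 2 mm pixels) preserves the anatomy at roughly a
quarter of the pixel count; the acceptance recovery runs use the
full-resolution default (96-pixel grid, 1.2 mm pixels). The end-to-end
null-cohort error-rate property is checked at a further reduced grid with
40 fixed-seed replicates, because full-size replication would dominate the
suite's runtime; the acceptance threshold itself is unchanged.

## Known limitations

* The IR fit models noise implicitly as Gaussian on the signed signal;
  Rician bias near the null is visible as a small (<1%) T1 bias at SNR 50
  and shrinks with SNR, as the bias-monotonicity test checks.
* Registration is integer-translation only; subpixel motion and rotation
  are not modelled by the generator and not corrected.
* ECV is computed ROI-mean-T1-first (average T1 over the ROI, then invert);
  averaging per-pixel R1 instead is available behind a flag and differs at
  the third decimal for physiologic ROIs.
* The blood-pool ROI is an eroded central disk; in real data, papillary
  muscles and slow-flow artefacts would require manual placement.
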