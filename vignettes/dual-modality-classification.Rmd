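---
title: "Dual-modality classification of oral lesions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality classification of oral lesions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralfusion)
```

## The problem and the model

Oral squamous-cell carcinoma is usually screened visually; two optical
techniques add quantitative, complementary information. A VELscope-type
device excites mucosa at 400–460 nm: healthy tissue emits pale green
autofluorescence (NADH, FAD, collagen, elastin), malignant tissue loses it
and appears dark and more heterogeneous. Raman spectroscopy measures
inelastic scattering: protein- and nucleic-acid-dominated tumor tissue
elevates fingerprint bands (1004 cm⁻¹ phenylalanine ring breathing,
1156, 1339, 1450, 1523, 1656 cm⁻¹) relative to lipid-dominated normal
mucosa.

The package implements the complete discrimination chain for a paired
design (one tumor and one adjacent-normal sample per patient):

1. Raman preprocessing to one normalized fingerprint spectrum per sample;
2. two scale-invariant autofluorescence features per circular ROI;
3. PCA per modality, LDA/QDA on the first two scores;
4. feature-level fusion: the four concatenated PC scores re-classified;
5. confusion-matrix metrics and LOOCV / stratified k-fold validation.

Tumor is the positive class everywhere: sensitivity is the true-positive
rate among tumors, specificity the true-negative rate among normals. We fix
this convention globally rather than follow published tables that
occasionally transpose the pair.

## Raman preprocessing

The chain is fixed: Savitzky–Golay smoothing → baseline correction →
crop/resample → normalization → replicate averaging → renormalization.

* **Savitzky–Golay** (order 3): the window length is not dictated by the
  acquisition protocol, so we default to 11 points at the 1 cm⁻¹ step —
  wide enough to suppress shot noise, narrow enough to leave the
  ~8 cm⁻¹-FWHM bands essentially undistorted. Edges use mirror padding so
  the axis keeps its length. The filter is exact on polynomials up to its
  order, which the tests exploit as an oracle.
* **Baseline**: no standard names a method for this kind of data, so we use
  iterative polynomial fitting (order 5, clamp-to-minimum refitting, at
  most 50 iterations, early exit at a 1e-8 relative tolerance) — the common
  choice for fluorescence-dominated Raman backgrounds. The estimate
  converges onto the lower envelope; an injected band's apex is preserved
  to within a few percent (tested at 5%).
* **Fingerprint window**: linear interpolation onto the canonical
  700–1800 cm⁻¹ grid at 1 cm⁻¹ (1101 points).
* **Normalization**: min–max per spectrum by default (normalized intensity
  in [0, 1]); unit-area and unit-norm modes are available.
* **Replicate averaging**: five replicate spectra per sample are averaged
  pointwise. The acquisition protocol does not fix whether normalization
  precedes averaging; we normalize first and renormalize the mean, which is
  robust to per-acquisition laser-power drift (the instrument class spans
  roughly a factor of two in power), and expose the other order via
  `average_before_normalize`.

## Autofluorescence quantification

Each ROI is a clinician-style disc (center, radius); a pixel belongs to it
iff its center lies within the radius, with 0-based `(cx, cy)` coordinates.
Features are computed on the green channel (the informative channel for
this kind of fluorescence) and normalized by the whole-image mean:

* `norm_intensity = mean(ROI) / mean(image)`
* `norm_heterogeneity = sd(ROI) / mean(image)` (population SD, divisor *n*,
  so one-pixel ROIs are deterministic)

Dividing by the image mean neutralizes global brightness differences caused
by content outside the ROI — teeth, devices, prostheses — and makes both
features exactly invariant under linear intensity rescaling. The original
formulation of this normalization is published only by reference, so the
denominator is a reconstruction of its stated purpose, not of its algebra;
whether the ROI's own pixels are included in the denominator is a config
switch (`include_roi_in_global`, default `TRUE`), and the artifact-injection
test verifies the intended direction (brighter denominator, lower
normalized intensity).

## Dimension reduction, classification, fusion

PCA is fitted unsupervised on the pooled two-class matrix by SVD, with a
deterministic sign convention (largest-magnitude loading positive).
A guard, `max_components()`, keeps the component count strictly below half
the smallest class size; with 35 + 35 samples that allows up to 17, but the
default is **k = 2 per modality** because the published analyses feed PC1
and PC2 of each modality to the classifiers (one account mentions
inspecting three Raman PCs but still classifies on two; we follow the fed
count and leave `k_components` configurable).

LDA and QDA are implemented directly as Gaussian discriminants: empirical
class means and priors, pooled (linear) or per-class (quadratic)
covariance, discriminant score = exact log-density + log-prior. A ridge of
`1e-8 × mean(diag(Σ))` guards numerical rank in 4 dimensions with 35
samples per class; it is not a tuning parameter. Ties in the argmax resolve
to the lexicographically first label. Fitted models serialize to JSON for
audit. The test suite cross-checks scores against a direct
`solve()`/`det()` log-density oracle and predictions against the reference
implementations in MASS.

Fusion concatenates the two score pairs (rows aligned by sample id) into a
4-feature matrix. Scores are fused raw — no rescaling is part of the
published procedure — but `standardize = TRUE` divides each column by its
SD for sensitivity analysis.

## Cross-validation and leakage policy

LOOCV and stratified, seeded k-fold (default k = 10; the published account
does not state k) are provided. Two policies are reported side by side:

* default: PCA refitted inside every training fold (no information from
  the held-out sample reaches the transform — statistically sound);
* `paper_mode`: PCA fitted once on all samples, only the classifier is
  cross-validated — the reduce-then-validate shortcut implied when
  dimension reduction precedes validation.

Patient pairing (tumor + normal from the same patient) is deliberately
**not** grouped across folds by default, matching per-sample published
counts; grouping would be the stricter choice for generalization claims.

## The synthetic cohort generator

Clinical images and spectra of this kind are not publicly distributable, so
the generator emulates the statistical structure the analysis assumes, with
the study design as defaults: 35 patients × {tumor, normal} × 5 replicate
spectra (350 raw → 70 averaged) and one image per patient with two disjoint
ROIs.

A spectrum is `polynomial baseline + Σ Gaussian bands + iid N(0, σ)` noise
on 600–1900 cm⁻¹ at 1 cm⁻¹. Band shape is Gaussian with 8 cm⁻¹ FWHM
(no lineshape is dictated; this matches sharp fingerprint bands). Tumor
samples multiply the six discriminating bands by 1.5 and leave 1123 cm⁻¹
unchanged. Biological variability is drawn once per tissue sample and
shared by its replicates: a common log-amplitude factor (SD 0.20, overall
scattering level) and per-band log-amplitude jitter (SD 0.10). Images are
green-dominant backgrounds; the tumor ROI is drawn at
`background × (1 − drop)` with pixel SD multiplied by the heterogeneity
gain (defaults 0.35 and 2.0), and both ROIs receive iid patient-level
jitter (drop SD 0.16, log-gain SD 0.45) so that a null effect is exactly
class-symmetric. Reproducibility uses one root seed with per-patient child
streams, making cohorts bit-identical for identical specs and stable under
patient subsetting.

No quantitative tumor/normal intensity ratios are published for any band,
so the jitter scales cannot be claims of fidelity. They were calibrated
once — as the generator's definition of a "realistic" cohort — so that each
single modality lands in the 80–90% LOOCV-accuracy band characteristic of
this kind of study (measured means: Raman ≈ 83%, images ≈ 90%, fused
≈ 95%), and are exposed in `effect_params()` rather than hidden.

What the generator does **not** emulate: spatial spectral heterogeneity
within a sample (replicates differ only by noise), instrument drift and
cosmic rays, specular glare, lesion-shape irregularity, inflammation-driven
false positives, and any correlation between a patient's Raman and
autofluorescence effect sizes (the modalities are conditionally
independent given the class). Passing tests therefore demonstrate the
correctness and stability of the analysis chain under the assumed
structure, not clinical performance.

A known behaviour worth flagging: with min–max normalization a uniform 1.5×
elevation of the discriminating bands cancels in relative band heights, so
the class contrast is carried largely by the relative suppression of the
1123 cm⁻¹ band. Restricted to two principal components, occasional cohorts
relegate that contrast to PC3 and Raman-only LOOCV degrades sharply — a
realistic fragility of fixed-k PCA pipelines that the fused classifier
largely absorbs.

## Numerical choices and degenerate inputs

* Non-uniform grids are rejected with instructions to resample; coverage
  errors name the missing wavenumber range.
* Min–max normalization of a constant spectrum, PCA of identical rows,
  discriminants with coincident class means or singular covariance at zero
  ridge, empty ROI masks and non-positive image means all raise typed
  errors (`oralfusion_*` condition classes) rather than propagating NaN.
* All percentages are computed unrounded; printing rounds.
* Problem sizes in the test suite are chosen to keep the full run in a few
  minutes: oracle checks use tiny matrices; the cross-validation property
  tests use 35-patient cohorts over 50 seeds (fusion gain), 3 cohorts
  (chance-level nulls) and 12-patient cohorts over 50 seeds (CV optimism).

## A small worked run

```{r example}
rep <- run_pipeline(pipeline_config(cohort_spec(n_patients = 8, seed = 4)))
rep
```

The three blocks (`raman`, `velscope`, `fused`) each contain the PCA
models, resubstitution confusion matrix and metrics, and LOOCV/k-fold
results for both classifier kinds; `report_summary()`-style JSON plus
feature CSVs and serialized models are written when `out_dir` is set.

## Known limitations

* Two classes only; premalignant lesions (the clinically hardest group) are
  out of scope.
* ROIs are given, not segmented; no glare removal.
* No probability calibration, ROC analysis or confidence intervals — the
  published comparison reports point metrics only, and we deliberately do
  not extend beyond them.
* The synthetic calibration targets plausibility of *aggregate* accuracy,
  not spectra that a spectroscopist would mistake for real tissue.
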