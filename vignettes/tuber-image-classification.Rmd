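---
title: "Classifying medicinal tubers from images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying medicinal tubers from images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Alismatis Rhizoma (AR) is the dried tuber of *Alisma* species used in
traditional Chinese medicine. Its market value and pharmacology depend on the
source species (*A. plantago-aquatica* vs *A. orientale*) and on the growing
region, but dried tubers from different sources look similar enough that
authentication by eye is unreliable. The pipeline in this package identifies
species (2 classes) and geographic origin (4 classes: SC and GX for species
A, FJ and JX for species B) from a single photograph of one tuber on a
contrasting background, using classical machine-vision features and shallow
classifiers rather than deep networks, so that every step is inspectable and
cheap to run.

The original study's 400 photographs are not publicly deposited, so the
package ships a synthetic-data generator that emulates the dataset's
statistical structure. Everything downstream — preprocessing, feature
extraction, model fitting, evaluation — is the real method and would apply
unchanged to real photographs read with `read_image()`.

## Pipeline

1. **Preprocess** (`preprocess_image()`): 3×3 median filter per RGB channel;
   conversion to HSV; binarisation of the saturation channel (the colourful
   tuber sits on a near-achromatic background); cleanup to a single
   hole-free component; background set to pure white.
2. **Features** (`extract_features()`): a 17-element vector per image —
   three shape descriptors, two colour means, twelve texture statistics.
3. **Modeling** (`train_model()`, `run_study()`): seven fusion subsets of
   the three feature groups × four classifiers, trained on a stratified 7:3
   split.
4. **Evaluation** (`evaluate_model()`, `kfold_cv()`, `anova_models()`):
   confusion matrices, one-vs-rest precision/recall/F1 with macro averages,
   stratified 10-fold cross-validation, one-way ANOVA across models with
   per-model 95% confidence intervals.

## Feature definitions

**Shape** (from `region_props()` on the mask): circularity C = 4πA/P²,
rectangularity R = A/A_R (A_R the axis-aligned bounding-box area), and
aspect ratio L = J/I from the moment-equivalent ellipse. Area A is the
foreground pixel count. The perimeter P is the Moore boundary chain-code
length with diagonal steps weighted √2; this overestimates a smooth
continuous boundary by up to ~5%, so C for a digital disc lands near 0.91
rather than 1.0 — consistent, not bias-corrected. Axis lengths are
4·√eigenvalue of the foreground coordinate covariance with the standard
+1/12 unit-pixel correction (MATLAB `regionprops` semantics), which makes L
exact on axis-aligned rectangles. C is not clamped at 1.

**Colour** (`mean_hs()`): arithmetic means of the HSV hue and saturation
channels over foreground pixels only. Averaging over the whitened full
frame (closer to a naive `mean2` on the cleaned image) would couple the
feature to how much background padding an image carries; the full-frame
variant remains available via `foreground_only = FALSE`. Hue is averaged
arithmetically, not circularly — adequate away from the 0/1 wrap point,
where the default prototypes live; hues straddling the wrap would need a
circular mean.

**Texture** (`texture_features()`): the image is reduced to Rec.601
luminance, quantised to G = 16 equal-width levels, and gray-level
co-occurrence matrices (GLCMs) are computed at distances d ∈ {1, 2, 4} px
and angles θ ∈ {0°, 45°, 90°, 135°}, symmetric, counting only pixel pairs
that lie entirely inside the foreground (otherwise the white background
dominates the counts). From each GLCM: ASM = Σp², CON = Σ(i−j)²p,
COR = |Σ i·j·p − μxμy|/(σxσy) (0 when a marginal is degenerate),
ENT = −Σp·log₂p. Statistics are averaged over the four angles, giving
4 × 3 = 12 texture features. The 12-feature composition (statistics ×
distances, angle-averaged) is a design choice: it matches the published
feature count while keeping the vector robust to in-plane rotation, and is
fully configurable through `glcm_config()`. The entropy is implemented with
the conventional minus sign (so ENT ≥ 0, zero only for a single-valued
texture); the correlation uses the absolute value, so COR ∈ [0, 1].

## The synthetic generator

`render_sample()` draws one tuber as a randomly rotated ellipse with a
bounded low-order radial perturbation (harmonics 2–4, each ≤ 4% by default),
which keeps the region simply connected and the ground-truth axis ratio
computable while breaking the perfect-ellipse regularity. Class structure
enters through four prototypes (`default_prototypes()`), one per origin:

| origin | species | axis ratio | hue | saturation | roughness amp | scale (px) |
|--------|---------|-----------|------|-----------|----------------|-----------|
| SC | A | 1.15 ± 0.05 | 0.10 | 0.55 | 0.10 | 4 |
| GX | A | 1.45 ± 0.05 | 0.13 | 0.65 | 0.20 | 4 |
| FJ | B | 1.15 ± 0.05 | 0.08 | 0.75 | 0.30 | 6 |
| JX | B | 1.70 ± 0.05 | 0.11 | 0.85 | 0.40 | 6 |

Surface texture is a Gaussian random field smoothed to the prototype's
correlation length, multiplying the HSV value channel with the prototype's
relative amplitude — a single monotone handle on the GLCM statistics
(contrast rises, ASM falls, as amplitude grows). The background is
near-white with saturation below a configurable ceiling (0.08), and i.i.d.
Gaussian channel noise (sd 2 on the 0–255 scale) is added last. The source
study quantifies none of these class distributions, so the prototype values
are free parameters chosen once to be separable jointly but ambiguous
singly: species differ mainly in saturation, origins within a species in
axis ratio and roughness. No single feature group separates all four
origins, which is what gives the fusion ablation its structure.

Configuration is validated up front: every prototype must satisfy
`sat_mean − 3·sat_sd > background_sat_max` (the segmentability guarantee
that makes Otsu thresholding reliable) and the largest blob must fit with a
≥ 5 px margin. Defaults: 100 images per origin, 128 × 128 px — small enough
that the full 400-image study (generation through ablation) runs in about a
minute on one CPU, large enough that discretisation error in the shape
features stays within the tolerances the tests assert.

What the generator does **not** emulate: lighting gradients and shadows,
JPEG compression artifacts (output is lossless PNG), the transverse
annular grooves of real AR tubers, camera geometry, and multi-object
scenes. Passing tests therefore demonstrate that the pipeline recovers the
class structure it assumes — shape/colour/texture differences of the
modelled kind — not that it would reach any particular accuracy on real
photographs.

## Preprocessing choices

- **Threshold selection.** The source protocol states no threshold; the
  default is Otsu's criterion on a 256-bin saturation histogram
  (`otsu_threshold()`), parameter-free and reproducible; a fixed numeric
  threshold can be passed instead.
- **Connectivity.** 8-connected foreground with 4-connected background —
  the standard dual pair that avoids topological paradoxes in hole
  filling. Cleanup keeps the largest component (robustness to background
  specks) and fills interior holes by flood-filling the background from the
  raster border.
- **Median kernel** defaults to 3×3 (the 3×3 case is an exact median-of-9
  computed by a sorting network; larger kernels delegate to EBImage).
- **Idempotence.** Re-preprocessing an already-cleaned image reproduces the
  mask and the white background exactly; interior foreground pixels can
  shift slightly because a median filter is not idempotent on textured
  regions. Whitening never alters a pixel inside the mask.

## Modeling choices

The split is stratified 7:3 (largest-remainder rounding per class), fixed
per seed across the whole ablation so rows are comparable. No
hyperparameters were published; defaults are conventional: random forest
with 500 trees; RBF SVM with C = 1, γ = 1/p; a single-hidden-layer
backpropagation network with 32 units, up to 500 epochs, weight decay 1e-4;
ELM with 100 sigmoid hidden nodes. Features are z-scored with training-set
statistics for the scale-sensitive SVM/BP/ELM (constant features pass
through); the random forest sees raw features. The ELM is implemented in
the package: input weights and biases drawn uniform(−1, 1) from the seed and
fixed, hidden activations H = σ(XW + b), output weights β = H⁺ · one-hot(y)
by Moore–Penrose pseudoinverse — least squares with no iteration, and no
failure mode on rank-deficient H. A ridge term is deliberately omitted as
the minimal faithful reading of the method; regularisation could be added
where collinearity demands it.

The published split counts ("210 training / 90 test") are inconsistent with
400 images at 7:3; the package implements the exact 280/120 stratified
split, which matches the granularity of the published test accuracies
(e.g. 99.17% = 119/120).

## Evaluation choices

Per-class metrics are one-vs-rest; zero denominators yield 0 by the common
convention rather than NaN. Both per-class and macro aggregates are
reported, since published per-class "accuracy" columns are ambiguous.
Cross-validation folds are stratified and seeded (stratification is a
choice, not stated in the source). The ANOVA is fixed-effects one-way over
per-fold accuracies; all-identical groups are reported as degenerate
(p = NaN) rather than an arbitrary significance claim. Confidence intervals
are t-based (mean ± t₀.₉₇₅,ₙ₋₁ · se) per model.

## Reproducibility

A single global seed fans out to per-stage seeds through a fixed affine
rule (`seed · 1009 + stage offset`), so generation, splitting, model fits
and CV folds each get a private, collision-free stream. Two runs with the
same configuration and seed produce byte-identical images, feature tables
and reports — this is asserted by the test suite.

## Worked example

```{r}
library(tuberscope)

study <- run_study(config = synthetic_config(), seed = 1)
head(format_ablation(study$ablation))

cv <- kfold_cv(study$features, kind = "RF", task = "origin",
               groups = c("S", "T"), k = 10, seed = 1)
cv$mean
```

The `analysis/` directory decomposes the same study into five numbered
stage scripts (simulate, preprocess, extract, ablate, evaluate) that
exchange files under `results/`, and `scripts/acceptance.R` recomputes the
headline quantities from scratch into a JSON report.

## Known limitations

- Synthetic blobs are convex-ish and hole-free by construction; the
  pipeline's robustness to concave or perforated tubers is untested.
- The arithmetic hue mean is wrong for hue distributions straddling 0/1.
- The chain-code perimeter's ~5% positive bias propagates into circularity;
  comparisons across images are consistent, absolute values are not
  calibrated to continuous geometry.
- Accuracy figures obtained on synthetic data characterise the pipeline,
  not real Alismatis Rhizoma; the published accuracies on the original
  photographs are not reproducible without those images.
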