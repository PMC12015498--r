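# tuberscope

Image-based identification of the species and geographic origin of dried
medicinal tubers (Alismatis Rhizoma, the rhizome of *Alisma* species used in
traditional Chinese medicine). Given a photograph of a single tuber on a
contrasting background, the pipeline segments the tuber, extracts a
17-element feature vector, and classifies it into one of two source species
(*A. plantago-aquatica*: origins SC, GX; *A. orientale*: origins FJ, JX) or
one of the four origins directly.

The package is aimed at researchers in herbal-material authentication and
at anyone who needs a fully inspectable, classical machine-vision baseline
(no pretrained networks) for single-object image classification. The
original study's 400 photographs are not deposited, so the package includes
a synthetic tuber-image generator with controllable class structure; every
downstream stage is the real method and applies unchanged to real images.

## Method

For each image, after median denoising, HSV conversion, Otsu thresholding
of the saturation channel, mask cleanup and background whitening:

- **Shape (3):** circularity C = 4πA/P², rectangularity R = A/A_R,
  aspect ratio L = J/I, from area A, chain-code perimeter P, bounding-box
  area A_R, and the moment-equivalent ellipse axes J ≥ I.
- **Colour (2):** means of the HSV hue and saturation channels over the
  foreground.
- **Texture (12):** gray-level co-occurrence matrices (G = 16 levels,
  symmetric, foreground-only) at distances d ∈ {1, 2, 4} px, angle-averaged
  over θ ∈ {0°, 45°, 90°, 135°}; from each, ASM = Σp²,
  CON = Σ(i−j)²p(i,j), COR = |Σ ij·p − μxμy|/(σxσy), ENT = −Σp·log₂p.

Feature groups S (shape), C (colour), T (texture) and their seven fusions
feed four classifiers — backpropagation network (BP), random forest (RF),
RBF support-vector machine (SVM), and an extreme learning machine (ELM,
implemented here: random fixed input weights, pseudoinverse least-squares
output weights, no iterative training) — on a stratified 7:3 split.
Evaluation covers confusion matrices, one-vs-rest precision/recall/F1 with
macro averages, stratified 10-fold cross-validation, and one-way ANOVA
across models with 95% confidence intervals.

See `vignettes/tuber-image-classification.Rmd` for the full methods
account and design rationale.

## Worked example

```r
library(tuberscope)

study <- run_study(config = synthetic_config(), seed = 1)   # ~1 min
tab <- format_ablation(study$ablation)
tab[tab$Task == "origin" & tab$Models == "RF", -1]
```

```
 Models Fusion feature Feature number/pcs Training set accuracy/% Test set accuracy/%
     RF              S                  3                  100.00               66.67
     RF              C                  2                  100.00               96.67
     RF              T                 12                  100.00               89.17
     RF            S+T                 15                  100.00               99.17
     RF            S+C                  5                  100.00               99.17
     RF            C+T                 14                  100.00               96.67
     RF          S+C+T                 17                  100.00              100.00
```

Each row is one fusion of feature groups for the four-origin task: shape
alone reaches 66.67% on the 120-image test set, texture alone 89.17%, and
the shape+texture fusion 99.17% — multi-feature fusion outperforming any
single group, which is the study's central qualitative finding. 10-fold
cross-validation of the shape+texture random forest:

```r
kfold_cv(study$features, kind = "RF", task = "origin",
         groups = c("S", "T"), k = 10, seed = 1)$mean
#> [1] 0.9875
```

The numbered scripts under `analysis/` run the same study as five separate
stages (simulate → preprocess → extract → ablate → evaluate), writing
images, feature tables and report tables under `results/`.

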