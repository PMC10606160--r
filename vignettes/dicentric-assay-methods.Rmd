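---
title: "Methods: automated dicentric chromosome assay with a compact one-stage detector"
author: "dicentricAssay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated dicentric chromosome assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The dicentric chromosome assay (DCA) is the reference method of cytogenetic
biodosimetry: after an accidental or clinical radiation exposure, the
absorbed dose is estimated by counting dicentric chromosomes — aberrant
chromosomes carrying two centromeres, produced by misrepair of
radiation-induced double-strand breaks — in Giemsa-stained metaphase
spreads. A normal human metaphase contains 46 chromosomes, each with one
centromeric constriction; the dicentric yield per cell rises with dose
(background is roughly 1 per 1000 cells) and follows a linear-quadratic
dose-response for photon exposures. Manual scoring is accurate but slow and
expertise-bound, which is exactly the bottleneck in mass-casualty triage.

`dicentricAssay` automates the full loop as a single R toolkit:

1. **synthesis** — metaphase-like images with exact ground truth,
2. **labeling** — automatic bounding boxes from Otsu thresholding and
   connected components,
3. **augmentation** — copy-paste of segmented chromosome patches to
   rebalance the rare dicentric class,
4. **detection** — a compact anchor-based one-stage convolutional detector
   trained with the CIoU location loss and binary cross-entropy
   objectness/class losses by mini-batch SGD,
5. **evaluation** — precision/recall at IoU 0.5, F1-confidence curves,
   all-point-interpolated AP and mAP, chromosomes per metaphase,
6. **dose estimation** — weighted least-squares fit of
   F(D) = αD² + βD + γ and inversion of the quadratic to a dose in Gy.

Everything runs on a laptop CPU in minutes; no GPU, no external dataset,
no pretrained weights are required (a checkpoint produced elsewhere can be
supplied to `chromosomeDetector(init = ...)` for warm starts).

## The synthetic metaphase generator

There is no public metaphase image corpus bundled with the package, so the
generator is a first-class module, not a test fixture. A chromosome is
rendered as a band of varying radius around a quadratic Bézier medial
axis: the chord length is the chromosome length, the bend angle is the
curvature, and the band radius follows a cosine-notch profile — one notch
(a centromeric constriction, 55% of the width removed by default) for a
normal chromosome, two interior notches at 32% and 68% of the axis for a
dicentric. Chromosomes are placed by rejection sampling with a hard
constraint of zero mask overlap and a configurable Chebyshev-metric gap
(2 px at defaults), because the threshold-based labeling procedure assumes
separable objects. Additive Gaussian noise is applied last and clipped to
the 8-bit range. The Giemsa convention is dark chromatin (gray level 60)
on a light slide (gray level 220); an `invert` flag flips it.

Defaults mirror the conditions of a real assay image: a 640×640 canvas
with 46 chromosomes, lengths 40–90 px. `deskSceneSpec()` is the scaled-down
preset used for the package's training demonstrations and tests: 320 px,
12 chromosomes of length 28–44 px of which 3 are dicentric, noise SD 5.
These sizes were fixed once when the preset was designed: the chromosomes
must be large enough to be resolvable at the detector's stride-8 scale and
numerous enough that a scene is non-trivial, while a full train/evaluate
cycle stays in the minutes range on one CPU core.

What the generator deliberately does **not** emulate: chromatid banding
texture, stain debris, intensity gradients, blur, and — most importantly —
touching or overlapping chromosomes. Passing results on synthetic scenes
therefore demonstrate that the pipeline's machinery is correct, not that
the detector would reach the same accuracy on clinical metaphase images,
where overlaps and texture dominate the error budget.

The per-image dicentric count can be fixed, or drawn from
`Poisson(F(D))` with F from a supplied dose-response model, which closes
the loop for end-to-end dose-recovery simulations.

## Automatic labeling

Normal chromosomes are labeled exactly the way a practitioner scripts it:
a global Otsu threshold (maximizing between-class variance over the 256
8-bit levels; ties resolved to the lowest level; the darker side is
foreground), 8-connectivity connected components, an area filter
(`minArea = 20` px, needed because raw thresholding of noisy images
produces specks), and the tight box of each surviving region. Touching
chromosomes merge into one region — an accepted limitation of the
procedure, which is why the generator enforces separability. The
connected-component labeling is implemented in compiled code with a
selectable 4- or 8-connectivity; a flood-fill oracle in the test suite
verifies the partition.

## Copy-paste augmentation

Dicentrics are rare, so the detector's training set is rebalanced by
compositing segmented chromosome patches into images: a patch is cut from
a source box, Otsu-segmented inside the crop, reduced to its largest
connected component, and pasted at a uniformly sampled position where its
mask (dilated by a 2 px margin) overlaps zero foreground pixels. Only mask
pixels are composited, so the paste carries no rectangular halo. For every
dicentric paste, one normal patch is pasted alongside (`normalPerDicentric
= 1`), so the model cannot learn to recognize dicentrics by segmentation
edges alone. Patch pools are kept per split — training patches are never
pasted into validation images — to avoid leakage between splits.
Random flips and 90° rotations of patches are enabled by default for pose
diversity and can be switched off.

## The detector

The detector is a deliberately compact anchor-based one-stage network —
about 38,000 parameters at the default widths, far below the 0.5 M
ceiling the package sets itself — with two detection scales:

* backbone: three 3×3 stride-2 convolutions (widths 8, 16, 24) to
  stride 8, followed by a three-conv trunk at stride 8 and a parallel
  stride-2 branch (width 32) to stride 16; leaky-ReLU (slope 0.1)
  activations;
* heads: a 1×1 convolution per scale emitting, for each of 3 anchors per
  cell, `(t_x, t_y, t_w, t_h)`, an objectness logit and one logit per
  class.

Raw outputs decode against the grid and anchor priors as

$$b_x = \sigma(t_x) + C_x,\quad b_y = \sigma(t_y) + C_y,\quad
  b_w = p_w e^{t_w},\quad b_h = p_h e^{t_h},$$

with centers in grid units (scaled by the stride to pixels) and `t_w, t_h`
clamped to ±12 so the exponential cannot overflow. Anchor priors are
estimated from the training boxes by k-means under the `1 − IoU` distance
(boxes compared concentric), with mean width/height centroid updates; the
iteration stops, keeping the previous centroids, if a mean update would
increase the objective, so the reported objective is non-increasing by
construction. Sorted by area, the smallest three anchors serve the
stride-8 grid and the largest three the stride-16 grid.

Each ground-truth box is assigned, at every scale, to the cell containing
its center and the free anchor of highest concentric IoU. The training
loss is a weighted sum of three parts:

* **location**: the complete-IoU (CIoU) loss
  $1 - IoU + \rho^2/c^2 + \alpha\upsilon$ (center-distance and
  aspect-ratio penalties on top of IoU), averaged over assigned slots;
* **objectness**: binary cross-entropy of the predicted confidence at
  every (cell, anchor) slot, the no-object slots down-weighted by
  $\lambda_{noobj} = 0.5$, since almost all of the
  $S^2 B$ candidates contain nothing;
* **class**: per-class binary cross-entropy at object slots only, with
  one-hot targets.

All probabilities are clamped to $[10^{-7}, 1-10^{-7}]$ inside the logs,
so every loss is finite. Target confidence is 1 at assigned slots (the
binary reading of the objectness term), not IoU-valued.

### Numerical choices in training

Training is plain mini-batch SGD with momentum 0.9, matching the
optimizer of the original protocol at configurable scale. Three choices
matter for stability and are worth recording:

* **Gradient path.** The convolution forward/backward passes run in
  compiled code (im2col + GEMM). Objectness and class gradients are the
  exact `σ(z) − y` forms; the location gradient uses central finite
  differences of the CIoU value with respect to the decoded center/size
  (step 10⁻³ px) chained through the analytic decode Jacobian. A test
  verifies the end-to-end gradient against finite differences through the
  whole network.
* **Gradient clipping.** The objectness term is a sum over thousands of
  slots, so early batch gradients are large; the global gradient norm is
  clipped to 20 before the momentum update. Without clipping, learning
  rates that are otherwise well-behaved diverge.
* **Loss weights and schedule.** Component weights default to
  (location 10, objectness 1, class 2) in the desk training preset: with
  the objectness sum dominating the raw gradient, an unweighted sum
  leaves box regression underpowered. A half-cosine decay of the learning
  rate (0.02 → 0.001 over the run) is used by the preset; constant
  learning rate remains the function default for reproducibility of
  simple examples. The objectness bias is initialized to −4 so the
  untrained network predicts a low object prior.

Inference decodes every slot, scores each candidate as
objectness × best class probability, drops candidates below the score
threshold, and applies greedy per-class non-maximum suppression. Per-class
suppression is the default because a duplicate box of the *wrong* class
should count against that class's precision rather than silently deleting
the correct detection (class-agnostic suppression is available and
measurably lowers mAP on synthetic scenes for exactly this reason).

## Evaluation

Matching is greedy at a fixed IoU threshold of 0.5: per class, detections
in descending confidence order take the unmatched ground truth of highest
IoU. Dataset-level curves are computed after pooling matches across
images. The F1-confidence curve is evaluated exactly at every distinct
detection confidence (plus the endpoints), not on a binned grid. AP is
the all-point interpolated area under the precision-recall curve
(monotone precision envelope); mAP is the unweighted mean over classes;
confidence ties are broken by higher IoU, then input order. The
chromosomes-per-metaphase statistic (total detections across both classes
divided by images) is the assay-specific sanity check against the
expected 46.

## Dose-response fitting and inversion

Calibration points `(dose, n_cells, n_dicentrics)` are fitted by weighted
least squares to F(D) = αD² + βD + γ with weights `n_cells`, the
Poisson-motivated choice (frequency variance scales as 1/n). Three
noise-free points at distinct doses are interpolated exactly. A negative
fitted background γ is clipped to zero with a warning — γ is a frequency.
Near the boundary this truncation makes the *reported* γ biased upward
even though the least-squares estimator itself is unbiased; the package's
Monte-Carlo recovery study therefore runs at a background (0.02/cell)
where the constraint stays inactive. At a realistic human background of
~0.001/cell, an unbiased γ needs many more than 10³ cells at dose 0 —
which is exactly why calibration laboratories score thousands of cells at
low doses.

Dose estimation inverts the quadratic: for α > 0,
$D = (-β + \sqrt{β² + 4α(F − γ)})/(2α)$, the non-negative root; α = 0
falls back to the linear solution; F ≤ γ returns 0 Gy, as does a negative
discriminant (possible only for F < γ), with a warning. The round trip
`estimateDose(m, doseResponse(m, D)) = D` is exact to floating point, and
the estimate is monotone in F for α, β > 0.

## The pipeline and reproducibility

`runPipeline()` chains generation → labeling → augmentation → training →
evaluation → dose calibration. Every stage derives its RNG stream from
one root seed by fixed offsets, artifacts are stamped with an MD5 hash of
the configuration, completed stages are skipped when re-entered with an
unchanged configuration, and two fresh runs with the same configuration
are byte-identical in labels, loss history and reports. The default
pipeline configuration is a miniature (160 px scenes, 24 training images,
15 epochs) chosen so the full loop, run twice, completes in about two
minutes.

## Problem sizes used by the test suite

The package's own checks run at sizes fixed when the suite was designed:

* labeling recovery: 100 default-scale metaphases (640 px, 46
  chromosomes);
* augmentation contract: 50 desk-preset images rebalanced from 5 to 50
  dicentric boxes;
* detector training: 200 desk-preset images (12 chromosomes each, 3
  dicentric), 30 epochs, evaluated on 50 held-out images;
* overfit sanity: one image, 200 single-image epochs;
* dose recovery: 5 doses × 10³ cells × 100 replicates.

## Known limitations

* The synthetic scenes are separable by construction; real metaphases
  contain touching and overlapping chromosomes that both the labeling
  procedure and the detector would mishandle.
* The detector is intentionally tiny and trained for tens of epochs; it
  demonstrates the training dynamics (decreasing losses, recoverable
  boxes) and reaches useful accuracy on synthetic scenes, but it is not a
  production dicentric scorer and no pretrained backbone is bundled.
* The labeling module does not split merged regions (no watershed); how a
  production pipeline should curate merged boxes is left open.
* Dose estimation ships no uncertainty interval by default; the
  coefficient covariance is stored on the fitted model for users who want
  the delta method.
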