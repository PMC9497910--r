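---
title: "Tile-based FCN segmentation of cytology whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-based FCN segmentation of cytology whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Rapid on-site evaluation (ROSE) of EBUS-TBNA aspirate smears asks a
cytopathologist to find metastatic tumor cells on a gigapixel whole-slide
image (WSI) within minutes. `cytofcn` implements a fully automatic pipeline
for this task: the slide is decomposed into a patch-based hierarchical tile
structure, background tiles are discarded cheaply, and the remaining tiles
are segmented per pixel into background (class 0), benign/nontarget cells
(class 1), and malignant/target cells (class 2) by a single-stream fully
convolutional network, whose tile outputs are stitched back into a
slide-level class map and tumor segmentation.

## Tiling and coordinates

A pyramid level of width $W$ and height $H$ is cut into
$\gamma = \lfloor W/w \rfloor$ columns and $\zeta = \lfloor H/\psi \rfloor$
rows of $w \times \psi$ tiles (default $512 \times 512$). A pixel
$(i, j)$ (0-based, column/row, origin top-left) lives in tile
$\alpha = \lfloor i/w \rfloor$, $\beta = \lfloor j/\psi \rfloor$ at in-tile
offset $x = i - \alpha w$, $y = j - \beta\psi$; the floor arithmetic
discards the border remainder, which rarely holds material of interest, so
the stitched output measures $\gamma w \times \zeta\psi$ pixels rather than
the original slide extent. Internally pyramid levels are indexed
$v = 1..N$ with $v = N$ the full resolution; file readers that number the
full-resolution page first are inverted by the adapter in `read_pyramid()`.

## Background filtering

Filtering runs on the coarsest pyramid level that still holds at least one
unit tile's worth of pixels and one full tile in both axes
(`select_filter_level()`), so a gigapixel slide is thresholded on a
thumbnail. The level image is converted to Rec.601 luminance, Otsu's
method (256-bin histogram, exhaustive maximisation of between-class
variance, deterministic lowest-cut tie-break) gives a threshold, and
pixels strictly darker than it count as tissue — stained cells are dark on
bright glass. Each full-resolution tile footprint is projected onto the
mask by exact rational scaling with area-weighted boundary pixels
(implemented with a bilinearly interpolated summed-area table, which is
exact for piecewise-constant masks), so the measured tissue fraction does
not depend on which level the mask was computed on when the mask is ideal.
A tile is kept iff its tissue fraction is at least 0.70; the rule
discards patches with *less than* 70% tissue, so exactly 70% is kept.
Slides with no kept tiles short-circuit to an all-background result
without a single model call.

## The network

The model is a five-block VGG-style fully convolutional network with a
single 32-pixel-stride upsampling path: blocks of 2/2/3/3/3 3x3 stride-1
convolutions (widths 64/128/256/512/512) each followed by ReLU and a 2x2
stride-2 max-pooling; then a 7x7 convolution to 4096 channels with
dropout 0.5, a 1x1 convolution to 4096 with dropout 0.5, a 1x1 score
convolution to 3 channels, one 64x64 stride-32 transposed convolution back
to 3 channels, a crop to the input extent and a per-pixel softmax.

Tabular descriptions of this architecture family often state "same"
padding, which cannot produce the canonical feature sizes (a 512 input
cannot become 710 under same padding). The sizes are reproduced exactly
by the original FCN reproduction conventions, adopted here: the first
convolution is zero-padded by 100, all other 3x3 convolutions by 1, the
7x7 and 1x1 convolutions are unpadded, pooling uses ceiling-mode output
sizes $\lceil s/2 \rceil$, the transposed convolution maps side $s$ to
$(s-1) \cdot 32 + 64$, and the final crop removes a fixed 19-pixel offset
(the standard FCN-32s alignment) before cutting the input-sized window.
Under these conventions a 512 input traces to
710, 355, 178, 89, 45, 23, 17 and 576 exactly; `shape_trace()` is the
closed-form oracle for this arithmetic and the live forward pass is tested
against it layer for layer.

Counting conventions for this architecture differ (six convolutional
*blocks/stages* versus sixteen convolutional layers); the layer-by-layer
sequence above is authoritative here, as it alone reproduces the canonical
sizes.

Weight initialisation is not specified in the source description; the
backbone uses seeded fan-in Gaussian (He) initialisation, the score layer
starts at zero, and the transposed convolution starts as an exact bilinear
interpolation kernel — the standard single-stream FCN recipe — so an
untrained model performs plain bilinear upsampling of its score map. No
pretrained weights are used (their use in the original work is unknown),
and no data augmentation is applied (none is described).

All layer arithmetic (convolution, ceiling-mode pooling, transposed
convolution, forward and backward) is implemented natively in
RcppArmadillo; convolutions are evaluated as one GEMM per kernel offset so
the heavy lifting runs on BLAS without an im2col memory blow-up.

## Training presets

The `"reference"` preset is the full-scale configuration: plain SGD, learning
rate $10^{-10}$, dropout 0.5, weight decay 0.0005, batch size 1, and
categorical cross-entropy *summed* over pixels. The summed reduction
matters: with $512^2$ pixels per tile, a summed-loss gradient is ~260,000
times a mean-loss gradient, which is what makes a $10^{-10}$ rate
meaningful. This preset needs GPU-scale iteration counts to converge.

The `"smoke"` preset exists to train desk-scale models on synthetic
fixtures in minutes on one CPU. It keeps the optimizer, architecture
family and batch size but mean-reduces the loss, uses learning rate 0.01
with a step schedule (0.3x after 12 epochs), disables dropout, and freezes
the transposed convolution at its bilinear initialisation (standard FCN
practice — the layer is an interpolator, not a feature extractor). These
choices deserve justification:

* **Learning rate 0.01, not a mean-reduced transcription of the
  reference rate.** With a randomly initialised (non-pretrained) backbone, the
  readout must extract a between-class feature difference that deep random
  ReLU networks contract severely (nearby input colors map to nearly
  parallel deep features). Empirically, mean-reduced rates at or below
  $10^{-3}$ leave the class-separating component of the score layer
  essentially unmoved within a desk-scale epoch budget, while 0.03 and
  above destabilises the jointly trained backbone; 0.01 converges
  reliably.
* **Step schedule, not geometric decay.** At a constant 0.01 the run
  converges and then destabilises after roughly 25 epochs as the growing
  score weights amplify update noise, while geometric per-epoch decay
  slows the critical middle phase of training; keeping the full rate
  through epoch 12 and then stepping to 0.3x preserves the converged
  state without sacrificing convergence speed.
* **Dropout off.** With a narrow (48-channel) head, 0.5 dropout noise is
  of the same order as the contracted between-class signal and dominates
  the desk-scale gradient budget. The reference configuration keeps
  dropout 0.5.

Weight decay applies to convolution weights, not biases. Tile order and
dropout masks are drawn from a single RNG stream seeded by the training
seed, so training is exactly reproducible. Momentum is not part of the
stated configuration and none is used.

## Synthetic fixtures: what they emulate and what they do not

The generator (`fixture_spec()` / `generate_slide()`) renders pyramidal
slides that exercise every pipeline stage: a near-white background (glass),
tile-aligned material cells densely covered by overlapping discs
(about 95% tissue per material tile at the defaults, so material tiles
robustly pass the 70% rule and empty tiles robustly fail it), three exact
area-averaged pyramid levels, and a pixel-exact 3-class reference mask.
Benign material is a mid-dark blue-violet; malignant material is much
darker magenta with a higher fraction of near-black "nuclei" pixels,
mimicking the hyperchromatic, high nucleus-to-cytoplasm appearance of
metastatic clusters. Malignant tiles contain tumor discs *amid* benign
bystander discs (as aspirates contain tumor clusters amid lymphocytes);
tumor discs are drawn on top and are 1.6x larger, forming compact blobs
that remain resolvable at the network's 32-pixel output stride (the
block-resolution ceiling of the default geometry is DSC ≈ 0.99).

Three design properties matter for interpreting test results:

* Both tissue colors are well below the background luminance and the
  background-tissue gap dominates the histogram, so Otsu lands between
  glass and tissue rather than between the two tissue classes.
* Classes are separable by low-level appearance (darkness and hue). A
  network that passes the recovery test has learned this separation — it
  has *not* demonstrated recognition of real cytomorphology (syncytial
  groups, nucleoli, nuclear pleomorphism), stain variation, folds, or
  pen marks. Fixtures validate the machinery, not clinical performance.
* Fixed seeds make slides byte-identical; all pixel values are quantised
  to the 8-bit grid so TIFF round trips are exact.

## Evaluation and statistics

The positive class for evaluation is the target (tumor) class only
(class-map label 2, matching the retention rule `m > 1`). From pixel
counts TP/FP/FN/TN: precision $TP/(TP+FP)$, sensitivity $TP/(TP+FN)$,
$DSC = 2TP/(2TP+FP+FN)$ and $IoU = TP/(TP+FP+FN)$; a zero denominator
yields `NA` (an undefined score is never silently reported as 0), and
undefined per-slide scores are excluded from group statistics with a
logged count. The unit of statistical analysis is the per-slide score;
pooled-pixel global scores are also reported. Data splits are always at
slide level (never tile level), seeded, with ids sorted before shuffling
so the assignment is invariant to input order; `k`-fold partitions differ
in size by at most one. Fisher's LSD runs a one-way ANOVA (via `aov`) and
compares each pair with
$t = (\bar x_i - \bar x_j) / \sqrt{MSE (1/n_i + 1/n_j)}$ on the residual
degrees of freedom, two-sided, with no multiplicity adjustment — that is
the LSD procedure; with two groups it reduces exactly to the pooled
two-sample t-test.

## Numerical choices and degenerate inputs

* Otsu ties break toward the lowest cut; the returned threshold is the
  midpoint between the two adjacent bin centers, and "tissue" is strictly
  below it. A constant image is degenerate: `otsu_threshold()` errors,
  `compute_tissue_mask()` converts that into an all-background mask with
  a warning.
* Argmax class maps break ties toward the lowest class index.
* The tissue-fraction comparison is inclusive (`>= 0.70`).
* Softmax is computed with per-pixel max subtraction; cross-entropy clips
  probabilities at $10^{-12}$.
* Max-pooling ties take the first element in scan order, making pooling
  (and hence the whole pipeline) deterministic.
* Training with learning rate 0 or zero epochs leaves parameters
  bit-identical; a non-finite loss aborts with the epoch number.

## Problem sizes used by the tests

The test-suite and acceptance runs use desk-scale instances chosen to keep
a full run in minutes on one CPU: fixture slides of 2048 x 1024 pixels
with three pyramid levels (a 4 x 2 grid of 512-tiles), a narrow-width
network instance (8/16/24/24/24 backbone, 48-channel head — identical
layer sequence and spatial geometry to the full-width architecture, which
is what the shape-conformance checks pin down), training on 20 tiles of
256 x 256 pixels for 28 epochs under the smoke preset (tiles stratified
into tumor-rich, benign-rich and sparse so no class dominates the
gradient stream), and whole-slide inference on held-out 512-tiles.
Convolution GEMMs run in single precision, which roughly halves
single-core training time with no measurable effect on segmentation
quality. The full-width specification is
constructed and shape-validated in the same suite; its closed-form trace
is the quantity the acceptance script reports.

## Known limitations

* The reference-preset configuration is not practical without GPU-scale
  budgets; no claim about clinical-data performance is made or tested
  here.
* Only RGB slides are supported; JPEG2000-compressed SVS dialects and
  vendor-specific formats beyond TIFF-compatible containers are out of
  scope, as are stain normalisation and ICC color management.
* The stitched result covers the tiled region only; the discarded border
  remainder is absent by design.
* Tile boundaries are hard: no overlapping-window averaging or boundary
  smoothing is applied (none is described in the source method).
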