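---
title: "Methods: berry instance segmentation and counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: berry instance segmentation and counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berryseg)
```

## The problem

Table-grape growers thin each cluster to a target berry number early in the
season, which requires counting the berries of a single bunch from an image.
Berries at thinning time are small (roughly 5–100 px wide at network input
scale), nearly the colour of the surrounding foliage, and densely packed so
that most berries partially occlude their neighbours. `berryseg` implements a
two-stage instance-segmentation pipeline specialized for this regime and a
linear calibration from detected to actual counts.

Every network layer in this package is implemented natively in R with dense
matrix algebra (im2col convolutions, windowed attention as per-window matrix
products). That makes the package self-contained and auditable down to the
arithmetic, at the price of CPU-scale rather than GPU-scale throughput; the
design consequences are described under "Desk-scale training" below.

## The model

**Backbone.** A Swin-Transformer-Tiny hierarchy: the image is split into
4×4 patches, linearly embedded to 96 channels, and processed by four stages
of transformer blocks with window size 7, depths (2, 2, 6, 2) and heads
(3, 6, 12, 24). Each block pair applies windowed multi-head self-attention
and its shifted-window variant,

$$\hat Z^{l} = \mathrm{W\text{-}MSA}(\mathrm{LN}(Z^{l-1})) + Z^{l-1},\qquad
  Z^{l} = \mathrm{MLP}(\mathrm{LN}(\hat Z^{l})) + \hat Z^{l},$$

with relative position bias inside each window and cyclic shift plus an
attention mask for the shifted blocks. Patch merging halves the resolution
and doubles the channel width between stages, yielding the pyramid C2–C5 at
strides 4/8/16/32 with widths 96/192/384/768. Stage depths must be even so
the two window variants alternate in pairs. Inputs are zero-padded
bottom-right to multiples of 32, preserving the top-left coordinate origin.

**Neck (ASFF).** Instead of FPN's top-down sums, every backbone level is
resampled to every target resolution (1×1 convolution for channel
adjustment; nearest-neighbour interpolation for up-sampling; stride-2 3×3
convolution for 1/2 down-sampling, preceded by one or two max-poolings for
1/4 and 1/8) and fused per location with softmax weights:

$$Y^{l}_{ij} = \alpha^{l}_{ij} X^{1\to l}_{ij} + \beta^{l}_{ij} X^{2\to l}_{ij}
             + \gamma^{l}_{ij} X^{3\to l}_{ij} + \delta^{l}_{ij} X^{4\to l}_{ij},$$

where the four weights are the softmax of per-location logits computed by
1×1 convolutions on the resized maps. Design points that the published
description leaves open, resolved here to the ASFF reference recipe:

* the logit path compresses each resized map to a 16-channel embedding
  (`compress = 16`), concatenates the four embeddings and derives the 4
  logit maps with one 1×1 convolution — with 16 (the reference default for
  non-RFB models) the assembled network's parameter count lands exactly on
  the published total;
* each resampling and expand convolution is followed by batch
  normalization and a leaky ReLU (slope 0.1). The leaky slope matters: with
  a hard ReLU, dead embedding channels leave a sizeable fraction of the
  fusion-logit parameters with exactly zero gradient on small random
  inputs, which would silence parts of the adaptive fusion;
* a 3×3 "expand" convolution follows each fused map;
* anchors use five strides but ASFF yields four maps, so a stride-64
  proposal level is appended by max-pooling the coarsest fused output
  (the standard extra-level construction);
* fusion parameters are independent per pyramid level, and interpolation is
  nearest-neighbour (exactly shape-preserving).

**Anchors.** One scale per level, multiplying the stride: the COCO default
scale 8 gives base anchor sides 32–512 px, far too coarse for berries. From
the emulated dataset statistics (widths/heights 5–100 px, areas
60–10,000 px², aspect ratios 0.5–2), the berry-optimized scale is 2, giving
sides 8, 16, 32, 64, 128 over strides 4–64 with area-preserving ratios
0.5/1/2. `dataset_box_stats()` recomputes these statistics from any COCO
dataset and suggests the scale from {1, 2, 4, 8} whose anchor-area span is
best centred (log scale) on the observed areas.

**Soft-NMS.** Hard NMS deletes any candidate overlapping a higher-scoring
one beyond a threshold, which in dense bunches deletes genuinely distinct,
occluded berries. Gaussian Soft-NMS instead decays scores,

$$S_i \leftarrow S_i\, e^{-\mathrm{IoU}(M, b_i)^2/\sigma},$$

keeping heavily overlapped but real neighbours alive. σ defaults to 0.5
(the Soft-NMS reference default; the source text does not state one) and
the decayed-score floor to 0.05. Whether the original work applies Soft-NMS
inside the RPN, at final detection, or both is ambiguous in the text; here
it is applied at both stages behind independent switches, both on by
default. Ties on equal scores keep the lower original index, making the
procedure fully deterministic.

**Heads.** Standard two-stage heads: ROI-aligned 7×7 features, two
1024-wide fully connected layers, a 2-way classifier (berry vs background)
and class-specific box regression; a mask head with four 3×3 convolutions,
a 2×2 up-convolution and a 1×1 logit layer predicting 28×28 masks from
14×14 ROI features, binarized at 0.5 after bilinear pasting into image
space. With these conventions the assembled network counts 50.71 M
trainable parameters, and swapping ASFF for FPN with default anchors
reproduces the 47.37 M of the corresponding Mask R-CNN — both matching the
published totals, which pins the head wiring.

## Synthetic scenes

No field dataset ships with the package (the original imagery is not
deposited), so `generate_bunch_scene()` renders what the statistics
describe: a cluster of shaded elliptical berries in painter's order over a
leaf-green textured background, with berry and background colours
deliberately close. Radii are drawn log-uniformly from [5, 24] px (so the
small-berry-heavy end of the band dominates), aspect ratios from
[0.8, 1.25], and centre spacing is controlled by `overlap_level` (0 forces
disjoint berries). Only visible pixels are annotated; a berry whose visible
fraction falls below `min_visible_fraction` (default 0.15) is dropped from
annotations and from the true count, as is any fragment below the observed
60 px² area floor or outside the emulated statistical bands — occlusion can
leave slivers (a thin equatorial band between two occluders) whose boxes no
field annotation would contain. The generator's purpose is distributional
emulation, not photorealism: passing tests demonstrate correct geometry,
occlusion bookkeeping and pipeline behaviour on in-band data, not field
accuracy under real illumination, blur, or foliage clutter.

An "easy" preset (`easy_scene_spec()`: a handful of large, well-separated,
high-contrast berries) defines the smoke-experiment conditions.

## Desk-scale training

`train()` keeps the full published schedule in its configuration (AdamW,
learning rate 1e-4 decayed ×0.1 after epochs 8 and 11 of 12, batch 2,
random horizontal/vertical flips, 1333×800 resize convention) but runs it
desk-scale:

* the backbone and neck stay frozen at initialization and their pyramids
  are cached per image and flip variant; the RPN and ROI heads are
  optimized with hand-written backpropagation (50 iterations by default,
  128×128 images — the smoke problem size used throughout the tests);
* RPN anchor assignment uses a positive-IoU threshold of 0.5 rather than
  the classic 0.7: measured against the stride-quantized anchor grid,
  most ~30 px near-circular berries have no anchor at 0.7 IoU but about
  two at 0.5, and head-only training needs more than the single argmax
  anchor per berry;
* ROI training samples the ground-truth boxes, jittered copies and random
  background windows rather than live RPN proposals, a stable and cheap
  approximation at this scale;
* losses are the standard five: RPN objectness (binary cross-entropy) and
  deltas (smooth L1, β = 1/9), ROI cross-entropy, ROI smooth L1 (β = 1),
  and per-pixel mask cross-entropy, all weighted 1 (no weights are
  published).

The end-to-end smoke experiment (two easy scenes, 150 iterations, the
fixed seeds in the test suite) reliably drives the loss down and recovers
every berry of the easy scene at IoU ≥ 0.5. Full-image, full-schedule
training is a GPU concern and out of scope; the evaluation pipeline is
additionally exercised with an injected perfect-oracle detector, which must
and does produce AP = 1, RMSE = 0, R² = 1.

## Evaluation

`coco_ap_suite()` follows the reference COCO protocol: greedy per-image
matching at IoU thresholds 0.50:0.05:0.95 (a tie at exactly the threshold
counts as a match), ignore handling for out-of-range ground truths and
detections, 101-point interpolated precision, maxDets = 100. APs
(area < 32²) and APm (32²–96²) stratify by ground-truth mask area; APl is
omitted because berries above 96² px are essentially absent. Bunches can
exceed 100 berries, so `max_dets` is configurable (the counting CLI uses
300); the oracle-equivalence tests pin the default at 100. The test suite
validates the implementation to 1e-4 against an independent, literal
transcription of the reference evaluator on seeded random fixtures.

## Count calibration

Detected counts systematically deviate from manual counts under occlusion,
so a linear model `actual = k · predicted + b` is fitted by closed-form
least squares (validated against `lm()` and a 101×101 grid-perturbation
oracle). Reported alongside are the RMSE of the raw predictions,
$\sqrt{\tfrac1n\sum_i(\hat y_i - y_i)^2}$, and the coefficient of
determination of the fitted line, $R^2 = 1 - \mathrm{SS}_{res} /
\mathrm{SS}_{tot}$. The source text prints a degenerate R² formula (no
squares, no residual structure); this package implements the standard
definition, which is what "coefficient of determination" denotes and what
regression scatter plots report. `calibrate_counts()` applies
`round(k · x + b)` to new predictions.

## Numerical choices and limitations

* Boxes are corner-format, 0-based continuous coordinates with
  exclusive-corner areas, matching COCO tooling; masks serialize as
  uncompressed column-major RLE.
* Window attention degrades gracefully: a window larger than the token grid
  shrinks to the grid (with shift disabled for single windows); odd grids
  zero-pad bottom-right.
* Resampling targets are taken from the destination level's actual shape,
  so odd sizes cannot produce off-by-one pyramids.
* Initialization: truncated-normal (sd 0.02) for linear/attention weights,
  He-normal for convolutions, unit batch-norm statistics; everything is
  seeded and bit-reproducible.
* The detector trained at desk scale overfits its training scenes by
  design (the smoke criterion); nothing here estimates field accuracy.
* Images enter at native resolution padded to multiples of 32; the
  1333×800 resize convention is available for larger inputs.
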