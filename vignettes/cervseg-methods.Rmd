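---
title: "cervseg: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cervseg: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cervseg` segments acetowhite lesions in colposcopic images. This vignette
is the package's account of the science inside it: the model and its
assumptions, the parameters that matter, what the synthetic data do and do
not establish, and the numerical choices made where the design was open.

## The segmentation network

The network is a U-shaped encoder–decoder with two parallel encoder
branches:

* a **residual-style branch** of identity-mapping blocks
  (`y = F(x) + x`), contributing deep semantic features — its four taps
  are projected by 1×1 convolutions to 64/128/256/512 channels at strides
  2/4/8/16;
* a **lightweight branch** of inverted residual blocks (pointwise
  expansion → depthwise 3×3 → linear pointwise projection), contributing
  cheap spatial detail — taps projected to 16/24/32/96 channels at the
  same strides. Taps are taken at the expanded (post-depthwise ReLU)
  representation, mirroring how expansion activations are tapped in
  depthwise-separable classification backbones.

Per level the two pyramids are fused by bilinear alignment and channel
concatenation. With 256×256 input the deepest fusion is a
512 + 96 = **608-channel bottleneck at 16×16**. The bottleneck passes
through a lightweight atrous spatial pyramid pooling (ASPP) block: three
depthwise-separable 3×3 branches at dilation rates 1, 6 and 12 plus a
global-average-pooling branch, each producing 256 channels, concatenated
to **1024 channels**. Four decoder stages then upsample ×2 with
transposed convolutions (kernel 2, stride 2), concatenate the matching
fused skip after squeeze-and-excitation (SE) gating, and apply two 3×3
convolution + batch-norm + ReLU pairs, narrowing to 512/256/128/64
channels; a 1×1 convolution and sigmoid produce the probability map.
The deepest decoder stage has no skip (there is no fused level at stride
1). The ablation variant drops the lightweight branch and fusion; skips
become SE-gated residual taps and the bottleneck entering ASPP has 512
channels.

Assumptions worth making explicit: the task is binary (lesion vs
background) — CIN grade enters only through the data pipeline, not the
output head; inputs are square with side divisible by 16; lesions are
assumed bright relative to their surround (the acetowhite cue), which the
phantom generator reproduces.

Three design points were genuinely open and decided as follows:

* **Fusion before attention.** SE gates are applied to the *fused* skip
  inside each decoder stage (fusion-then-SE), since the attention is meant
  to refine what the skip propagates into the decoder.
* **SE placement and ratio.** One SE block per skip connection, reduction
  ratio 16 at full width (a conventional value; smaller reduced-width
  configurations scale it down so the bottleneck never vanishes).
* **Backbone interiors.** The encoder branches are reduced-depth but
  faithful in style (one residual/inverted-residual block per stage).
  With no pretrained weights obtainable, taps are randomly initialized
  (He) and the 1×1 tap projections reconcile internal widths with the
  contract widths. A `freezeBackbones` switch exists for transfer
  settings.

## The hybrid loss

Training minimizes `L = L_Dice + L_Tversky`:

* `L_Dice = 1 − (2Σyŷ + ε)/(Σy + Σŷ + ε)` maintains region-overlap
  accuracy;
* `L_Tversky = 1 − (Σyŷ + ε)/(Σyŷ + αΣy(1−ŷ) + βΣ(1−y)ŷ + ε)` with
  defaults **α = 0.7, β = 0.3** penalizes false negatives more than false
  positives. With lesions occupying a few percent of the frame, a model
  can buy pixel accuracy by under-segmenting; the asymmetry pushes against
  exactly that failure mode. α and β are configurable; at α = β = 0.5 the
  Tversky term reduces to Dice (exactly so as ε → 0; the suite verifies
  the identity at ε = 1e−12).
* `ε = 1e−6` guards the ratios; it is shared between the two terms so the
  sum identity `combined = dice + tversky` holds exactly.
* Sums run over **all pixels of the batch** rather than per image. Per-
  image ratios are noisy when a lesion occupies a handful of pixels; the
  pooled ratio is the stabler objective. An optional binary cross-entropy
  term exists (`includeBCE`) but defaults off — the hybrid loss is the sum
  of the two overlap terms.

## Evaluation suite

All region metrics derive from the pooled 2×2 pixel confusion matrix
`p[i, j]` (true class i, predicted class j): pixel accuracy, mean pixel
accuracy, mean IoU, frequency-weighted IoU and the Dice coefficient
`2TP/(2TP + FP + FN)`. Pooling over a dataset (rather than averaging
per-image metrics) is the convention for such summary tables; both
granularities are available (`perImage`).

The Hausdorff distance is the max of the two directed sup–inf Euclidean
distances between boundary pixel sets, with boundaries defined as
foreground pixels having a background 4-neighbor or touching the image
edge. It is **undefined for empty masks**: rather than silently scoring
0, such pairs raise a typed condition, are excluded from averages, and
are counted in the report (`details$hd_excluded`). Cohen's κ
`(p_o − p_e)/(1 − p_e)` is computed pixel-wise; two constant, identical
maps score κ = 1 by convention, and a constant map against a varied one
takes the usual chance-corrected value (≤ 0). Hausdorff and κ do not pool
across images and are averaged per image.

## Grad-CAM++ explainability

For a dense sigmoid output there is no single "class score"; the target
scalar is the **sum of predicted probabilities over predicted-foreground
pixels** (probability > 0.5), the standard segmentation adaptation. With
first gradients g of that target w.r.t. a chosen feature map A, channel
weights follow the Grad-CAM++ positive-gradient form
`α = g²/(2g² + Σ_spatial(A)·g³)` and `w_k = Σ α_k · ReLU(g_k)`; the map
`ReLU(Σ_k w_k A_k)` is min–max normalized (idempotent; maximum exactly 1
whenever anything survives the ReLU) and bilinearly upsampled. The default
layer is the deepest residual-branch tap. Heatmap agreement with a
reference mask binarizes the normalized map at 0.5 (configurable) before
κ. If no pixel clears the target threshold the heatmap is all-zero with a
warning rather than an error.

## Synthetic phantoms: what they emulate and what they do not

Phantoms provide exact ground truth for every pipeline stage: a dark
background, a bright pinkish elliptical cervix field covering 40–70% of
the frame, lesion blobs strictly inside the ellipse that are brighter by
`lesionContrast` (default 0.25) — the acetowhite cue — Gaussian noise
(σ = 0.03), and small saturated specular discs that are **never** part of
the mask, so a model must learn to not segment mere brightness.

Blob outlines are radial-harmonic polygons
`r(θ) = R(1 + Σ_{h=2..5} a_h sin(hθ + φ_h))`, |a_h| ≤ 0.25, sampled at 72
vertices — smooth, irregular, and honest polygon annotations: the shipped
mask of every phantom is exactly the rasterization of its shipped
annotation file. Default total lesion area fractions are class-ordered —
CIN1 (0.02, 0.06), CIN2 (0.06, 0.12), CIN3 (0.12, 0.22) — creating a
learnable class-correlated signal and genuinely small CIN1 lesions that
exercise the Tversky rationale. These morphometric values are the
package's own choices: no published per-grade area statistics back them.
Area constraints are enforced on the rasterized mask with a damped
multiplicative correction loop and bounded retries.

What passing on phantoms does **not** show: robustness to real-image
nuisances — speculum occlusion, blood and mucus, green-filter/iodine
modalities, blur, inter-device color shifts — or clinical accuracy on any
real population. The phantom experiments validate the machinery (shapes,
gradients, losses, metrics, training dynamics), not the clinic.

## Training configuration

Full-scale defaults follow the conventional strategy for this
architecture family: Adam, initial learning rate 1e−4, batch 16, up to
300 epochs, early stopping (patience 25) and reduce-on-plateau (×0.5
after 10 stale epochs), with online augmentation on. The augmentation
policy (rotation ±30°, flips at p = 0.5, brightness/contrast ±0.2,
elastic α = 40 px at σ = 6 px) applies identical geometric transforms to
image and mask; masks are resampled nearest-neighbor and re-thresholded
so no interpolation gray values survive. Input standardization is
branch-specific, with fixed constants on the 0–255 scale: ImageNet
channel means/sds for the residual branch and the symmetric [−1, 1]
mapping for the lightweight branch.

### The desk-scale recipe

`deskRecipe()` defines the package's CPU-scale study conditions: 64×64
phantoms, 150 training / 30 validation / 30 test images (balanced across
grades), 30 epochs, batch 8, combined loss, randomly initialized
encoders, online augmentation off, Adam at 1e−3 (a small from-scratch
model trained for 570 steps wants a larger rate than the full-scale
1e−4). The network widths are scaled to taps 8/16/32/64 and 4/6/8/12,
ASPP branches of 16 and decoder 32/24/16/12 — the same topology at
roughly 210k parameters, chosen so a full train/evaluate cycle completes
in a few minutes on one CPU while reaching held-out Dice well above 0.8.
The reduced widths and the learning rate are the only departures from the
full-scale defaults, and both are exposed, not hard-coded.

## Numerical choices

* **Rasterization rule.** A pixel is foreground iff its center lies
  inside the polygon (even-odd rule) or exactly on an edge; vertices are
  rounded to integers first (no sub-pixel rule is defined by the
  annotation dialect); shapes merge by union (overlapping lesion
  annotations must not cancel); out-of-frame geometry is clipped;
  zero-area shapes contribute nothing and warn. The suite verifies the
  implementation against an independent per-pixel point-in-polygon
  oracle, exhaustively over the frame.
* **Engine.** Activations are (N·H·W)×C double matrices; convolutions are
  im2col + BLAS GEMM (fused in C++ with per-sample buffers), transposed
  convolutions are fixed at kernel 2/stride 2 (exact ×2, no checkerboard
  overlap), batch norm uses biased batch variance with running-stat
  momentum 0.1 and ε = 1e−5, and the dominant batch-norm + ReLU pattern
  is a fused kernel. Reverse-mode gradients are checked against finite
  differences (1e−4) in the suite. Convolution biases are omitted where
  batch norm follows (its shift makes them redundant).
* **Initialization.** He-normal weights, zero biases, unit batch-norm
  gain; all draws flow from a single seed, so two builds with the same
  seed are bit-identical.
* **Thresholds.** Probability 0.5 binarizes predictions at inference
  (no threshold is otherwise implied by a sigmoid output); 0.5 also
  binarizes normalized heatmaps for κ. Both are arguments, not
  constants.
* **Proportional allocation.** Dataset expansion and stratified splitting
  round with the largest-remainder method, which guarantees exact totals
  with every group within one unit of its quota; the split additionally
  rebalances across classes so the global train/validation/test sizes
  also follow largest remainder. Ties fall to the larger fractional
  remainder, then first group.
* **Degenerate inputs.** Empty manifests, zero-dimension images,
  empty-mask Hausdorff, constant-rater κ and all-zero Grad-CAM gradients
  all have defined, tested behavior (error, typed condition, or warning —
  never a silent 0).

## Known limitations

* No pretrained encoder weights: results on real images would require
  either substantial training data or externally supplied weights loaded
  into the engine's parameter store.
* The engine is CPU-only, double precision, single-device; it is sized
  for the package's experiments, not for 2000-image/300-epoch training,
  which the configuration describes but a GPU framework would run.
* PNG is the supported raster format (read and write).
* Binary masks only; multi-class segmentation and instance separation are
  out of scope.
* The Hausdorff distance is the classical supremum form; percentile
  variants sometimes preferred for robustness are not provided.
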