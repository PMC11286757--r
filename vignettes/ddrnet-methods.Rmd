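---
title: "Dilated residual attention networks for white blood cell classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dilated residual attention networks for white blood cell classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ddrnet)
```

## The problem

Differential white blood cell counting asks, for a microscope image of a
single stained leukocyte, which of four classes it belongs to: eosinophil,
lymphocyte, monocyte or neutrophil. The morphological cues are well known to
hematologists — neutrophils carry a multilobed nucleus, monocytes a
kidney-shaped one, lymphocytes a nucleus that fills most of the cell, and
eosinophils a distinctly granular cytoplasm — but they are subtle enough,
and staining variation large enough, that automated classification is a
real problem. This package implements a compact convolutional network
(DDRNet) designed around exactly those cues, together with everything
needed to exercise it end to end without external data: a morphology-aware
synthetic image generator, the augmentation and training recipe, one-vs-rest
evaluation metrics, an ablation harness over the architectural blocks, and
Grad-CAM attribution maps.

## The network

The classifier is assembled from four stages. All activation volumes are
`(height, width, channel)` arrays; group normalization (32 groups by
default) is used inside the feature blocks and batch normalization only
once, at the post-fusion stage.

**Convolution stem.** A 3x3 convolution to `stem_channels` filters
(default 32), 2x2/stride-2 max pooling, group normalization, ReLU. This
halves the spatial resolution once; all later blocks preserve it.

**Dilated residual block (DRDB).** The stem output is projected by a 1x1
convolution to the branch width (default 64) and fed to six parallel
residual branches. Each branch computes `x + T(x)` where `T` is
convolution - group norm - ReLU - convolution - group norm, with 3x3
kernels. Branches 1, 3 and 5 use ordinary convolutions; branches 2, 4 and 6
use dilated convolutions with the dilation sequence 1, 2, 4 (padding equal
to the dilation keeps every branch size-preserving). Two stacked 3x3
kernels at dilation d span `2(3 + 2(d-1)) - 1` pixels, so the six branches
see receptive fields from 5 to 17 pixels at identical parameter cost. The
six outputs are concatenated (6x the branch width) and reduced by a 1x1
convolution, group norm and ReLU.

**Global/local feature enhancement (GLFEB).** The residual output runs
through three convolution + group norm + ReLU layers with widths (64, 128,
64). In parallel, the stem feature — the "global" path — is bilinearly
resampled to the local path's spatial size (a no-op at the default
geometry) and projected by a 1x1 convolution to the same channel count c.
Both are concatenated to 2c channels and passed through tanh, so every
entry of this stage lies strictly in (-1, 1).

**Channel and spatial attention (CSAB).** Channel attention pools the
feature map globally by both average and max, passes each vector through a
shared two-layer bottleneck (reduction ratio 8), sums the two outputs and
applies a sigmoid — one gate in (0, 1) per channel. Spatial attention
collapses the channels with a single 5x5 convolution, applies ReLU, and
normalizes the map to sum to 1 over all its entries; an all-zero map
degenerates to the uniform map (with a warning from the user-facing
operation). The block output is the elementwise product
`at[h,w,c] * Qc[c] * Qs[h,w]`.

**Fusion and head.** The attention output is summed elementwise with a 1x1
projection of the GLFEB local-path output (the projection reconciles the c
vs 2c channel counts), then batch normalization, dropout (rate 0.2), global
average pooling and a dense softmax head over the four classes.

### Design choices the architecture leaves open

Several aspects are genuinely underdetermined by the block descriptions
above, and the package fixes them as follows.

* **Classifier head and loss.** The four classes are mutually exclusive, so
  the default head is softmax with categorical cross-entropy; sigmoid
  gating stays where it belongs inside the attention block. A
  `head = "sigmoid"` switch provides independent per-class scores with
  binary cross-entropy for users who want one-vs-all outputs.
* **Spatial-attention normalization axis.** The attention map has a single
  channel, so "normalize across channels" is ill-defined; the map is
  normalized over all its spatial entries so it integrates to 1. A
  consequence worth knowing: the attention output is thereby scaled by
  roughly `1/(H*W)` relative to its input, and the following fusion sum is
  numerically dominated by the projected convolution path. The post-fusion
  batch normalization absorbs the scale during training, but it means the
  fusion activation carries little of the attention signal (see the
  Grad-CAM default below).
* **Convolution padding.** All size-preserving convolutions pad by edge
  replication, not zeros. A stained smear has no natural black border;
  zero padding manufactures the strongest edge in the whole image along
  the canvas boundary, which contaminates both the features and any
  gradient-based attribution with corner artifacts.
* **Widths.** The branch width (64), reduction convolution (1x1,
  6·width → width), global-path projection and attention bottleneck widths
  are not dictated by the block structure; the defaults follow common
  practice for residual and channel-attention designs and are all
  configurable in `model_config()`.
* **Initialization.** He-uniform for convolutions and dense layers, unit
  gain / zero shift for normalization layers; fully seed-controlled.
* **Group-count fallback.** Where 32 does not divide a layer's channel
  count, that layer uses `gcd(32, C)` groups.
* **Depth.** One DRDB stage by default; `drdb_depth` stacks more.

## Training recipe

`train_config()` encodes the recipe: Adam, constant learning rate 0.01, 30
epochs, dropout 0.2. The batch size is not part of the recipe; the default
is 32 (a desk-scale choice; with batches this size the implied
batch size would be roughly 184). Per epoch the training split is
reshuffled; validation metrics use a `val` split when present and fall back
to an eval-mode pass over the training split otherwise. The weights with
the best validation accuracy are checkpointed, ties broken by lower
validation loss. Training aborts with a diagnostic naming the epoch and
iteration if the loss turns non-finite. In deterministic mode (default) a
single integer seed fixes initialization, shuffling and dropout, and
training is bit-reproducible.

## Augmentation and class balancing

Four transforms are implemented, each with exact index semantics on
`[0, 1]`-valued arrays: horizontal flip (`out[i, j] = in[i, W-1-j]`),
rotation (default magnitude 10 degrees, clockwise positive, bilinear
interpolation, zero fill, about the image center by default with the
literal origin-anchored mapping also exposed), zoom (default scale 2;
center-anchored bilinear magnification by default, with the literal
origin-anchored nearest-neighbor floor-index mapping also exposed), and
mean-anchored random contrast with factor drawn from (0.7, 1.3) — a range
the package chooses, as only the transform itself is prescribed. Cropping
is deliberately absent: it risks cutting away the diagnostic part of the
cell.

`balance_augment()` expands every class within one split to a target count
by applying a randomly chosen non-empty subset of the enabled transforms
(in the fixed order flip, rotate, zoom, contrast) to randomly chosen
originals. Originals are never discarded, a target below an original class
count is an error, synthesized images inherit label and split, and a
signature census avoids emitting duplicate images while novel ones remain
reachable. Balancing is applied after splitting, never before — augmenting
first would leak near-copies of training images into the test split.

## The synthetic generator

`generate_synthetic_cells()` draws one cell per 224x224 RGB image on a
stain-tinted background with Gaussian pixel noise (sd 0.02). Nuclei are
unions of Gaussian-blurred ellipses; class morphology follows the
hematological cues: 3-5 separate lobes (neutrophil), two lobes plus
Poisson-scattered reddish granules in the cytoplasm (eosinophil), a large
ellipse with a bite taken out (monocyte, kidney shape), and a single
nucleus covering about 80% of the cell area with a thin cytoplasm rim
(lymphocyte). Every image records the cell's ground-truth bounding box,
which the Grad-CAM localization checks use. Generation is sequential and
fully seeded: the same spec yields byte-identical sets.

What the generator emulates: class-defining nucleus morphology, granule
texture, stain-like coloring, background noise, and mild size/position/
orientation variation. What it does not emulate: neighboring red blood
cells and platelets, staining batch effects, focus blur, illumination
gradients, overlapping or clipped cells, and the long tail of atypical
morphologies in real smears. Tests passing on these images therefore
demonstrate that the architecture, gradients, training loop and metrics
work and that the model can learn genuinely class-separable morphology;
they say nothing about clinical performance on real data.

## Problem sizes for the bundled checks

The test suite and the acceptance script run everything at desk scale, a
deliberate package choice so the whole pipeline is verifiable on one CPU:
synthetic sets of 400 images (100 per class) split 80:20, images resized
to 32x32 for training, and a width-reduced configuration (stem 16, branch
width 16, enhancement widths 16/32/16). Under these conditions the network
reaches 100% training accuracy on a 40-image set within 50 epochs and full
test accuracy on the 400-image set after 15 epochs; the ablation harness
runs all seven block combinations at 2 epochs. The full-width default
configuration (676,245 parameters) is used for the parameter-economy
comparison against the standard 18-layer residual reference (about 11.2 M
at the same input/output sizes), instantiated here as a closed-form
per-layer parameter walk.

## Evaluation metrics

All metrics derive from the K-class confusion matrix (rows true, columns
predicted) by one-vs-rest marginalization into TP/TN/FP/FN. Accuracy,
precision, recall, F1 (the harmonic mean of precision and recall) and the
Matthews correlation coefficient use their standard definitions; printed
variants of these formulas sometimes disagree with the standard ones, and
this package deliberately implements the standard forms. Zero-denominator
cases return 0 and are flagged rather than raised. Macro averages are
unweighted means over classes, matching the per-class reporting layout.

## Grad-CAM

`grad_cam()` is the canonical formulation: the gradient of the target
class's logit with respect to a named stage's activation is averaged over
space to give per-channel weights; the heatmap is the ReLU of the
weight-summed activation, bilinearly upsampled to the input size and
max-normalized. The default attribution layer is the deepest residual
(DRDB) stage rather than the post-fusion stage: as noted above, the
sum-to-1 spatial attention normalization scales the attention output far
below the fused convolution path, so post-fusion activations carry almost
no localization signal, while the residual stage — the deepest purely
convolutional features before global mixing and tanh squashing — shows the
clearest class-discriminative localization. Any stage can be requested by
name. When the localization checks compare a heatmap peak against the
ground-truth bounding box they do so at the cam's native feature-grid
resolution (the box is mapped onto that grid with outward rounding), since
one upsampled cam cell spans several input pixels and a pixel-exact
comparison would measure quantization, not localization.

## Numerical notes and degenerate inputs

* Group/batch normalization use a variance floor of 1e-5.
* Oracle comparisons in the tests use 1e-5 absolute tolerance unless a
  tighter one is stated; metric cross-checks use 1e-8.
* Argmax prediction ties break toward the lowest class index,
  deterministically.
* An all-zero spatial-attention map yields the uniform map; its gradient is
  treated as zero (the uniform fallback is constant in the input).
* `max.col`-style tie handling, shuffling and dropout all draw from R's
  RNG, so a single `set.seed()` makes a whole run reproducible.
* Images with values outside `[0, 1]` are clipped at load time; grayscale
  sources are replicated to three channels; RGBA alpha is dropped.

## Known limitations

* No GPU path and no minibatch parallelism: the compiled kernels are
  single-threaded im2col + GEMM. Full-width training at 224x224 is out of
  desk-scale reach; the package is built to demonstrate and verify the
  method, not to reproduce benchmark-scale experiments.
* The synthetic generator's realism gap (above) bounds what the bundled
  checks can claim about real smears.
* Batch-norm running statistics need a few dozen update steps before
  eval-mode accuracy reflects train-mode accuracy; very short runs can
  look artificially weak in eval mode.
* The sigmoid head is provided for completeness but the evaluation
  pipeline assumes mutually exclusive classes.
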