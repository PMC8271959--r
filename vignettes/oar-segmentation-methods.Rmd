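---
title: "Methods: attention U-Net segmentation of thoracic organs at risk with STAPLE fold fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention U-Net segmentation of thoracic organs at risk with STAPLE fold fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiotherapy planning for thoracic tumours requires contouring the organs at
risk (OARs) on CT: esophagus, heart, trachea, aorta (four-organ
configuration, P = 5 classes with background) or left/right lung, spinal
cord, esophagus, heart, trachea (six-organ configuration, P = 7). The
esophagus is the hard case: it is thin (a few voxels across), its wall
contrast against mediastinal soft tissue is often under 30 HU, and its
boundary is ambiguous even for experts. `oarseg` implements a slice-wise
(2D) segmentation pipeline for this problem, so that no 3D convolutions or
GPU-scale memory are needed, together with the surface metrics and
label-fusion post-processing used to evaluate and stabilise it.

## Model

The network is a U-Net variant:

* **Encoder** — a ResNet34 or SEResNeXt50 backbone consumed stage by stage.
  The stage widths are (64, 64, 128, 256, 512) for ResNet34 and
  (64, 256, 512, 1024, 2048) for SEResNeXt50; the stem halves resolution,
  each later stage halves it again (stride product 32). One gray CT slice is
  replicated into 3 identical channels so the stem keeps the 3-channel
  ImageNet shape; the architecture accepts externally converted pretrained
  convolution weights, but everything here (tests, phantom runs) uses
  He-normal random initialisation.
* **Normalisation** — GroupNorm everywhere, including inside the backbone
  blocks (replacing BatchNorm; running statistics are meaningless at batch
  sizes of a few slices). The group count is the largest divisor of the
  channel width not exceeding 32, so every decoder width (16…256) is
  covered. BatchNorm remains available behind `norm_spec("batch")` for
  comparison runs. The practical consequence, asserted in the tests: in
  evaluation mode the output for a slice is identical whether it is
  processed alone or inside a batch.
* **ASPP bottleneck** — between the deepest encoder stage and the first
  decoder stage, an atrous spatial pyramid pooling block (1x1 branch, 3x3
  dilated branches at rates 6/12/18, global-pooling branch, concatenation,
  1x1 projection; Conv-GroupNorm-ReLU in every branch). Output width equals
  the deepest encoder width. The dilation rates are the standard choice for
  this block; at the 2x2 bottleneck of a 64x64 phantom slice the dilated
  kernels mostly see padding, which is harmless — the block matters at CT
  resolution (512x512 inputs, 16x16 bottleneck).
* **Decoder** — five stages with output widths (256, 128, 64, 32, 16) for
  either backbone. A stage bilinearly upsamples the previous output x2,
  concatenates the encoder skip (the last stage has none), and merges two
  branches by element-wise addition: branch one is two 3x3
  Conv-GroupNorm-ReLU blocks followed by a spatial attention module; branch
  two is a single 1x1 Conv-GroupNorm block acting as a learnable shortcut.
  A 1x1 convolution and per-pixel softmax produce the class probabilities.
  The head bias is initialised to a ~90% background prior (log class
  priors), the standard remedy for extreme foreground/background imbalance:
  starting from a near-uniform softmax, the network first grows a large
  false-positive region for each rare class and the soft-Dice gradient for
  shrinking it scales inversely with the region size, which can stall
  optimisation for many epochs; starting from a background-dominated
  prediction, the Dice gradient concentrates on the true foreground voxels
  from the first step.
* **Spatial attention module (SAM)** — two multiplicative gates. The channel
  gate is parameter-free: sigmoid(spatial mean + spatial max) per channel.
  The spatial gate concatenates the channel-wise mean and max maps and
  passes them through a 7x7 convolution (zero-initialised bias) and a
  sigmoid. Both gates lie in [0, 1], so the module can only attenuate,
  never amplify, and saturated gates make it the identity. How the mean and
  max enter the channel gate (sum, here) and the spatial kernel size (7,
  the convention in the attention literature) are choices the source
  architecture leaves open; both are arguments of `sam_block()`.

Because no deep-learning framework is available in the target environment,
the layers (grouped/dilated convolution via im2col + BLAS GEMM, GroupNorm,
max-pooling, bilinear upsampling, SE blocks, SAM, ASPP) and their exact
backward passes are implemented in this package on RcppArmadillo. Every
layer's gradient is verified against central finite differences in the test
suite, end to end through the assembled network.

## Objective

Training minimises

L = theta * Dice_loss + sigma * CE_loss,  theta = 0.9, sigma = 0.1,

where Dice_loss is 1 minus the mean per-class soft Dice (predicted
probabilities against one-hot targets, smoothing eps = 1e-6, sums taken
over the whole batch per class), and CE_loss is the per-pixel cross-entropy
weighted by a per-class factor phi — (0.2, 0.5, 0.5, 0.5, 0.5) for the
four-organ task and (0.1, 0.2, 0.2, 0.3, 0.4, 0.4, 0.4) for the six-organ
task — with the log argument floored at 1e-12. One printed form of the
multi-class Dice loss places the 1/P factor outside the bracket, which
would make its minimum negative; this implementation uses the standard
1 − mean(per-class Dice), which is zero exactly at a perfect confident
prediction and coincides with the printed form for P = 1. The gradient with
respect to the logits is computed analytically (softmax Jacobian folded in)
and is finite-difference-checked in the tests.

## Preprocessing

Volumes are windowed to [A, B] HU and rescaled to [0, 1]:
clip((I − A)/(B − A), 0, 1). Defaults: (−1000, 400) for the six-organ
configuration and (−400, 400) for the four-organ configuration. Values
outside the window are truncated to the endpoints rather than extrapolated.
All axial slices (last NIfTI axis by convention here) are extracted; empty
slices are kept by default (`keep_empty` flag). Augmentation during
training: horizontal flip with probability 0.5, rotation uniform in ±15°,
and a mild elastic warp (coarse 4x4 Gaussian displacement grid, sd 4 px,
bilinearly upsampled); images are warped bilinearly, labels with nearest
neighbour. The flip probability and rotation range follow the named
augmentations; the elastic parameters are this package's choice of "mild".

## Evaluation metrics

Per class: Dice overlap 2|T∩N|/(|T|+|N|) (two empty masks score 1, exactly
one empty scores 0 — patients with an empty prediction must still score);
Hausdorff distance in mm between mask surfaces, and HD95. Surfaces are
face-connected boundary voxels (6-connectivity in 3D; the grid border
counts as background), voxel centres scaled by the per-axis spacing, so
anisotropic voxels are handled without sub-voxel interpolation. HD95 takes
the 95th percentile of each directed distance sample (type-7 quantile)
before the outer max. The implementation (nearest-point kernel in C++) is
tested for exact agreement with a brute-force double-loop oracle on
hundreds of random mask pairs.

## STAPLE fold fusion

K-fold training yields K models; each predicts a label volume and the K
candidate volumes are fused. Each foreground class is binarised and fused
separately by STAPLE, an EM algorithm treating the K predictions as raters
with unknown sensitivity p and specificity q:

* E-step: W_i = a_i/(a_i+b_i) with a_i = pi_i * prod_j p_j^{D_ij}(1−p_j)^{1−D_ij},
  b_i = (1−pi_i) * prod_j q_j^{1−D_ij}(1−q_j)^{D_ij} (computed in log space);
* M-step: p_j = Σ W_i D_ij / Σ W_i, q_j = Σ(1−W_i)(1−D_ij)/Σ(1−W_i);
* iterate until |Δ Σ W| < 1e-6 or 100 iterations, from p = q = 0.99999.

The observed-data log-likelihood is tracked and asserted non-decreasing.
The foreground prior pi is a single global value equal to the mean rater
vote fraction (clamped to [0.01, 0.99]), the classic formulation. A
spatially varying per-voxel vote-fraction prior is available as an option
but is *not* the default: it feeds the rater votes into both the prior and
the likelihood, and in simulation this double counting inflated the
sensitivity error by an order of magnitude (≈0.17 vs ≈0.01) and prevented
convergence. An all-empty class skips EM and returns an empty mask.

The fused volume takes, per voxel, the class with the highest posterior if
that posterior reaches 0.5, else background; majority voting (strict
majority, ties to background — conservative for small organs) is provided
as the baseline the EM approach is compared against. On simulated raters of
heterogeneous quality the STAPLE fusion scores at least as well as the
vote, which is the seeded fixture form of the claim motivating the
post-processing step.

## Synthetic phantoms

`make_phantom()` renders, inside Gaussian noise (sd 10 HU, a realistic
standard-dose soft-tissue noise level) around a 30 HU soft-tissue
background: a thin tube of radius 2.5 at +30 HU contrast (the esophagus
analog — deliberately at the low-contrast regime that makes the real organ
hard), a large 120 HU ellipsoid (heart analog), an air tube at −950 HU
(trachea analog) and a bright 200 HU tube (aorta analog), P = 5. Default
grid 64x64x16 at 1x1x2.5 mm so CPU training finishes in minutes.
`random_phantom_spec()` jitters organ centres (±2 voxels) and sizes (±15%)
per patient. Everything is deterministic given the seed.

What the phantom does *not* emulate: anatomical texture, partial-volume
effects, scanner artifacts, inter-patient field-of-view variation, and
contact between organs. Passing the phantom tests therefore demonstrates
that the pipeline's mechanics (optimisation, fusion, metrics) work and that
the network can learn a low-contrast thin structure; it says nothing about
clinical accuracy, which requires the real challenge datasets.

## Training protocol and problem sizes

The published recipe — Adam, 30 epochs, K = 5 (six-organ) / K = 4
(four-organ) patient-level folds, the three augmentations — is exposed in
`train_config()`; learning rate and batch size are not stated in the
source and default to 3e-4 and 8. The end-to-end phantom run used by the
test suite and the acceptance script scales this down to the 8-patient
64x64x16 dataset with 4 folds and 5 epochs, batch 4 and lr 1e-3 — more,
smaller steps suit the ~500-update budget of the toy problem; the library
defaults are left at the full-scale values. Checkpoint selection: highest
mean foreground validation Dice, computed slice-wise (2D) per epoch for
speed; final evaluation is always volumetric. Fold splits are round-robin
over seed-shuffled patients, never by slice; the tests audit that no
patient leaks between a fold's training and validation sets.

## Numerical choices

* GroupNorm eps 1e-5; Adam (0.9, 0.999, 1e-8); He-normal fan-in init.
* Inputs not divisible by 32 are symmetrically zero-padded and cropped
  back after the softmax head (inference only).
* Bilinear upsampling uses half-pixel centres (align-corners false), which
  is parameter-free and deterministic.
* STAPLE p, q are clamped to [1e-7, 1−1e-7] to keep the log-space E-step
  finite; ties in `max.col` argmaxes are broken deterministically
  ("first").
* Dice smoothing eps 1e-6 defines the empty-class behaviour of the loss
  (empty prediction of an empty class costs nothing).

## Known limitations

* 2D slice-wise inference: no through-plane context; the restacked volume
  can be axially inconsistent (mitigated, not removed, by fold fusion).
* The hand-rolled layers are CPU double precision — fine at phantom scale,
  roughly an order of magnitude slower than a tuned framework at CT scale.
* STAPLE here is the voxel-independent binary formulation; no MRF spatial
  prior, no soft (probabilistic) rater inputs.
* ImageNet weight files are not bundled or downloaded; `pretrained` marks
  the intent in the spec of the backbone, and checkpoints restore exactly.
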