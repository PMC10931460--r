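---
title: "Methods: cross-channel attention severity regression on synthetic face videos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-channel attention severity regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ccanet)
```

## The model

`ccanet` estimates a BDI-II depression score (0–63) from face video. The
pipeline is: frame sampling → cascaded face detection and landmark-guided
cropping → residual backbone → pyramid splice → cross-channel attention →
global average pooling → one fully connected unit → frame score; frame
scores average to a video score, evaluated as RMSE and MAE over videos and
binned into None (0–13), Mild (14–19), Moderate (20–28), Severe (29–63).

The regression target is used on its raw 0–63 scale (the training loss is
plain squared error per frame, each frame inheriting its video's label)
and the training objective is minimised with Adam at learning rate 0.001
and decay rate 1e-4, batches of 128 frames, a 3:1 train:validation split
*at the video level*, and the parameter state with the smallest validation
loss over the epochs is the one kept. These optimisation defaults are the
reference settings for this architecture family; everything is exposed in
`train_config()`.

### The attention unit

For a feature map with C channels, the unit computes, per batch element:

* `z_c = (1/HW) Σ_ij X_c(i,j)` — global **average** pooling (average, not
  max, so that diffuse changes around the facial landmarks are retained);
* `S = σ(W₂ δ(W₁ z))` — a bottleneck gate with reduction `r` (default 16),
  ReLU `δ`, sigmoid `σ`;
* `ω = σ(C1D_k(S))` — a one-dimensional convolution of width `k = 5`
  *across the channel axis* with zero padding `(k−1)/2`, capturing local
  cross-channel interaction that the dense gate cannot localise;
* `x̃_c = x_c · ω_c` — channel-wise rescaling.

Two printed-formula ambiguities were resolved as implementation decisions:
the second gate matrix must be C × C/r for the dimensions to compose, and
the unit deliberately applies *both* sigmoids (inside the gate and after
the convolution) as specified — the attenuation tests rely on ω ∈ (0, 1).
The 1-D convolution carries a scalar bias (disable with
`attention_params(conv_bias = FALSE)`).

SE (gate only), ECA (convolution only) and CBAM (channel gate from average
plus max pooling, then a 7×7 spatial gate) are provided behind the same
interface; a negative test asserts that the convolution gate is *not*
channel-permutation equivariant, which is precisely what distinguishes the
cross-channel unit from SE.

The unit attaches once to the spliced pyramid output. The architecture
diagrams in this model family can also be read as placing attention inside
every residual block; the post-pyramid placement was chosen because the
ablation variants ("pyramid + SE", "pyramid + ECA", …) are defined as
post-pyramid attachments, which keeps all six variants structurally
comparable.

### The improved pyramid

The backbone is a standard bottleneck residual network (depths 50 and 101,
block plans 3-4-6-3 and 3-4-23-3; batch normalisation with ε = 1e-5,
momentum 0.1; convolutions before normalisation carry no bias). Features
{c2..c5} at strides {4, 8, 16, 32} are projected to 256 channels by 1×1
convolutions and fused top-down, with nearest-neighbour 2× upsampling
under the coordinate transform `src = dst · (srcSize/dstSize)`, floored
and clamped — the floor-and-clamp reading is what makes the real-valued
transform consistent with integer 2× replication. After per-level
smoothing (1×1 on p5, 3×3 elsewhere), p3..p5 are resized to p2's
resolution and all four levels are **concatenated** along the channel
axis (1024 channels at 32×32 for a 128×128 input). Concatenation was
chosen over summation for the splice because it preserves level-specific
information while still combining shallow and deep features; a summation
mode would be a trivial variant but is not what the ablation models use.
A p1 level (stride 2) is never built: fusion operates on c2..c5 only.

### The detection cascade

P-Net (fully convolutional, 12×12 receptive field, stride 2 via one
pooling), R-Net (24×24) and O-Net (48×48, which also outputs the five
landmarks) all use 3×3 convolutions at stride 1 and 2×2 max pooling at
stride 2, with three heads each (2-way classification, 4 box offsets, 10
landmark coordinates). Training patches come from the synthetic generator:
face patches (IoU ≥ 0.65 with truth, carrying offsets and landmarks),
part-faces (IoU ∈ [0.3, 0.65), offsets only), background (IoU < 0.3);
the per-sample indicators β switch exactly the annotated tasks on, and
task weights default to the canonical 1/0.5/0.5 (P, R) and 1/0.5/1 (O).
Box targets are `(truth − crop)/side`; at inference the predicted offsets
are applied to each stage's crop box.

Unstated detector hyperparameters are config-exposed with these defaults:
pyramid factor 0.709 starting at `12/min_face_px`, stage score thresholds
(0.6, 0.7, 0.7), stage NMS thresholds (0.7, 0.7, 0.7). Landmarks guide
cropping only — no rotation alignment is applied. Crops expand the box to
a square with a 15 % margin per side before nearest-neighbour resizing.
Between-stage NMS uses the standard intersection-over-union; the *output*
stage uses min-mode overlap (intersection over the smaller area), the
canonical choice there, because imperfect box regression otherwise leaves
nested duplicate windows that plain IoU at 0.7 does not suppress.

## The synthetic data generator

No public face-video corpus with BDI-II labels is redistributable, so the
generator is a first-class module, not a fixture. It emulates exactly the
study conditions the pipeline needs: single-face frames with known box and
five landmarks; one latent severity per video in [0, 63]; per-frame centre
jitter; uniform severity sampling by default.

Severity maps to geometry by fixed affine coefficients, so monotonicity is
exact and testable: mouth curvature `0.35 − 0.7·severity/63` (signed;
positive = smile) and eye openness `1 − 0.75·severity/63` (in (0, 1]).
These two cues were chosen because reduced smiling and narrowed eye
aperture are the facial correlates this model family is motivated by; the
affine form makes learnability a property a test can assert rather than
hope for. Faces are drawn as an ellipse with eyes, nose wedge and a
parabolic mouth arc on a low-frequency textured background, plus Gaussian
intensity noise (default σ = 0.02 in [0, 1] units); images persist as
8-bit PNG with CSV labels and ground-truth sidecars.

What the generator does *not* emulate — and therefore what passing tests
do **not** show about real data: identity variation, pose and illumination
change, occlusion, expression dynamics over time, camera noise statistics,
and any non-geometric severity signal. A model that learns these synthetic
cues has demonstrated that the architecture, losses, optimisation and
plumbing work end-to-end; it has demonstrated nothing about clinical
validity.

## Problem sizes and numerical choices

Desk-scale runs use width-reduced models; all reductions are configuration
values, never code paths of their own:

* learning sanity: 100 videos × 8 frames at 48×48, cropped to 32×32,
  backbone width multiplier 0.125 with one block per stage, 16 pyramid
  channels, 8 epochs, batch 64, 10 seeds — the trained attention model's
  validation RMSE (≈ 5–7) sits far below the validation-label standard
  deviation (≈ 18), i.e. it comfortably beats the mean predictor; the
  pyramid-only variant under the identical budget is reported alongside as
  a direction-only diagnostic.
* detector sanity: 2 200 training patches, width multiplier 0.5, 10
  epochs; evaluated on 100 held-out frames at IoU 0.5.
* the shape contract is checked at the full 256-channel pyramid width with
  a narrow backbone, since the contract constrains the pyramid, not the
  backbone width.

Numerical details: He-style initialisation seeded through a deterministic
stage-seed derivation (`derive_seed`), so one global seed reproduces every
stage independently; BCE probabilities are clamped at 1e-12; NMS breaks
score ties by lower original index; boxes are 0-based half-open; non-
integer BDI-II scores floor before binning; degenerate boxes, empty
videos, out-of-range severities and mismatched shapes are rejected with
explanatory errors. Training aborts with a diagnostic on non-finite loss.
Input frames are standardised per channel with constants computed on the
training split and stored in the checkpoint.

The classification loss is standard binary cross-entropy. One printed
variant of that formula in circulation, `−(y log p + (1−y)(1 − log p))`,
is not a valid loss (it is unbounded below and rewards confident errors on
negatives), so no exact-as-printed mode is provided.

## Known limitations

* The cascade is trained on synthetic patches only; it is a working
  detector for the synthetic distribution, not a general face detector.
* Frame-to-video aggregation is the arithmetic mean (median by config);
  subject-level grouping (one subject appearing in several videos) is
  exposed as an option but the synthetic generator produces one subject
  per video, so it is untested against real repeated-subject structure.
* The per-block attention placement mode mirrors the residual-stage
  reading of the architecture but is off by default and not part of the
  tested contract.
* Reproducing clinical-corpus error levels (RMSE ≈ 8.65 / MAE ≈ 6.66 on
  AVEC 2014) requires that restricted corpus and GPU-scale training of the
  full-width 50/101 backbones; nothing at desk scale speaks to those
  numbers.
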