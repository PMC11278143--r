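---
title: "Weakly supervised 2.5D self-training for carotid segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised 2.5D self-training for carotid segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Carotid arteries in non-contrast T1-weighted brain MR appear, in axial
slices, as paired dark near-circular sections a few millimetres wide,
wrapped in bright perivascular fat, beside mid-intensity muscle. Pixel
masks for them are costly to produce; axis-aligned bounding boxes per
slice are cheap. `carotidseg` turns such boxes into segmentation masks
by recursive self-training, and compensates for the loss of
through-plane information in slice-wise segmentation by a 2.5D input
encoding.

## 2.5D pseudo-RGB encoding

Each axial slice `k` of a preprocessed volume becomes a three-channel
image: channel R is slice `k-1`, G is slice `k` (the segmentation
target), B is slice `k+1`. At the first and last slice the missing
neighbour is replaced by the edge slice itself. We chose edge
replication over zero-filling because a zero channel would be an
intensity pattern the network never sees elsewhere in training, turning
volume boundaries into out-of-distribution inputs. Only slices whose
weak mask is non-empty enter the dataset: the weak annotation protocol
labels the carotid-bearing slices, so carotid-free slices carry no
(even weak) supervision signal. Whether adding them as pure-background
examples would help is untested here and left out by design.

## Preprocessing

Volumes are resampled to isotropic 1 mm voxels (trilinear for images,
nearest-neighbour for masks; output shape per axis is
`round(extent_mm / target_mm)`), reduced to 8 bits, and divided by 255.
The 16→8-bit reduction is a per-volume min–max linear rescale with
half-up rounding: it is parameter-free and uses the full dynamic range
of every volume. A fixed-range alternative (divide by 257) was
considered and rejected because acquisition scaling varies across
scanners, which would waste most of the 8-bit range on some volumes. A
constant volume maps to all zeros by convention. No bias-field or
spatial normalisation is applied — the pipeline is meant to tolerate
acquisition variation rather than remove it.

## The residual U-net

Five resolution levels. Every block applies two padded 3×3 stride-1
convolutions, each followed by batch normalisation and PReLU, with an
additive shortcut across the pair; the shortcut is the identity when
input and output channel counts match and a 1×1 projection otherwise.
Between encoder levels 2×2 average pooling halves the spatial
dimensions while channels double; the decoder mirrors this with
nearest-neighbour 2× upsampling and concatenation of the matching
encoder features. The head is a 1×1 convolution with a sigmoid, and
probabilities are thresholded at 0.5 (inclusive).

Design points that were genuinely open, and what we chose:

* **Residual wiring.** "Residual connections between the convolutions"
  admits several readings; we use the standard Res-Unet block (shortcut
  across the two-convolution pair, projected by 1×1 convolution on
  channel change), which keeps every block's output a sum of a learned
  refinement and its input.
* **Decoder upsampling.** Nearest-neighbour upsample + convolution
  rather than transposed convolution, avoiding checkerboard artifacts.
* **Dropout.** Placed after each block's final activation as *channel*
  (spatially shared) dropout. The reference rate is 0.6, appropriate
  for the 64–1000-channel full-scale network.
* **Ordering.** conv → batch norm → PReLU.
* **Width.** Only the bottleneck width (1000) is pinned at reference
  scale; earlier levels follow the doubling rule from `base_filters`
  (64 at reference scale, giving 64/128/256/512/1000).

The layers are implemented in the package itself — forward and backward
passes in R over `(H, W, C, N)` arrays with a compiled im2col + GEMM
convolution kernel — and verified end-to-end against finite
differences (relative error ~1e-6 in the test suite). This keeps the
package self-contained: no deep-learning framework exists in the
supported dependency set, and the training loop (Adam, batch-norm
statistics, best-epoch checkpointing) is small enough to own.

## Training

Soft Dice loss with smoothing constant 1 (per-slice, averaged over the
minibatch): zero for a perfect binary match and well defined for empty
slices. Adam with the continuous exponential schedule
`lr(step) = 1e-4 · 0.96^(step/253)`; we read the decay as non-staircase
since nothing indicates discrete drops, and the two interpretations
agree at every multiple of 253 steps anyway. Cross-validation folds are
assigned at *volume* level (volumes shuffled by seed, dealt
round-robin), so slices of one volume can never straddle a
training/validation split; the assignment is computed once and reused
identically in every self-training round. Early stopping monitors the
validation mean IoU at threshold 0.5 with patience 10 (reference scale)
and the best-epoch weights are kept. Batch size defaults to 8. What
covariate the original fold stratification balanced is not derivable
from its description; volume-level round-robin is the implemented
strategy and the natural place to hook alternatives.

## Recursive mask refinement

Each round: (1) train the 5-fold ensemble on the current masks (round 0:
the raw boxes); (2) re-segment every training slice with the mean of the
five probability maps, thresholded at 0.5; (3) during the first four
rounds, erode the prediction with the radius-1 digital disk (the
5-pixel cross; pixels beyond the border count as background) to speed
up removal of the false positives inherited from box supervision; (4)
split the image at the vertical midline into a left and right carotid
side and, per side, accept the prediction only if its IoU with that
side's boxes is at least 0.5, otherwise revert the side to the boxes;
(5) clip to the boxes. Erosion precedes the acceptance test because the
update is specified as an ordered four-step procedure; the containment
(clip) and revert rules together guarantee no round can produce a mask
outside, or worse than, the weak labels.

Decisions under this scheme: "above 50 %" is implemented inclusively
(`>= 0.5`) — the boundary has measure zero in practice and an inclusive
rule is exactly testable; a side empty in both prediction and boxes
scores IoU 1 and is accepted, so carotid-free half-images never revert
spuriously; the split column is configurable for anatomies that are not
left–right symmetric about the midline; an 8-connected structuring
element is available behind `erosion_conn = 8`.

## Metrics

IoU and DSC with the both-empty convention of 1 (a correct empty
prediction is not an error; `empty = NA` excludes such items instead).
Aggregation is per-slice mean ± population SD. The identity
`DSC = 2·IoU/(1+IoU)` ties the two metrics for any shared pair set and
is asserted over random masks in the tests; published tables that
violate this identity for a common evaluation set cannot be reproduced
from these definitions, so the standard definitions are implemented and
no attempt is made to imitate such numbers.

# The phantom generator

`generate_phantom()` emulates the appearance regime the pipeline
targets, not MR physics. Two tubes run along the slice axis with
sinusoidal in-plane centerline wobble; a voxel is ground-truth
foreground if its 3D distance to a centerline is at most the tube
radius, so oblique sections widen into ellipses exactly as a cut
cylinder does. Each tube carries a 1.5 px brighter ring (perivascular
fat) and sits in a mid-intensity background with i.i.d. Gaussian noise,
clipped to [0, 1].

Defaults, chosen once for realism at the 1 px = 1 mm convention:
radius 2.5 px (a 5 mm artery, mid-range of 4–6 mm), intensities
0.25 / 0.55 / 0.85 (lumen < muscle < fat), noise SD 0.05, wobble
amplitude 2.5 px with period 36 slices (most sections near-circular, a
minority markedly oblique — the per-slice weak-area distribution over a
500-slice sample is right-skewed, mirroring the small-area dominance of
real carotid data, and this is asserted as a test). Weak boxes are each
tube's tight per-slice box dilated by 2 px and shifted by ±1 px integer
jitter (annotator looseness), then minimally re-expanded so ground
truth is always contained — the weak-supervision containment invariant.
Per-volume lumen intensity is drawn uniformly (default 0.15–0.35) to
emulate between-subject contrast variation, the dominant driver of the
reported performance spread in real data. All randomness derives from
one master seed through a counter-based derivation, so every sample is
bit-reproducible.

What the phantom does *not* model: bifurcations, plaque, flow-related
signal variation, bias fields, anisotropic acquisition, or neighbouring
anatomy that could be confused with a vessel. Tests passing on phantoms
therefore demonstrate the *mechanics* of the pipeline (label refinement
improves on boxes when the object is a dark tube in a brighter
surround), not clinical segmentation accuracy.

# Scaled-down study conditions

The self-training study exercised by the test suite and by
`scripts/acceptance.R` uses problem sizes chosen so the whole pipeline
runs in minutes on one CPU core: 6 training phantoms plus 2 held-out
phantoms of 16 slices at 32×32; a network with `base_filters = 4` and a
64-filter bottleneck; 3 rounds (erosion in all of them, consistent with
"the first four rounds"); 3 replicate master seeds. Training
hyperparameters are adapted to this scale in the same spirit: learning
rate 1e-3 (the reference 1e-4 is calibrated to a ~250-step epoch;
test-scale folds see ~20 steps per epoch), at most 6 epochs with
patience 3, and channel dropout 0.2 (a 0.6 channel-dropout rate on
4-channel layers would leave blocks with one or two live channels most
steps). The reference-scale defaults of every configuration object are
unchanged and asserted verbatim by the golden-config test.

At this scale the margin-2, jitter-1 boxes around a radius-2.5 tube are
loose (box IoU vs ground truth ≈ 0.25), and a perfect tube prediction
would score below the 0.5 acceptance gate against its box; refinement
therefore proceeds the way the erosion step intends — each accepted
round shaves the box-shaped estimate toward the tube while the gate and
clipping prevent collapse — and the refined masks measurably beat the
boxes against hidden ground truth, with held-out IoU non-decreasing
across rounds. In the full-scale regime, where tight boxes around
near-circular sections give box IoU well above 0.5, the same gate
instead admits the network's tube-shaped predictions directly.

# Numerical conventions

* Half-up rounding for augmentation copy counts (so 1.3× of 10 is 13)
  and resampled grid shapes.
* Population (not sample) SD for the area-stratification threshold and
  for reported metric SDs; at realistic dataset sizes the difference is
  negligible, and the population form makes small worked examples
  exact.
* Ties at the stratification threshold go to the small stratum; the
  degenerate all-equal-areas dataset is therefore all-small.
* Binarization is inclusive at the threshold (`p >= 0.5`).
* Augmentation amplitude ranges (contrast and gamma factors
  U(0.8, 1.2), noise SD 0.01, shift ≤ 10 % of extent, zoom
  U(0.9, 1.1), 3×3 Gaussian blur with σ = 0.8) are package choices —
  only the application probabilities and the rotation bound are pinned
  by the reference configuration — and all are exposed in
  `augmentation_policy()` and the YAML config.
* Rotation/shift/zoom compose into a single inverse-mapped affine warp
  (bilinear for images, nearest-neighbour with zero padding for masks),
  so a geometric augmentation interpolates the image exactly once.

# Known limitations

* The hand-rolled training loop is single-threaded CPU code; the
  reference-scale network (240×240, 1000-filter bottleneck) is
  expressible but impractical to train here. One code path serves both
  scales, so correctness properties verified at test scale transfer
  structurally.
* `NA` validation IoU (no validation slices) disables early stopping
  for that fold.
* The phantom's left/right tubes never cross the midline, matching the
  fixed vertical split; real anatomy with strong lateral asymmetry
  would need `split_col` tuned or a localization step, which is out of
  scope.
* Round-level metrics on phantoms are reported against the training
  volumes' hidden ground truth and a small held-out set; no claim is
  made about transfer to clinical data.
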