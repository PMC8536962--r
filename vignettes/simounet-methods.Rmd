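---
title: "SIMOU-Net: model, training objective and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SIMOU-Net: model, training objective and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simounet)
```

## The problem

Foetal brain segmentation in in-utero MR images is hard for reasons that are
mostly geometric: the brain occupies a small, variably placed and variably
oriented part of the field of view; its boundary fades toward the top and
bottom slices of a stack; and in central slices the brain and skull
boundaries may touch or overlap. A single encoder–decoder network (the
classical U-Net) produces one prediction map from its last decoder layer and
therefore carries all of this uncertainty into a single estimate.

SIMOU-Net (single-input multi-output U-Net) addresses this by combining the
U-Net encoder–decoder with the deep-supervision idea of holistically nested
edge detection (HED): feature maps are *tapped* at every level of both the
contracting ("down", global context) and expansive ("up", local detail)
paths, upsampled to the input resolution, and concatenated into several
*prediction heads*. One forward pass yields five probability maps,

* `P_dux` — all side outputs except the last,
* `P_du`  — all side outputs,
* `P_u`   — expansive-path side outputs only,
* `P_d`   — contracting-path side outputs only,
* `P_f`   — the conventional final decoder output,

which act as a *within-network ensemble*: fusing them per pixel by mean
(`P_AVG`), median (`P_MED`) or maximum (`P_MAX`) reduces prediction variance
without training several networks.

## Architecture

The default specification (`simouSpec()`) has eight contracting levels with
feature channels 32, 32, 64, 64, 128, 128, 256, 512. Each level applies two
3×3 convolutions with ELU activations followed by batch normalisation; 2×2
max pooling (stride 2) connects consecutive levels. The expansive path
mirrors this with 2×2 stride-2 transposed convolutions (chosen over plain
interpolation so that upsampling is itself learned), skip concatenation from
the matching contracting level, two 3×3 ELU convolutions and batch
normalisation. Dropout (default rate 0.5) is applied on the last three
contracting and first three expansive levels, where features are densest.
One side output is tapped after each contracting block (before pooling,
`s1..s8`) and after each expansive block (`s9..s15`) — 15 taps in total.

Each tap is reduced to `sideHeadChannels` (default 1, i.e. one score map per
scale) by a 1×1 convolution and brought to full resolution by a stack of 2×2
stride-2 transposed convolutions, one per halving (stacked small strides
rather than one large-stride kernel, to limit checkerboard artefacts). A
head concatenates its taps channel-wise, applies two 3×3 ELU convolutions
with `postConcatChannels` filters and a final 1×1 convolution, and emits a
probability map through a sigmoid. A single-channel sigmoid output is used
in place of a two-class softmax — mathematically equivalent for a binary
problem — with thresholding (default 0.5, ties to foreground) deferred to
evaluation time.

Design choices worth making explicit:

* **Size-preserving convolutions.** Full-resolution concatenation of 15 side
  outputs and equally sized skip connections require "same" padding;
  unpadded convolutions would force ad-hoc cropping at every merge.
* **Resolution floor.** With eight levels, seven stride-2 halvings would
  demand inputs divisible by 128. The builder instead performs stride-2
  transitions until the resolution would fall below 1 px and stride-1
  (identity pooling / 1×1 up-projection) transitions beyond; for the 64×64
  inputs used throughout the package's experiments the two deepest levels
  sit at 1×1 px. Indivisible shapes are rejected with the required factor.
* **Width multiplier.** All channel counts, including the post-concatenation
  head filters (64 at full width — so each head maps a 64-component feature
  vector to the output), scale with a single `widthMultiplier`. This keeps
  scaled-down networks structurally faithful: a 1/8-width network is the
  same graph with 1/8 of every capacity.
* **Head composition.** `P_dux` is defined by the side-output listing
  `s1..s14` (the final tap `s15` excluded); the looser verbal description of
  it as "side outputs plus main output" is not followed, as the two
  contradict each other and the listing is the operational definition.
* **SIMO wrapping.** `simoUnetSpec()` applies the identical machinery to the
  classical 5-level U-Net (base channels 64…1024): 9 taps, the same five-head
  pattern. This isolates the contribution of the multi-output wrapper from
  the deeper backbone.

All network primitives — convolution, transposed convolution, max pooling,
batch normalisation, ELU, dropout, and their gradients — are implemented in
the package's compiled kernels (single-threaded, im2col + GEMM), and the
full backward pass is verified against central finite differences in the
test suite to ~1e-7 relative error.

## Weight initialisation

Every kernel is drawn from a zero-mean Gaussian with standard deviation
`sqrt(2/eta)`, where `eta = kh * kw * c_in` is the number of incoming nodes
of one neuron (He initialisation, appropriate for ELU/ReLU-type networks).
Biases start at zero, batch normalisation at identity. The square-root form
is used: the scale `2/eta` itself would shrink deep activations by orders of
magnitude, and the cited U-Net lineage uses the square root.

## Training objective

The per-image loss couples a foreground-weighted cross-entropy with a
smoothed soft-Dice, to counteract the severe foreground/background pixel
imbalance of foetal slices. For flattened truth `y` and predicted
probabilities `p`:

* `bce = mean_pixels(0.5 * y * log p)` (log clipped at 1e-7),
* `dice = (2 * sum(y p) + eps) / (sum y + sum p + eps)`, `eps = 1e-6`,
* loss `= -(1/B) * sum_batch(bce + dice)`; minimum −1 at `p = y`.

The printed form of this loss in its source description has prediction and
truth in swapped positions, which is degenerate for binary truth (the log of
a binary map); the implemented form is the standard one the loss originates
from. Clipping guards only the logarithm — the Dice term uses raw
predictions, so an all-background case scores `eps/eps = 1` (loss −1)
rather than being distorted by the clip floor.

The multi-output objective is `sum_t alpha_t * loss(head_t)` over the five
heads. The per-head weights are not prescribed anywhere; the default is
`alpha = (1,1,1,1,1)` since no head is privileged in the training protocol.

Optimisation uses RMSprop (learning rate 3e-4, gradient moving-average decay
0.8, epsilon 1e-7) with batch size 32 and up to 1000 epochs in the
full-scale protocol, stopping early when the validation loss has not
improved for 100 epochs and restoring the best-validation weights.
Validation Dice/Jaccard of the mean-fused maps are recorded per epoch
alongside both losses.

## Data augmentation

Each training image can receive one augmented companion per epoch: a random
rotation in ±180°, a random zoom in [0.1, 2.0] (taken literally, although
0.1 is extreme), and independent horizontal/vertical flips — applied
identically to image and mask. Images are resampled bilinearly, masks by
nearest neighbour and re-binarised at 0.5; out-of-bounds pixels are filled
with background 0 and the original shape is preserved. The inverse rotation
recovers a mask with Dice ≥ 0.95 (interpolation tolerance), which the test
suite checks.

## The phantom generator

No clinical data ship with the package; a synthetic foetal-head phantom
stands in for them, deliberately reproducing the failure modes that matter:

* an elliptical "brain" (randomised centre, orientation and semi-axes, by
  default 8–16 px at the mid slice of a 64×64 image) whose cross-sectional
  area follows `(4 t (1-t))^e` along the normalised stack position `t` —
  maximal mid-stack, vanishingly small at the ends (`e = 1` by default);
* a bright skull ring at `skullGapPX` (default 3 px; values ≤ 0 force
  brain/skull overlap, the over-segmentation hazard of central slices)
  inside a darker head ellipse that may clip at the field-of-view edge;
* brain/background contrast scaled toward the stack ends down to
  `contrastFalloff` (default 0.35) of its mid-slice value — the
  under-segmentation hazard of end slices;
* additive Gaussian noise (sd 0.05 in intensity units) and, with
  probability 0.15 per slice, a shifted faint replica of the head emulating
  a motion ghost.

Geometry defaults are 12–18 slices per subject, 1 mm in-plane spacing and
2.4 mm slice thickness (within the 2.0–2.6 mm range typical of foetal
acquisitions, which varies with gestational age). A synthetic
gestational-age proxy derived from the brain size is stored in the
metadata, and the manifest's stratum label is the balanced quartile of
mid-slice brain area — the stratification surrogate used for folding, since
the real protocol's stratification variable is not documented. The artefact
rates themselves are free parameters: no quantitative artefact statistics
exist to calibrate against, so they were chosen once to look plausible and
left alone.

Everything is a pure function of `(masterSeed, subjectIndex)`; tests rely on
bit-identical regeneration.

What the phantom does *not* emulate: MR physics (no k-space simulation, no
bias field beyond the contrast falloff), anatomical texture inside the
brain, or abnormal morphologies. Passing the package's tests therefore
demonstrates correctness of the machinery and learnability of a
geometrically faithful surrogate task — not clinical performance.

## Cross-validation protocol

Folding is subject-grouped (all slices of a foetus stay together — the
alternative leaks near-duplicate neighbouring slices between training and
test) and stratified: within each stratum subjects are shuffled by seed and
dealt to the fold with the fewest members, so per-stratum and global fold
sizes each differ by at most one. `runCrossValidation()` holds each fold out
in turn, reserves about one in five remaining subjects (at least one) for
early stopping, trains a freshly initialised model, and scores every head
and fused map on the held-out subjects.

## Evaluation suite

Metrics are computed slice-wise in 2D and averaged per case, matching a
2D segmentation method; 3D distances are out of scope:

* **Overlap:** `J = TP/(TP+FP+FN)`, `D = 2TP/(2TP+FP+FN)`,
  `Sen = TP/(TP+FN)`, per slice, averaged over slices whose ground truth
  contains foreground. Undefined ratios become `NA` with a notice, never a
  silent zero.
* **Hausdorff distance (mm):** the exact symmetric maximum (not a
  percentile variant) over foreground pixels, with coordinates scaled by
  the in-plane spacing; slices with an empty mask on either side are
  excluded from its average.
* **Volume (cm³):** summed foreground count × `dx·dy·dz` / 1000 over the
  *full* stack (empty-truth slices count toward volume even though they are
  excluded from overlap averaging); `MAVD = |V_auto − V_manual|`.
* **Agreement:** squared Pearson correlation between automated and manual
  volumes and Bland–Altman limits `mean ± 1.96 × sample sd` of the
  differences.

Every metric is property-tested against an independent brute-force oracle
(per-pixel loops, all-pairs distances, voxel counting, per-pixel sorting for
the fusion operators) on hundreds of random small masks.

## Problem sizes of the shipped experiments

The package's own experiments (test suite and `scripts/acceptance.R`) run a
1/8-width SIMOU-Net on 12 phantom subjects of ~15 slices at 64×64 px — a
size chosen so the complete stratified 3-fold protocol trains in minutes on
one CPU core while leaving the architecture untouched. For these scaled
runs the training configuration is adapted to the reduced problem: learning
rate 3e-3 and batch size 8 (a ~150-slice dataset needs larger, more
frequent RMSprop steps than the full-scale corpus to traverse comparable
parameter distance within 15 epochs), at most 15 epochs with early stopping
effectively disabled, and augmentation off (the phantom population already
randomises orientation, position and size; the full augmentation policy
remains available and tested). Dropout keeps its default 0.5.

Under these conditions the mean-fused head segments held-out phantoms with
case-mean Dice well above 0.9, the mean fusion outperforms the
contracting-path-only head `P_d` (whose global-features-only design is
expected to trail), and the maximum fusion trails both mean and median —
the same qualitative ordering reported for the clinical-scale experiments.
Full-scale clinical numbers are *not* reproducible from this package: no
clinical data are included, and the shipped experiments make no claim
beyond the synthetic task.

## Numerical choices and degenerate inputs

* Binarisation threshold 0.5 with `>=` tie-breaking (ties to foreground).
* Dice smoothing `eps = 1e-6`; log clip `1e-7`; batch-norm epsilon `1e-5`,
  running-statistics momentum 0.9 (inference uses running statistics).
* Mask re-binarisation after interpolation at 0.5.
* RMSprop epsilon `1e-7`.
* Cases whose ground truth has no foreground slice are excluded from
  evaluation with a logged message; empty masks make Hausdorff `NA`, and
  zero-variance volume lists make r² `NA`.
* Per-slice PNGs are written 8-bit with the exact intensity window recorded
  in the JSON sidecar (reads restore original units up to quantisation);
  NIfTI (float64 image, uint8 mask) is the lossless canonical format.

## Known limitations

* The phantom's simplicity means segmentation scores on it saturate near 1;
  it separates *broken* from *working* pipelines but not *good* from
  *state-of-the-art* models.
* Only the `elu` activation and constant learning rate are implemented; no
  multi-device training.
* Attention gates, nested skip paths and multi-stage refinement baselines
  are out of scope; the only wrapped backbone is the plain U-Net.
* Compute kernels favour clarity and determinism over peak throughput; the
  package targets method study and small experiments, not GPU-scale
  training.
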