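---
title: "Methods and design choices in periseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in periseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periseg)
```

`periseg` implements a complete desk-scale pipeline for multi-class
segmentation of periodontal ultrasound sweeps: synthetic data generation,
semi-automatic annotation, preparation of the 384×384×5 training
representation, freehand-3D compounding with an annotation quality check, a
native U-Net, and evaluation metrics. This vignette explains the models and
conventions behind each step, the parameters that matter, and the limits of
what the synthetic experiments can show.

## The segmentation problem

A tracked ("freehand") probe sweeps across the dental arch producing tall
grayscale frames (natively 375 px wide × 735 px high) with all anatomy in the
upper half. Five structures are annotated per frame — cortical bone, tooth
crown, gingiva, periodontal pocket, tooth root (class codes 1–5 in that fixed
order; 0 is background). The class structure is extremely unbalanced: gingiva
and bone appear in every frame, crown/root only in frames over a tooth
(roughly half the sweep — the rest crosses inter-dental spaces), and the
pocket, a sliver a few pixels wide, in only about 10% of frames. Ground truth
comes from a human operator, so part of the pipeline exists to find and fix
annotation mistakes.

## The sweep phantom

`phantom_config()` / `generate_sweep()` produce frames, per-pixel label
matrices and rigid probe poses with that statistical structure. Design
choices, and what they do and do not emulate:

* **Geometry.** Per dental segment the phantom draws a bright convex crown
  ellipse near the top, a tapered root beneath it, a gingival band across the
  frame, a thin bright cortical-bone band under the gingiva, and a ≤5 px
  pocket sliver hugging the root's left edge inside the gingival band.
  Painting order implements the priority crown > root > pocket > bone >
  gingiva, so labels are disjoint by construction. All structures stay in the
  upper half of the frame; sizes are proportional to the configured frame
  size.
* **Run structure.** Anatomy is piecewise-constant over contiguous *segments*
  (dental segments of 6–12 frames alternating with inter-dental gaps whose
  mean length realises `interdental_fraction`, default 0.45), the way a slow
  physical sweep traverses teeth and gaps. Pockets occupy 2-frame sub-runs of
  dental segments; the per-segment inclusion probability is calibrated so the
  *marginal* per-frame pocket probability equals `pocket_prevalence`
  (default 0.10). Short sub-runs keep the count variance near binomial, which
  is what the prevalence checks assume. A per-frame independent presence
  model was rejected: isolated one-frame structures are anatomically wrong
  and make any neighbourhood-based quality check unusable.
* **Intensity.** A pixel of class `k` has clean intensity
  `class_intensity_means[k]`, multiplied by `(1 + a·η)` with `η ~ N(0,1)` and
  `a = noise_amplitude` (default 0.35) — the standard multiplicative speckle
  surrogate — then Gaussian-blurred (`blur_sigma`, default 1.5 px) and
  clipped to [0, 255]. With `noise_amplitude = 0, blur_sigma = 0` the frame
  *equals* its label matrix mapped through the intensity means, which several
  tests exploit. A warning is raised when class means sit closer than twice
  the speckle standard deviation of the dimmer class — intentional at the
  default (high-noise) setting for the bright bone/crown pair.
* **Poses.** Frame `f` is translated `(f−1)·pose_step` mm along the sweep
  axis with smooth sinusoidal perturbations (in-plane amplitude 0.15 px
  equivalents, 5% of the step along the axis) and sub-degree sinusoidal
  rotations composed from exact axis rotations, so every matrix is orthonormal
  to machine precision.
* **Not emulated:** wave physics, shadowing, attenuation, anisotropic speckle
  texture, patient-specific anatomy, probe pressure deformation. Passing
  tests on the phantom demonstrates the *machinery* (geometry handling, data
  flow, learnability, QC logic), not clinical performance.

`corrupt_labels()` emulates a low-experience annotator for label-noise
experiments: on a chosen fraction of frames one present class mask is
dilated, eroded (disc structuring element) or shifted by `severity` pixels.
An operation that would empty the mask (eroding a structure thinner than the
severity) or leave it unchanged falls back to shift, then dilation: the
corruption models *mis-traced* annotations, which is the error class a
3-D consistency check can catch — a deleted annotation is indistinguishable,
from masks alone, from the structure being genuinely absent.

## Seeded region growing

`grow_region()` admits exactly the pixels 4-connectedly reachable from the
seed through unlabeled pixels whose intensity differs from the *seed's* by at
most `T`, using breadth-first traversal with a FIFO queue. Two choices were
genuinely open:

* **Similarity anchor.** Candidates are compared to the seed intensity, not
  to a running region mean or the last-added pixel. Seed-anchoring makes the
  predicate order-independent, so re-growing the same seed under a new
  threshold (the track-bar interaction) is deterministic and monotone:
  `T1 ≤ T2` implies the `T1` region is a subset of the `T2` region. Both
  properties are asserted against an exhaustive fixpoint flood-fill oracle.
* **Connectivity.** 4-neighbourhood, the conservative choice: diagonal
  adjacency leaks across single-pixel boundaries, and the pocket is only a
  few pixels wide.

The interactive tool is modelled as a state machine (`growth_session()`,
`session_step()`): `seed` starts a pending growth, `threshold` re-grows it
(and merely stores the value when nothing is pending), `commit` writes the
pending region under the active class, `cancel` discards it, `erase`/`draw`
edit with a Euclidean disc brush clipped at borders. Growth excludes
already-labeled pixels, so committed classes are disjoint at all times;
editing is refused while a growth is pending to preserve that invariant.
Batch replay of plain-text scripts (`run_session_script()`) replaces the
GUI: the same script on the same image always yields the same label matrix.

## Dataset preparation

* **Crop/pad.** Native frames are 375 wide × 735 high with the anatomy in the
  upper half, so `crop_pad()` keeps rows 1–384 (top-anchored vertical crop)
  and zero-pads columns on the right to 384. Zeros are neutral for both masks
  and network input.
* **Mask stack.** `build_mask_stack()` produces the 384×384×5 binary tensor
  with immutable channel order bone, crown, gingiva, pocket, root; absent
  classes stay all-zero. The on-disk container is a raw uint8 `.bin` plus a
  JSON sidecar naming dimensions and class order — self-describing, and the
  round trip is bit-exact.
* **Splits.** `split_dataset()` shuffles deterministically under a seed and
  takes `floor(0.8·N)` train, `floor(0.1·N)` validation, remainder test.
  This floor/floor/remainder rule is the only one consistent with both
  reference count sets (2135 → 1708/213/214 and 3417 → 2733/341/343), and
  both are asserted in the suite.
* **DICOM.** Frame extraction reads uncompressed little-endian grayscale
  DICOM (explicit or implicit VR, single- or multi-frame) with a minimal
  parser written for the package — no R DICOM reader is available in the
  supported dependency set — and is cross-checked in the tests against files
  written by pydicom. 8-bit input is written to PNG pixel-identically;
  deeper input is rescaled affinely from the file's stored range to 0–255.

## 3-D compounding and the annotation quality check

Pixel (row r, col c) of frame f maps to the world point
`R_f · ((c−1)s, (r−1)s, 0)ᵀ + t_f` (s = pixel spacing; image x along
columns, y along rows, z normal to the frame, right-handed) and is deposited
into the nearest voxel of an axis-aligned grid fitted to the sweep. Voxel
intensity is the mean of deposits; the label is the majority vote with ties
broken toward the lowest class code; provenance (for `frame_at()`) is the
frame with the most deposits, ties toward the lowest index. With identity
rotations, steps equal to the voxel spacing and matched pixel spacing, the
volume reproduces the input stack bit-exactly — the suite's stacking
equivalence check — and cross-sections round-trip to the source frames.

`flag_inconsistent_frames()` makes the visual "does the mask fit the 3-D
object?" check quantitative. For frame f and class k the score is the
**maximum** Dice overlap between f's class-k mask and the pose-projected
(nearest-neighbour resampled) class-k mask of each frame within ±3 frames;
a class absent from both frames scores 1 for that neighbour. A frame is
flagged when any class scores below the threshold (default 0.9, a toolkit
choice — the reference workflow gives no numeric criterion).

Taking the maximum over the neighbourhood rather than Dice against the
*union* of neighbours is deliberate: a dilated mask inflates the union of its
neighbours' projections, so union-Dice flags the clean frames *next to* an
error, and class-presence transitions (dental ↔ inter-dental) would flag
legitimate anatomy changes. With the maximum, a frame is penalised only if it
agrees with none of its neighbours; since the phantom guarantees at least one
same-anatomy neighbour within the window, clean frames score 1 on noise-free
sweeps.

**Known limitation.** For a structure spanning only ~2 frames (short pocket
runs), a corrupted frame is its clean partner's only same-structure
neighbour, so both fall below threshold: every corrupted frame is flagged,
but the partner can be flagged too. This is inherent to mask-only
consistency checking, and matches the human workflow where the operator
inspects the flagged region and decides which frame to correct
(`apply_correction()` replaces one frame's labels, appends an audit entry and
recompounds the volume).

## The U-Net

The architecture was fixed by reverse-engineering the two published
parameter counts. At depth 5 with a single grayscale input channel, per-level
widths `w·2^(l−1)`, two 3×3 same-padded biased convolutions + ReLU per level,
2×2 max-pooling, 2×2 stride-2 transposed convolutions, skip concatenation and
a 1×1 five-channel head, middle widths 256 and 512 give exactly 1,940,885 and
7,759,653 trainable parameters — the unique standard-U-Net variant matching
both (no batch normalisation; biases on every convolution). The
layer-by-layer sum is kept in the test suite as a documented oracle
(`unet_param_count()` vs a hand-computed count for a tiny configuration, and
both published sizes exactly). Those counts also force the single-channel
input; RGB input is accepted and converted by channel averaging.

Choices the reference description leaves open, made here as package defaults:

* **Loss**: mean per-pixel binary cross-entropy over the five sigmoid
  channels (channels are independent binary problems; the non-overlap
  guarantee is enforced at prediction time by per-pixel arg-max with a 0.5
  floor).
* **Optimiser**: Adam (β₁ = 0.9, β₂ = 0.999) with configurable learning
  rate; gradients are computed by hand-written backpropagation through the
  Rcpp convolution/pool/upconv kernels and verified against central finite
  differences in the suite.
* **Initialisation**: He-scaled Gaussian weights; hidden biases start at
  +0.05 rather than 0. With masks that are ~90% background, the early
  optimisation pressure drives activations negative and zero-initialised
  ReLU blocks can die wholesale (the final decoder block first, which blocks
  all learning); a small positive bias keeps units initially active. The
  output-head bias starts at 0.
* **Dropout** (`dropout_mode`): after every double-convolution block
  (`"all"`), only after contracting-path blocks (`"contracting_only"`), or
  nowhere (`"none"`, default) — the three published placements. Dropout has
  no parameters, so all modes share the same count (asserted).
* **Determinism**: initialisation, shuffling and dropout draw from a stream
  seeded by `rng_seed`, so training is reproducible up to floating-point
  non-associativity (on one thread, exactly).

Inputs of any size divisible by `2^(depth−1)` are accepted; 384×384 is the
reference size. Checkpoints are saved with `save_unet()` (serialised model
plus a YAML config sidecar) and reload to identical predictions.

## Evaluation metrics

"Presence" of a class in an image means ≥1 positive pixel (no minimum-area
threshold). Per class over an image set: accuracy `(TP+TN)/N`, specificity
`TN/(TN+FP)` — undefined exactly when `TN+FP = 0`, i.e. for classes present
in every image, rendered `"-"` in reports — sensitivity `TP/(TP+FN)`,
precision `TP/(TP+FP)`. Pixel IoU is `|∩|/|∪|`, defined as 1.0 for two empty
masks so the function is total; IoU statistics are aggregated over
true-positive images only, which excludes that case anyway. The weighted
average IoU weights each class's mean IoU by its TP count — the natural
weighting against the dataset's class imbalance. `correlate_iou()` reports
Pearson correlations of per-class mean IoU against mean mask size and
presence count, with an undefined marker below 3 complete pairs or at zero
variance.

## The label-quality experiment

The suite reproduces, at desk scale, the qualitative finding that cleaning
the training annotations matters more than dataset size: two identical
U-Nets (middle width 16, depth 3, Adam at 5·10⁻³, 50 epochs, identical
seeds) are trained on a 16-frame phantom sweep (96×192 frames at noise
amplitude 0.1, cropped to 96×96; 14 training / 2 held-out frames) — once on
clean labels and once with 30% of training frames corrupted at severity
10 px — and the clean model must achieve strictly higher test IoU, with a
floor asserting that it genuinely learned. These problem sizes are the
package's chosen desk-scale configuration; the full 384×384 / depth-5
setting is exercised structurally (parameter counts, shapes, prediction
contract) but not trained in the suite.

## Degenerate inputs and tie-breaks, collected

* Region growing: out-of-bounds or excluded seed → error; constant image at
  `T = 0` floods everything reachable.
* Compounding: label majority ties → lowest class code; provenance ties →
  lowest frame index; untouched voxels are `NA` intensity / label 0 /
  `NA` provenance (`frame_at()` returns `NA`).
* Cross-sections: nearest-plane lookup; the exact boundary position is valid,
  anything outside errors.
* QC: a single-frame sweep yields an empty report; both-empty class pairs
  score 1.
* Splits: `floor`/`floor`/remainder guarantees a partition for any N ≥ 1.
* Prediction: a pixel whose maximal sigmoid is below 0.5 is background in
  all channels.
* `pixel_iou(∅, ∅) = 1`; undefined rates are `NA` internally and `"-"` in
  rendered reports.
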