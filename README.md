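# periseg

Segmenting periodontal (gum/tooth) ultrasound images is hard for exactly the
reasons it matters clinically: the frames are low-contrast and speckled, the
five anatomical targets — cortical **bone**, tooth **crown**, **gingiva**,
periodontal **pocket**, tooth **root** — differ enormously in size and
frequency (gingiva is present in every frame and can be tens of times larger
than a pocket, which appears in only ~10% of frames), and the ground truth
itself is drawn by human operators whose mistakes propagate into any model
trained on it.

`periseg` is an R toolkit for this workflow, aimed at people building or
auditing segmentation datasets for tracked 2-D ultrasound sweeps:

* **Semi-automatic annotation** — seeded region growing (breadth-first
  traversal with a FIFO queue over the 4-neighbourhood, admitting pixels `p`
  with `|I(p) − I(seed)| ≤ T`), wrapped in the interactive
  seed / adjust-threshold / commit / cancel / erase / draw state machine,
  replayable headlessly from plain-text session scripts.
* **Dataset preparation** — pairing/repair checks for frame+mask PNG
  directories, DICOM frame extraction, top-anchored crop and right
  zero-padding of the native 375×735 frames to 384×384, assembly into the
  384×384×5 binary mask stack with fixed channel order
  (bone, crown, gingiva, pocket, root), and reproducible
  80/10/10 train/validation/test splits (floor/floor/remainder — for 2135
  files this gives exactly 1708/213/214, for 3417 files 2733/341/343).
* **Freehand-3D reconstruction and label QC** — nearest-voxel compounding of
  posed frames into intensity+label volumes (mean fusion for intensity,
  majority vote for labels), cross-sections, voxel→source-frame navigation,
  and a quantitative quality check that flags frames whose masks do not fit
  the 3-D object: per class, the maximum Dice overlap against the
  pose-projected masks of nearby frames.
* **U-Net** — a configurable encoder–decoder (two 3×3 biased convolutions +
  ReLU per level, 2×2 max-pool, 2×2 transposed-convolution upsampling, skip
  concatenation, 1×1 five-channel sigmoid head) implemented natively in
  R/Rcpp with Adam and per-pixel binary cross-entropy; the two reference
  sizes (middle width 256 and 512 at depth 5) have exactly **1,940,885** and
  **7,759,653** trainable parameters. Prediction binarises with per-pixel
  arg-max so output masks never overlap.
* **Evaluation** — image-level presence confusion (TP/TN/FP/FN), accuracy /
  specificity / sensitivity / precision with the `"-"` convention for
  undefined specificity (classes present in every image), IoU restricted to
  true-positive images, TP-weighted average IoU, and size/prevalence–IoU
  correlations.
* **A synthetic sweep phantom** — frames + ground-truth masks + probe poses
  with the real data's statistical structure (anatomy in the upper half,
  ever-present gingiva/bone, ~45% inter-dental frames without crown/root,
  pockets on ~10% of frames, multiplicative speckle, smooth pose drift), plus
  controlled annotation corruption (dilate/erode/shift one class mask) for
  label-noise experiments.

## Worked example

```r
library(periseg)

build_unet(unet_config(middle_width = 256))
#> unet: depth 5, widths 16-32-64-128-256, input channels 1, dropout none
#>   1,940,885 trainable parameters; trained epochs: 0

split_dataset(sprintf("frame%04d.png", 1:2135), rng_seed = 1)
#> dataset_split (seed 1): train 1708 / validation 213 / test 214

# a small noise-free sweep with two deliberately corrupted annotations
cfg <- phantom_config(n_frames = 10, frame_width = 128, frame_height = 256,
                      noise_amplitude = 0, blur_sigma = 0, rng_seed = 7)
sweep <- generate_sweep(cfg)
sweep
#> us_sweep: 10 frames of 256x128 px (0.050 mm/px), source 'phantom-seed7'
#>   dental frames: 8/10; class presence: bone 10, crown 8, gingiva 10, pocket 2, root 8

bad <- corrupt_labels(sweep$labels, error_rate = 0.2, severity = 10, rng_seed = 3)
sweep$labels <- bad$labels
bad$corrupted
#> [1] 5 7

flag_inconsistent_frames(sweep, threshold = 0.9)
#> qc_report: 10 frames scored, threshold 0.90 (window +/-3)
#>   flagged frames: 4, 5, 7
```

Both corrupted frames (5 and 7) are flagged. Frame 4 is a conservative extra
flag: the pocket in this sweep exists only on frames 4–5, so once frame 5's
pocket mask is corrupted, frame 4's only pocket-bearing neighbour disagrees
with it and the check cannot tell which of the two is wrong — it flags the
pair and leaves the decision to the operator, who would then correct frame 5
with the annotation tool and recompound
(`apply_correction()`).

The same workflow is scriptable end to end from a shell via the bundled CLI
(`system.file("scripts", "periseg", package = "periseg")`):

```sh
periseg phantom  --out sweep --n-frames 20 --seed 1
periseg prep     --in sweep --out prep --seed 1
periseg train    --prep prep --out model --middle-width 16 --depth 3 --epochs 50
periseg predict  --model model/model.rds --in prep/images --out pred
periseg evaluate --pred pred --gt prep/stacks --out eval
periseg recon    --in sweep --out recon      # NIfTI volume export
periseg qc       --in sweep --out qc --threshold 0.9
```

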