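---
title: "Volumetric tumor segmentation with densely connected 3D encoder-decoders: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{znet3d methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Gliomas are delineated on multimodal MRI: four co-registered acquisitions
(Flair, T1, contrast-enhanced T1, T2) per subject, with expert voxel labels
distinguishing non-enhancing tumor core (label 1), peritumoral edema
(label 2) and enhancing tumor (label 4) on a background of 0 (label 3 marks
a voxel whose annotation is missing). Segmentation quality is scored on
three nested binary regions derived from that labeling:

* **WT** (whole tumor): labels {1, 2, 4}
* **TC** (tumor core): labels {1, 4}
* **ET** (enhancing tumor): label {4}

so that ET &sube; TC &sube; WT voxelwise — an invariant this package checks
at every stage that touches masks.

`znet3d` implements the full path from BraTS-layout NIfTI directories to
dice-scored predictions: I/O, preprocessing, rotation augmentation, a
densely connected 3D encoder-decoder network trained with ADAM under a
binary cross-entropy loss, and a synthetic phantom generator that makes the
whole pipeline testable on a laptop CPU with no data download.

## Preprocessing

Each modality is min-max normalized to [0, 1] **per modality and per case**:
absolute MR intensities are not comparable between scanners, subjects, or
acquisition types, so a global normalization scope would mix incomparable
scales. A constant volume maps to all zeros. Volumes are then resampled from
the native 240 x 240 x 155 grid to the network grid (128-cube at reference
scale) and stacked into a (4, D, H, W) tensor in the fixed order Flair, T1,
T1ce, T2.

Numerical choices worth recording:

* **Interpolation.** Images are resampled trilinearly on an align-corners
  grid; labels use nearest neighbour so the resampled value set is a subset
  of the input's. The native-to-network resize (including the anisotropic
  155-slice axis) has no canonical published scheme; per-axis trilinear
  resampling is the conventional choice and is what is implemented.
* **Order of operations.** Normalize before resizing (trilinear weights are
  convex, so values stay in [0, 1]); resize the label volume first and
  derive the three masks from the *resized* labels, which guarantees the
  three mask channels are mutually consistent at the network resolution.
* **Missing labels.** Label 3 is kept by the loader and remapped to
  background by `derive_masks()`, each time with a warning: silently
  discarding annotation must be visible in logs.

## Rotation augmentation

The training set is expanded five-fold by in-plane rotation of every axial
slice about the slice center: the default plan is the four angles
{-5&deg;, +5&deg;, +10&deg;, +15&deg;} plus the original. The angle *range*
[-5&deg;, +15&deg;] and the five-fold expansion (369 cases to 1845 pairs)
are fixed by the reference protocol; the four specific angles inside the
range are not published, so evenly spread values consistent with the
protocol's illustrated examples (-5&deg; and +10&deg;) were chosen once and
are configurable. Images rotate bilinearly, labels by nearest neighbour
(all mask channels sample the same source voxel, so nesting is preserved
exactly); exposed corners are filled with 0, the background intensity after
normalization. Augmentation runs after preprocessing, at network
resolution, halving the number of interpolation passes. The expansion is
deterministic and content-independent: `length(cases) * (1 + length(angles))`.

One documented inconsistency in the reference protocol: the train fraction
is stated once as 60% and once as 80%. It is a configuration value here
(`train_fraction`, default 0.8); the discrepancy is noted, not resolved.

## The network

The architecture is an encoder-decoder with dense same-resolution
concatenation ("Z" wiring):

* **Blocks.** Every stage is a double-convolution block: twice
  [3D convolution (kernel 3, stride 1, padding 1) &rarr; 3D batch
  normalization &rarr; ReLU]. Padding 1 with stride 1 preserves spatial
  dims, so all spatial change is carried by explicit pooling/upsampling.
* **Encoder.** `depth` stages (4 at reference scale) of 2x2x2 max pooling
  followed by a block; the deepest block doubles as the bottleneck. Input
  dims must be divisible by `2^depth` — checked at configuration time.
* **Decoder.** `depth` stages of 2x trilinear upsampling, concatenation
  with *every* feature map available at that spatial resolution, then a
  block. In a single-chain encoder there is exactly one such map per level
  (the same-level encoder output, or the input block at full resolution),
  so the dense wiring reduces to one skip concatenation per level; because
  the concatenated channel width is known at build time, no 1x1x1
  projection is needed on the skip path ("size normalization" lives in the
  output block, and trilinear upsampling cannot produce off-by-one dims on
  a divisible grid).
* **Output.** A 1x1x1 convolution to 3 channels and an elementwise sigmoid:
  the three nested regions are predicted as *independent* binary channels,
  matching the binary cross-entropy loss. Thresholded predictions are
  therefore not forced to nest; ground-truth stacks are.
* **Channel schedule.** `base_width` in the input block and first encoder
  stage, doubling per stage (32-64-128-256 at reference scale). Widths are
  not published; they are configurable, and the tests run tiny widths.
* **Initialization.** Kaiming-style normal for convolutions, unit gain/zero
  shift for batch norm, seeded and fully deterministic. The output bias
  starts at -3 &asymp; logit(0.047), the order of the foreground fraction in
  tumor volumes: with a heavily class-imbalanced sigmoid + cross-entropy
  head this avoids spending early optimizer steps learning "mostly
  background" (the focal-loss prior-initialization trick).

Because no deep-learning framework is available to this package's target
environment, all layers carry hand-written forward *and* backward passes
(convolution as slab-chunked im2col + BLAS). The analytic gradients are
verified against central finite differences in the test suite, which is the
load-bearing correctness argument for the whole training module.

### Batch vs. instance statistics

The reference protocol trains with batch size 1, where batch normalization
over (D, H, W) *is* instance normalization. At desk scale (a few hundred
optimizer steps) frozen running averages would systematically mismatch the
statistics the network was actually trained under, so inference also uses
the current volume's statistics; running averages are still tracked.
This choice is visible, deliberate, and matters only when batches are tiny.

## Training and evaluation

ADAM (0.9/0.999) minimizes the mean binary cross-entropy over all voxels
and channels. Batch size defaults to 1; larger batches accumulate gradients
before stepping. The per-epoch case order derives from `seed + epoch`, so
loss traces are exactly reproducible and epoch-prefixes are stable across
runs of different lengths. A non-finite loss aborts with a diagnostic. The
parameters with the best mean validation dice are checkpointed alongside
the final ones.

The default learning rate is 1e-4 (conventional for full-scale volumetric
segmentation, where training takes tens of thousands of steps). The
scaled-down experiments in the acceptance tests use 1e-2 to 3e-2: with
~30-160 total ADAM steps, each parameter can move at most ~steps x lr, and
the output bias alone must travel ~3 logits, so the step size must scale
inversely with the step budget. This is a property of the optimizer's
update magnitude, not a tuned-to-pass constant.

Evaluation uses the dice coefficient 2|MS &cap; GT| / (|MS| + |GT|). The
printed form of the metric in the source publication (union over
intersection) is dimensionally not a similarity in [0, 1] and contradicts
the definition used by its own references and results; the standard dice is
implemented as the evident intent. Two empty masks score 1.0 (perfect
agreement on absence; the formula is 0/0 there and a convention is
required). Report aggregation follows the leaderboard convention: per-case
dice per region, region means, and an overall mean defined as the
arithmetic mean of the three region means.

## The phantom generator

Phantoms emulate the BraTS layout exactly — four co-registered
pseudo-modalities plus a {0, 1, 2, 4} label volume, written as five
compressed NIfTI files per case directory. Geometry is a smooth ellipsoid
"brain" (semi-axes 0.45 x grid, mild radial shading) on zero background
carrying, with probability `tumor_probability`, a nested spherical lesion:
enhancing core (1/3 of the outer radius), non-enhancing shell (2/3), edema
shell (full radius), with floors so every region is nonempty. Region
intensities follow a fixed contrast table that mimics real glioma MRI
qualitatively — edema brightest on pseudo-Flair/T2 (0.90/0.80 vs. 0.35/0.40
brain), enhancing core brightest on pseudo-T1ce (0.95 vs. 0.40 brain) — plus
Gaussian noise (sigma 0.03 on the 0-1 intensity scale, about 1/18 of the
smallest region contrast). Everything is deterministic given the seed;
dataset generation seeds case *i* with `seed + i`.

Stated defaults: 32-cube grids keep CPU training of the recovery experiment
in minutes (the full 240 x 240 x 155 grid is supported and exercised once
in the acceptance tests); the outer radius is drawn from
`round(c(0.16, 0.28) * min(shape))` voxels, i.e. lesions occupying roughly
1-10% of the brain, the scale of typical gliomas.

What a green phantom test does and does not establish: it proves the mask
algebra, the geometry plumbing, the learnability of contrast-coded nested
regions, and the determinism of the full loop. It does *not* establish
performance on real gliomas — real lesions are multifocal, textured,
deformable, and embedded in anatomy; no MR physics is simulated. The
published full-scale dice values are therefore explicitly outside the
desk-scale acceptance surface, and the acceptance report contains no
numeric targets.

## Known limitations

* No Hausdorff or sensitivity/specificity metrics; no post-processing
  (e.g. connected-component filtering); no mixed precision or GPU path.
* Predicted masks may violate the nesting invariant (independent channel
  thresholds); enforcing nesting at prediction time would be a
  post-processing choice the reference protocol does not make.
* The NIfTI reader/writer covers the single-file NIfTI-1 subset this
  pipeline emits and consumes (datatypes uint8/int16/int32/uint16/float32/
  float64, scl rescale, both endiannesses); it preserves on-disk voxel
  order and does not reorient to RAS/LPS. Interoperability is
  cross-checked against an independent Python reader in the tests.
* Full-scale (128-cube, depth-4, base-32) *training* is supported but slow
  in pure CPU R; at that scale this package is a reference implementation,
  not a speed-competitive trainer.
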