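---
title: "otoseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{otoseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Middle- and inner-ear surgery depends on understanding the 3D geometry of
small, intricate structures — the fluid-filled inner-ear labyrinth, the
three middle-ear ossicles, the facial nerve canal, the sigmoid sinus, and
the compact-bone otic capsule that shells the labyrinth — as they appear in
high-resolution temporal-bone CT. Manual voxel-wise segmentation of these
structures takes minutes per structure and expert attention throughout.
`otoseg` implements a fully automated segmentation pipeline for this
setting: preprocessing, a trainable 3D encoder–decoder segmentation
network, Hounsfield-unit (HU) constrained morphological refinement of the
network's predictions, derivation of the otic capsule from the refined
inner-ear label, and an objective evaluation suite.

Because clinical temporal-bone CT datasets are not freely distributable,
the package also ships a procedural phantom generator that emulates the
relevant tissue/geometry configuration and serves as the test substrate
for the whole pipeline.

## Pipeline overview

1. **Ingestion** (`read_volume`, `read_labelmap`): NIfTI-1 volumes are
   reoriented on load to a canonical frame — axis 1 left→right, axis 2
   posterior→anterior, axis 3 inferior→superior — so the left–right axis is
   unambiguous everywhere downstream. A voxel's world position is its
   center: `world = origin + index * spacing` (0-based indices, mm).
2. **Preprocessing** (`window_rescale`, `standardize_side`): intensities
   are clamp-rescaled from the window [−500, 2000] HU to [0, 1]; left-sided
   scans are mirrored so all data present right-sided anatomy.
3. **Training** (`build_model`, `train`, `cross_validate`): one binary
   model per structure, trained with Adam on the soft Dice loss under a
   step-decay learning-rate schedule, with per-epoch intensity-jitter and
   flip augmentation, and optional k-fold cross-validation.
4. **Prediction + refinement** (`predict`, `binarize`, `refine_pipeline`):
   per-voxel foreground probabilities are thresholded at 0.5 and the mask
   is refined on a 0.25 mm isotropic working grid: voxels outside the
   structure's tissue HU range are removed, the margins are grown through
   connected in-range voxels, and discontinuous islands are excluded.
5. **Otic capsule** (`derive_otic_capsule`): grown outward from the
   refined inner ear through voxels in the compact-bone range
   650–2500 HU. The capsule is not trained; it is derived.
6. **Evaluation** (`dice`, `average_hausdorff`, `volumetric_similarity`,
   `evaluate_pair`): Dice coefficient, average Hausdorff distance in mm,
   predicted-to-reference volume percentage, and wall time, aggregated as
   mean (SD) with the sample (n−1) convention.

`run_end_to_end()` executes all stages on seeded phantoms and writes
per-case NIfTI outputs, a metrics CSV and a stage-status manifest.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| HU window | −500..2000 HU | rescale range for network input |
| training grid | 256×256×240 @ 1 mm (full scale) | grid volumes are resampled to for training |
| working spacing | 0.25 mm | isotropic grid for refinement and metrics |
| epochs / lr | 2000 / 1e-4 (full scale) | Adam protocol; lr decays by 1/3 every 400 epochs |
| folds | 5 | cross-validation folds |
| jitter | ×[0.9, 1.1] at p = 0.1 | global intensity factor per volume per epoch |
| flip | p = 0.5 | synchronized left–right flip of volume + label |
| soft-tissue range | −400..550 HU | inner ear, facial nerve (and sinus, by assumption) |
| bone range | 100..2500 HU | ossicles |
| compact range | 650..2500 HU | otic capsule |
| growth cap | 50 iterations | ≈ 12.5 mm reach at 0.25 mm spacing |

The training grid and its spacing are independent configuration values:
the full-scale protocol's printed grid (256×256×240 at "1 mm") is
dimensionally inconsistent with the native acquisitions it describes, so
neither value is derived from the other.

The sigmoid sinus has no documented refinement range; the soft-tissue
range is used as an explicit assumption and can be overridden per
structure.

## The segmentation backend

The backend is a plain 3D U-Net: `depth` resolution levels; two 3×3×3
convolutions per block, each followed by instance normalization and ReLU;
2× max pooling between encoder levels; nearest-neighbor upsampling plus an
up-convolution and skip concatenation per decoder level; a 1×1×1
convolution and sigmoid head. `residual_blocks = TRUE` adds identity
shortcuts around each block (1×1×1 projection where channel counts
differ), standing in for the residual-network end of the architecture
family; the hybrid 2D-pretrained-encoder variant is out of scope.

Design notes, in rough order of how much they mattered:

* **Instance normalization** is not optional at this scale. Without it the
  network trains only at very small learning rates and collapses (all-
  background, saturated sigmoid, dead ReLUs) at usable ones. With it, the
  desk-scale configuration converges reliably. This is consistent with
  common practice for 3D segmentation networks trained with batch sizes of
  1–2.
* **Loss**: soft Dice, `1 − (2Σpr + ε)/(Σp + Σr + ε)` with ε = 1e−5. The
  protocol this package follows reports training curves in Dice terms but
  never names its loss; soft Dice is the natural pairing and keeps
  `1 − loss` comparable with the evaluation metric (they agree to ε-order
  for binary predictions — asserted by a cross-module test).
* **Optimizer**: Adam (β₁ = 0.9, β₂ = 0.999) with
  `lr(epoch) = initial_lr · decay^⌊epoch/decay_every⌋`, 0-based epochs.
  Gradients are accumulated over `batch_size` samples per step.
* **Determinism**: initialization, shuffling and augmentation draw from
  sub-seeds derived from `(seed, epoch, sample)`; with a fixed thread
  count, training and prediction are bitwise reproducible.
* **Unstated details** (batch size 2, He-style seeded initialization,
  binarization threshold 0.5) are package decisions, not protocol facts.

### Desk-scale training

The demonstration configuration (`demo_pipeline_config()`) trains at
0.5 mm (32³ voxels over the same field of view as the 64³ @ 0.25 mm
phantoms) and refines at 0.25 mm — the same coarse-train / fine-refine
pattern as the full-scale protocol, which trains at 1 mm and refines at
0.25 mm. Desk-scale overrides: depth 3, 4 base channels (≈ 2.5e4
parameters), and 30 epochs at initial lr 3e−2 — training converges by
epoch ~20, comfortably inside the ≤ 300-epoch budget of the end-to-end
acceptance experiment on one CPU core.
The full-scale defaults (2000 epochs at 1e−4) remain the package
defaults; the higher desk-scale rate simply reflects the much smaller
network and problem.

## HU-constrained refinement

`hu_constrained_refine` is shrink-then-grow: labeled voxels outside the
structure's HU range are removed first (so out-of-range voxels can never
seed growth), then unlabeled in-range voxels connected to the label are
added iteratively. Growth uses face (6-) connectivity by default: diagonal
(26-) growth can leak through a one-voxel-thin bone septum, which is
exactly the boundary that matters for a capsule-bounded structure. Island
analysis uses 26-connectivity, i.e. it is conservative about calling a
region "discontinuous". Both are configurable; HU range endpoints are
inclusive. The growth cap (50 iterations by default) is a safety bound for
pathological inputs, not a tuning parameter — convergence first is the
normal case, and the refinement is then idempotent.

`refine_pipeline` adds one step beyond the plain
resample → refine → islands chain: components smaller than 10 voxels on
the working grid are discarded *before* growth. Scattered false-positive
specks that land inside some other large in-range tissue (the sigmoid
sinus is genuinely larger than the inner ear) would otherwise be amplified
by region growing into dominant components that island removal can no
longer distinguish from the target. Removing sub-resolvable debris before
maximizing margins is the same "exclude incorrectly predicted voxels"
operation, applied where it is still cheap; set
`pre_island_min_size = 1` to disable it.

`derive_otic_capsule` seeds from in-range voxels face-adjacent to the
inner ear and grows within 650–2500 HU; with `max_iterations = 0` it
returns exactly the first shell. Its output is disjoint from the inner-ear
label by construction.

## Metrics

* **Dice**: `2|A∩B| / (|A| + |B|)`; both-empty pairs score 1 by
  convention, exactly-one-empty pairs 0.
* **Average Hausdorff distance**: the symmetric average of the two
  directed mean nearest-neighbor distances between *boundary* voxels
  (mask voxels with a face neighbor outside the mask), with Euclidean
  distances between voxel centers in world mm. Boundary (surface) rather
  than full-volume distances make the metric the mean contour error, which
  is what sub-voxel AHD magnitudes refer to; full-volume AHD is a
  different (smaller for overlapping masks) quantity. The production
  implementation is a compiled double loop over boundary point sets and is
  checked against a pure-R brute-force oracle.
* **Volumetric similarity**: `100 · volume(pred) / volume(ref)` in
  percent; > 100 means over-segmentation. Undefined (reported `NA`) when
  either mask is empty.
* `evaluate_pair` never errors on degenerate predictions: an empty
  prediction yields Dice 0 with AHD and volume similarity flagged
  undefined, so batch evaluations keep their rows.

## The phantom generator

Each phantom is a 64³ @ 0.25 mm (16 mm)³ scene in trabecular bone:

* **inner ear**: spheroid vestibule + a spiral cochlear tube (2.25 turns,
  decreasing radius) + three orthogonal 240° semicircular-canal arcs +
  thin connector ducts joining the canals and cochlea to the vestibule, so
  the labyrinth is one fluid-connected body (as in real anatomy — and
  required for margin growth to rebuild an eroded canal from the
  vestibule). Filled with fluid HU.
* **otic capsule**: the compact-HU shell of configured thickness
  (dilation minus interior) around the inner ear — an analytically known
  voxel set, which is what makes the capsule-derivation oracle exact.
* **ossicles**: 3 small compact-HU ellipsoids inside an air-filled
  middle-ear cavity lateral to the labyrinth.
* **facial nerve**: a thin soft-HU tube curving past the labyrinth.
* **sigmoid sinus**: a wide soft-HU channel spanning the posterior volume.
* Gaussian HU noise (SD 20 by default, a typical high-resolution CT noise
  level) added to the volume; ground-truth labels are the exact noise-free
  constructed sets, mirroring manual segmentation as the reference
  standard. Labels are pairwise disjoint by precedence masking.

Tissue HU means — air −1000, fluid 20, soft 40, trabecular 600, compact
1500 — are chosen so the standard refinement thresholds partition the
tissues: fluid/soft inside −400..550, compact inside 650..2500, and
trabecular in the 550..650 gap excluded from both. The trabecular value is
the load-bearing choice: it must exceed 550, or the entire bone background
becomes "soft tissue" to the refinement step and margin growth escapes the
capsule. 600 HU is realistic for dense temporal-bone trabecular bone. With
the default noise SD, tail probabilities across these margins are
negligible; at SD 30 a small fraction of trabecular voxels crosses 650 and
the capsule oracle degrades gracefully (the acceptance bound there is
DSC ≥ 0.95 rather than 1.0).

Datasets jitter structure radii by ±20%, placements by ±0.5 mm, and
randomize the side; left-sided phantoms are exact mirrors of their
right-sided twins at the same seed.

**What a green test does and does not establish.** The phantom captures
the tissue-contrast configuration the pipeline exploits (a fluid structure
shelled by compact bone in a distinct-HU background, soft-tissue
confusers, air cavities) and the geometric regime (thin tubes at 2–4
voxels diameter). It does not capture CT physics (beam hardening, metal
artifacts, partial-volume effects beyond linear interpolation), scanner
variability, pathology, or true anatomical shape variation. End-to-end
phantom results therefore validate the *machinery* — training converges,
prediction + refinement recovers a held-out structure, the capsule
derivation is exact on its construction — not clinical accuracy, whose
published numbers require the non-distributable clinical dataset and
full-scale GPU training.

## Numerical choices and degenerate inputs

* Resampling: output grids share the input origin; values are
  trilinearly (volumes) or nearest-neighbor (masks, mandatory)
  interpolated at output voxel centers; centers outside the input field of
  view are filled with −1000 HU (air) or 0 (mask). Identity targets are
  exact no-ops. Oblique acquisitions (grid axes not aligned with
  anatomical axes) are rejected at load rather than silently resampled.
* Volumes are written to NIfTI as float64 so HU values round-trip exactly;
  masks as uint8.
* `keep_largest` ties break toward the component containing the smallest
  linear voxel index — deterministic and orientation-stable.
* Empty inputs: empty masks refine to empty; an empty inner ear yields an
  empty capsule with a warning; metrics on empty masks follow the
  conventions above.
* Cross-run reproducibility: all stochastic stages consume sub-seeds
  derived from the master seed; two runs with the same configuration
  produce identical metrics (the wall-time column aside).

## Known limitations

* The backend is a small plain U-Net; the hybrid 2D-pretrained-encoder
  variant of the architecture family is represented only by the residual
  option.
* Training assumes whole volumes fit in memory (no patch sampling or
  sliding-window inference); adequate at phantom scale, not at clinical
  full resolution on one CPU.
* AHD is computed between boundary voxel centers, not sub-voxel surface
  meshes; at 0.25 mm working spacing the discretization error is below the
  reported precision.
* The NIfTI layer supports the common scalar datatypes and axis-aligned
  affines only; no DICOM ingestion.
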