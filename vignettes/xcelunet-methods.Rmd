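---
title: "Dual-task shoulder CT segmentation and glenohumeral staging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-task shoulder CT segmentation and glenohumeral staging: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Preoperative planning for shoulder arthroplasty needs two things from a CT
scan at once: accurate 3D surfaces of the proximal humerus and the scapula,
and a staging of the osteoarthritic state of the glenohumeral (GH) joint.
`xcelunet` implements a single volumetric network that does both: a shared
convolutional encoder feeds (a) two parallel decoders that segment bone
regions and bone contours, and (b) a lightweight classification branch that
grades three clinical conditions — osteophyte size (OS, three grades by
maximum protrusion: < 3 mm, 3–7 mm, > 7 mm), GH joint-space narrowing
(JS: physiological / narrowed / non-detectable), and humeroscapular
alignment (HSA: concentric / eccentric).

Because clinical shoulder CTs cannot ship with a package, all experiments
run on synthetic shoulder phantoms with exactly known segmentation and
condition ground truth (see "What the phantoms do and do not emulate").

# Network

The encoder has three blocks (two 3×3×3 convolutions with ReLU, then 2×2×2
max pooling), starting at 8 feature maps and doubling per block; the
bottleneck holds 64 maps at 1/8 resolution, so an 80³ crop yields a 10³
bottleneck. Two transpose-convolution decoders mirror the encoder: the mask
decoder (MD) ends in a 1×1×1 convolution with 3-way softmax over
(background, humerus, scapula); the contour decoder (CD) predicts the
corresponding class boundaries. Encoder skips feed both decoders, and each
CD block output is concatenated into the same-resolution MD block input
(unidirectional CD→MD skips), letting edge evidence sharpen region
prediction. The classification path applies global average pooling to the
bottleneck, dense layers of 64 and 16 units (ReLU), and three heads:
3-softmax OS, 3-softmax JS, and a single sigmoid HSA unit (decision
threshold 0.5).

Design points that were genuinely open and how they were resolved:

* **Two convolutions per block.** The block inventory ("convolutional,
  ReLU, max-pooling") does not state a count; two is the U-Net convention
  and is used throughout.
* **CD→MD skips concatenate** rather than add, for consistency with the
  concatenating encoder skips.
* **CD head activation** is a 3-way softmax over edge classes (background /
  humerus edge / scapula edge), symmetric with the MD head.
* **No batch normalization** — the architecture description never mentions
  it.
* **Bottleneck ownership.** The deepest 64-channel block is its own
  parameter group so the four freeze regimes (below) are unambiguous.

# Losses

Stage-1 training minimizes `L_r + L_c` with

* `L_r = 1 − (α·D + (1−α)·C)` on the MD output, where `D` is the soft Dice
  score over foreground classes present in the target and `C` is a
  distance-weighted cross-entropy *score*;
* `L_c = 1 − (β·C + (1−β)·Ĉ)` on the CD output against morphological-
  gradient edge targets, where `Ĉ` uses the reversed (far-from-boundary)
  weights.

The cross-entropy terms enter as scores in (0, 1]: `C = exp(−WCE)` with
`WCE` the weight-normalized mean voxel cross-entropy. The source
architecture delegates the exact functional form of these terms to its
reference implementation; the exponential mapping is this package's
choice — it makes `C` commensurate with the Dice score, bounds both losses
in [0, 1), and gives exactly zero loss at a perfect one-hot prediction.

The Dice weight follows the schedule `α(t) = max(0.5, 1 − 0.005·t)`:
α = 1 initially, linearly down to 0.5 at iteration 100, constant after.
"Reduced by a factor of 0.005" is implemented as linear subtraction — the
only reading that reaches exactly 0.5 at iteration 100 (a multiplicative
0.995^t would give 0.606). One iteration is one epoch, consistent with the
epoch-level early stopping. `β` is the ratio of shape-boundary voxels to
all voxels in the batch, jointly over classes.

Distance weights are `w_near = 1 + γ·exp(−d/τ)` and
`w_far = 1 + γ·(1 − exp(−d/τ))`, with `d` the exact Euclidean distance
transform (in mm) from the inter-class boundary voxels. Defaults γ = 5 and
τ = 3 mm put the emphasis band at the scale of the bone interfaces; both
are exposed in `train_config()`.

Classification uses categorical (OS, JS) and binary (HSA) cross-entropy,
each sample's loss multiplied by the inverse-frequency weight of its true
class, `K_c = (1/N_c) / Σ_i (1/N_i)` (weights sum to one and are invariant
to rescaling the counts). The three task losses are summed; whether to sum
or average is not specified and the two differ only by a learning-rate
factor.

# Two-stage training and freeze regimes

Stage 1 trains encoder + both decoders on full-shoulder volumes (ADAM,
learning rate 1e-4, early stopping after 40 epochs without validation-loss
improvement, best-validation weights returned). Stage 2 trains the
classification branch on GH-centred crops under one of four regimes:

| regime | encoder | bottleneck | decoders | classification |
|--------|---------|------------|----------|----------------|
| TL     | frozen  | frozen     | frozen   | trainable      |
| FT-B   | frozen  | trainable  | frozen   | trainable      |
| FT-E   | trainable | trainable | frozen  | trainable      |
| FT-N   | trainable | trainable | trainable | trainable    |

Stage 2 optimizes the classification loss only; because no gradient path
reaches the decoders from that loss, decoder weights are unchanged even
under FT-N (a joint-loss switch exists but defaults off — re-training the
segmentation losses during fine-tuning is exactly what can degrade scapula
segmentation). The stage-2 optimizer is re-instantiated, with no stage-1
moment carry-over. Under TL the entire segmentation backbone is frozen, so
TL segmentation outputs are bit-identical to stage 1 by construction — the
test suite audits this with parameter-group hashes.

The 15% validation split is the package's choice (only the train/test
split is prescribed); stage-2 reuses the 1e-4 learning rate and trains the
three heads jointly, both unstated in the source.

# Activation maps

For a chosen class set `s` (OS/JS/HSA) and class `c`, the map is the ReLU
of the gradient-weighted sum of the 64 bottleneck feature maps: gradients
of the class score `y` are taken with respect to the pre-pooling bottleneck
activations (spatial positions only exist before pooling), averaged over
the `Z` bottleneck voxels (Z = 1000 for an 80³ crop) to give per-map
weights, and the weighted sum is clamped at zero and trilinearly upsampled
to the crop. For softmax heads `y` is the pre-softmax logit of class `c`
(standard practice — probabilities saturate); for the sigmoid HSA head,
`y` is the logit for class 1 and its negative for class 0. A
`localization_score()` quantifies the top-decile activation mass inside a
stated region, turning the qualitative "activations sit on the osteophyte"
reading into a number.

# Surface reconstruction and metrics

Meshes come from an isosurface extractor over the binary class mask at
level 0.5, implemented as marching tetrahedra on the Kuhn 6-tetrahedron
cube decomposition with sub-voxel edge interpolation and welded vertices.
Relative to table-driven marching cubes this trades slightly more
triangles for a guaranteed watertight, ambiguity-free surface (the suite
checks Euler characteristic 2 on a sphere); no smoothing is applied. Only
the largest connected component is kept.

Reconstruction error is the one-way vertex analysis: for each vertex of
the target mesh, the Euclidean distance to the nearest predicted-mesh
vertex; reported as RMSE and (one-way) Hausdorff maximum. Distances are
vertex-to-vertex, exactly as the evaluation is worded; nearest queries use
a uniform-grid spatial index, with an exhaustive search retained as the
test oracle. Voxel overlap uses per-class Dice, precision and recall.

The OS auto-labeler measures the maximum one-way distance from the
morphologic (osteophyte-bearing) humerus surface to the osteophyte-cleared
surface and applies the 3/7 mm thresholds. The direction matters:
osteophytes exist only on the morphologic surface, so the reverse distance
is ~0 by construction. Boundary values 3 and 7 mm are assigned to grade 1,
keeping the three intervals exhaustive.

# Synthetic phantoms

`generate_phantom()` composes signed distance fields: a spherical humeral
head (default radius 18 mm) with a cylindrical shaft, fused spherical-cap
osteophytes on the infero-lateral head whose maximum protrusion normal to
the unperturbed sphere is exactly `osteophyte_height_mm` (so the
auto-labeler's morph-to-cleared distance recovers it by construction), and
a scapular plate whose glenoid fossa is a spherical cut with curvature
radius 1.6× the head radius — less conforming than the head, as in
anatomy, giving a unique pole where the head-glenoid clearance equals
`joint_gap_mm`. The cut follows the (possibly cranially shifted) head
centre, so the clearance is invariant under the eccentricity used for HSA.
Labels are thresholded fields; ground-truth surfaces are interpolated from
the continuous fields at sub-voxel accuracy and are therefore independent
of both the label voxelisation and the reconstruction path under test. CT
intensity blends tissue (40 HU) and bone (1200 HU) through a logistic
partial-volume profile of half-width half a voxel, plus seeded Gaussian
noise (25 HU).

Grading conventions used for generation, where the clinical criteria are
qualitative: JS grade 0 for a gap ≥ 3 mm, grade 1 for 1–3 mm, grade 2 below
one voxel (non-detectable at acquisition resolution); HSA eccentric for a
cranio-caudal shift ≥ 2 mm (no numeric cutoff exists clinically; 2 mm
clearly exceeds voxel noise). These are artifact conventions, not clinical
claims. `generate_dataset()` allocates OS grades by largest-remainder
quotas of the requested mix (default: the study prevalences
31.1/36.1/32.8%) and samples JS (38.2/27.2/34.6%) and HSA (56.1/43.9%)
from the study prevalences; per-grade parameter ranges keep osteophyte
heights at least one voxel away from the 3/7 mm class boundaries.

What the phantoms do **not** emulate: realistic scapular morphology (the
"scapula" is a carved plate), cortical/trabecular structure, metal
artifacts, beam hardening, anisotropic spacing, or inter-patient anatomy
variation. Tests passing on phantoms therefore demonstrate the
correctness of the implementation (losses, gradients, freeze mechanics,
geometry recovery) and the learnability of well-separated conditions —
not clinical performance.

# Problem sizes and numerical choices

The package's experiments are sized for a single CPU:

* Stage-1 learning runs use 16 phantoms at 48³ voxels (1 mm spacing,
  9 mm head radius) — large enough for three poolings with margin.
* Stage-2 runs use GH crops of 40–48³ from slightly larger phantoms;
  the 80³ crop (10³ bottleneck) remains the inference-time default.
* At this scale one epoch is a handful of optimizer steps, two orders of
  magnitude fewer than an epoch over a clinical corpus, so the scaled
  experiments use a learning rate of 1e-3; the clinical-scale default in
  `train_config()` stays at the prescribed 1e-4.
* For the same reason the scaled fine-tuning run disables early stopping
  (patience = the epoch budget): classification training traverses a long
  plateau — the pooled bottleneck features carry the osteophyte signal as a
  small variance on a large constant offset — and at desk scale that
  plateau outlasts the 40-epoch clinical patience, which would otherwise
  return the untrained initial weights. The clinical-scale default stays
  at 40 epochs.
* Convolution kernels compute in single precision (memory-bound GEMMs);
  weights and gradients are stored in double. All forward passes are
  deterministic; every stochastic step (initialization, shuffling,
  splits, phantom noise) derives from one seed.
* Degenerate inputs have defined behaviour: single-class volumes yield
  uniform distance-weight maps (with a warning), a degenerate sphere fit
  in GH-crop extraction falls back to the humerus centroid (with a
  warning), an all-background segmentation skips classification with an
  explicit status, and zero class counts make the balancing weights an
  error rather than an implicit guess.
* Probability clamps: classification cross-entropy floors the true-class
  probability at 1e-12; the Dice denominator carries ε = 1e-6.

# Known limitations

* The GH-box extraction method referenced by the original pipeline (a
  femoral-head procedure) is not public; the sphere-fit-plus-nearest-
  glenoid-point construction here is a stand-in and is flagged as such.
* The exact functional form of the distance cross-entropy terms lives in
  the original CEL-UNet implementation; the exponential score mapping
  here reproduces its role in the loss, not necessarily its constants.
* Phantom realism is deliberately limited (see above); no claim is made
  that headline clinical metrics are reproducible from phantoms.
* Training at clinical scale (160³ patches, hundreds of cases) is out of
  desk-scale reach; the code paths are the same, only the sizes differ.
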