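# xcelunet

Dual-task volumetric analysis of shoulder CT: one network that both
segments the proximal humerus and scapula and stages three osteoarthritic
conditions of the glenohumeral (GH) joint —

* **OS** — osteophyte size, graded by maximum protrusion
  (grade 0: < 3 mm, 1: 3–7 mm, 2: > 7 mm),
* **JS** — joint-space narrowing (physiological / narrowed /
  non-detectable),
* **HSA** — humeroscapular alignment (concentric / eccentric, i.e.
  cranio-caudally shifted humeral head).

The package is aimed at methods work on edge-aware multi-task
segmentation: it provides the full training and evaluation stack plus a
seeded synthetic-phantom generator, so every experiment is reproducible
without clinical data.

## What is inside

**Architecture.** A 3-block 3D encoder (3×3×3 convolutions + ReLU, 2×2×2
max pooling, 8→16→32 feature maps, 64-map bottleneck) feeds two parallel
transpose-convolution decoders — a mask decoder (MD) with 3-way softmax
over (background, humerus, scapula) and a contour decoder (CD) predicting
class boundaries — with encoder skips into both and unidirectional CD→MD
skips per block. A classification branch applies global average pooling to
the bottleneck, dense layers (64, 16), and three heads (3-softmax OS,
3-softmax JS, sigmoid HSA). The forward and backward passes are
implemented in the package (Rcpp/Armadillo kernels); no external deep
learning framework is involved.

**Losses.** Region loss `L_r = 1 − (α·D + (1−α)·C)` (soft Dice `D`,
distance-weighted cross-entropy score `C = exp(−WCE)`), with the schedule
`α(t) = max(0.5, 1 − 0.005·t)`; contour loss
`L_c = 1 − (β·C + (1−β)·Ĉ)` on morphological-gradient edge targets, `β` =
boundary-voxel fraction of the batch; class-balanced classification losses
with inverse-frequency weights `K_c = (1/N_c)/Σ(1/N_i)`.

**Two-stage training.** Stage 1 fits the segmentation module (ADAM,
early stopping, best-validation weights). Stage 2 trains the
classification branch under one of four regimes — TL (backbone frozen),
FT-B (bottleneck re-trained), FT-E (encoder + bottleneck), FT-N (all) —
with frozen groups audited by weight hashes.

**Explainability.** 3D gradient-weighted class activation maps from the
bottleneck (Z = 1000 spatial positions for an 80³ crop), trilinearly
upsampled and blendable over the CT, plus a localization score
(top-decile activation mass inside a region of interest).

**Surfaces and metrics.** Watertight isosurfaces by marching tetrahedra,
one-way vertex distances (RMSE / Hausdorff), per-class Dice / precision /
recall, and the automatic OS grader from paired morphologic vs
osteophyte-cleared humerus surfaces.

**Synthetic phantoms.** Signed-distance-field shoulder phantoms (head +
shaft + osteophyte caps + carved glenoid plate) with exact ground-truth
meshes, labels, and condition grades; seeded and bit-reproducible.

## Worked example

```r
library(xcelunet)

# a phantom with a medium osteophyte, narrowed joint space, eccentric head
ph <- generate_phantom(phantom_params(osteophyte_height_mm = 5,
                                      osteophyte_count = 2,
                                      joint_gap_mm = 2,
                                      eccentric_shift_mm = 4,
                                      seed = 11))
ph
#> shoulder phantom 96x96x96 voxels @ 1 mm | OS 1, JS 1, HSA 1

# the automatic osteophyte grader recovers the generated size class
al <- os_autolabel(ph$humerus_morph_mesh, ph$humerus_cleared_mesh)
al$s_o_mm
#> [1] 4.986593
al$grade
#> [1] 1

# surface reconstruction error of the voxelized labels vs the exact mesh
m <- labels_to_mesh(ph$labels, class_id = 1)
one_way_distances(ph$humerus_morph_mesh, m)
#> one-way distances: rmse 0.323 mm | mean 0.288 mm | hausdorff 0.672 mm (n=26216)
```

The recovered protrusion (4.98 mm of a generated 5 mm) lands in grade 1
(3–7 mm), and voxelizing at 1 mm spacing costs ~0.3 mm RMSE against the
exact surface — the discretisation floor any segmentation is measured
against.

End-to-end (generate → train both stages → evaluate → activation maps):

```r
run_pipeline(list(out_dir = "runs/demo", seed = 1,
                  generate = list(n = 12, grid = 48, head_radius = 9),
                  train_seg = list(epochs = 8),
                  train_cls = list(setup = "FT-E", epochs = 8,
                                   crop_edge = 32)))
```

or from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/xcel.R", package = "xcelunet"))') \
    pipeline --config demo.yaml
```

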