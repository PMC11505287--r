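---
title: "Multi-view recurrent tooth segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view recurrent tooth segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

An intra-oral scan of one dental arch arrives as a triangle mesh `M = (V, E, F)`
with no guarantees about manifoldness, closedness, orientation or resolution.
The goal is a labeling `g : F -> C` over the 17 classes
`C = {L1..L8, R1..R8, G}` — sixteen teeth named by quadrant and position
(1 = central incisor .. 8 = third molar) plus gingiva `G`.

Rather than operating on the geometry directly (point clouds, edge
convolutions, graph cuts), `dentseg` is *projection-based* and
*detect-and-segment*. Two mesial/distal surface landmarks per tooth are
assumed as input (a landmark detector is out of scope here; the synthetic
generator provides ground-truth landmarks, and sidecar files carry them for
real scans). The pipeline is:

1. **Occlusion alignment.** The landmark set is registered to a shipped
   canonical template by closed-form orthogonal Procrustes (Kabsch), giving
   an upright, origin-centered pose. Because correspondences are known by
   tooth slot and landmark role, iterative closest-point matching would add
   nothing: its correspondence step is the identity here, so the closed form
   is the fixed point, with the usual determinant guard against reflections.
2. **Next-view sampling.** For each tooth with finite landmarks, orthographic
   cameras are placed on a 15 mm sphere around the landmark midpoint. Pose 0
   sits straight above (+z); subsequent poses spiral down the sphere with
   zenith growing linearly to `max_zenith` and azimuth advancing by a fixed
   step, every camera looking at the center.
3. **Rendering.** Each view yields a depth map (`1 - t/depth_range`, clipped
   to (0,1], 0 = no hit) and a screen-space unit normal map (zero on
   background), plus the pixel-to-first-hit-face table that later drives
   unprojection. These purely geometric maps are invariant to lighting,
   shading and reflectance by construction.
4. **Recurrent U-Net.** A shared-weight per-view U-Net conditioned on a
   tooth-type scalar, followed by a bi-directional convolutional LSTM across
   the view sequence, produces one probability map per view, binarized into
   masks at the pipeline operating point (below).
5. **Unprojection, voting, cleanup.** Masks are cast back to first-hit faces.
   The multi-view certainty of (face, class) is the fraction of that tooth's
   views in which the face was hit among views where it was visible at all.
   Region voting assigns each face its argmax-certainty class (gingiva if
   all zero), and connected-component cleanup keeps each tooth's largest
   component, reassigning stray faces to their next-certain adjacent class.

## The synthetic jaw generator

The generator emulates the anatomy the method cares about, not scanner
physics. A parabolic arch (defaults 64 x 56 mm) carries sixteen crown slots
placed by arc length with average adult mesiodistal widths, crowns nearly in
interproximal contact as in natural dentition. Crowns are superellipse-based
paraboloid domes (radial exponent 2.5, quadratic vertical profile — so the
wall slope stays finite where the crown meets the gum; an infinitely steep
rim would make the area of the boundary region, and hence every
area-weighted score, pathologically sensitive to sub-pixel mask placement).
A gingival cuff raises the gum around every crown base and fills the
interdental space, as the gingival margin and papillae do; the remaining
sheet is a corrugated ridge along the arch. Everything is composited as a
height-field maximum over a triangulated band whose planar vertices are
jittered by 0.28 edge lengths and re-flipped for quality, yielding an
irregular, scan-like tessellation rather than a regular grid (networks
trained on perfectly regular meshes latch onto the grid texture and become
spuriously sensitive to remeshing). The default target edge length is 1 mm
(roughly 5,000 faces per arch, about 40x coarser than a real intra-oral
scan, chosen so a full study runs on one CPU; the bundled studies use
0.6-0.8 mm). Labels come from the surface attaining the height maximum at
each face centroid, and each case carries its analytic labeler so that
retessellated copies can be relabeled exactly (`synthetic_labels()`);
mesial/distal landmarks are placed on the occlusal surface offset along the
(rotated) arch tangent and projected exactly onto the mesh.

Anomaly knobs mirror common orthodontic presentations: per-tooth presence
flags (missing teeth), positional jitter (crowding — contacts between
neighboring crowns appear as adjacent differently-labeled faces), rotation
about the local vertical, and an eruption offset (retention). `sample_jaw_specs()`
draws a family of cases with third molars absent about a third of the time,
other teeth rarely missing, mild rotations (sd 0.12 rad), jitter up to
0.35 mm and occasional retention — a mix chosen once to resemble the
anatomically complex end of orthodontic case collections.

What the generator does **not** emulate: scanner noise and holes, dental
appliances, interdental concavities (crowns are convex caps), texture, and
real crown morphology (cusps, fissures). Passing tests therefore demonstrate
that the pipeline machinery — rendering, learning, unprojection, voting,
metrics — is correct and end-to-end trainable on idealized anatomy; they do
not certify clinical accuracy on real scans.

## Network and training

Architecture (defaults in parentheses, reduced study sizes in brackets):

* U-Net stages: widths (32, 64, 128, 256, 512) [8, 16, 32]; each stage is two
  3x3 same-padding convolutions with batch normalization between convolution
  and ReLU; 2x2 max pooling between stages; 2x2-stride-2 transposed
  convolutions for upsampling.
* Input channels: depth, three normal components, and a constant channel
  carrying the tooth-type signal `i_tt = (type index + 1)/16` over the arch
  order `L8..L1, R1..R8` (so `L8 = 1/16`). The signal shares one network
  across all sixteen binary tasks; a decoder-stage additive-embedding variant
  sits behind `itt_embedding = TRUE`.
* Recurrent unit: one bi-directional convolutional LSTM layer (3x3 kernels,
  32 [8] hidden channels per direction) consuming the final decoder feature
  maps; the two directions' states are concatenated and reduced by a 1x1
  convolution and sigmoid. Consuming feature maps rather than logits
  preserves more information for cross-view correlation; "both layers" is
  read as the two directions (a stacked variant was considered and dropped
  as redundant at these widths).
* Deep supervision: a 1x1 sigmoid head on every decoder stage; the loss is
  the unweighted sum of per-head Dice losses with the reference downsampled
  by nearest neighbour to each auxiliary resolution (downsampling targets is
  cheaper than upsampling predictions and standard for deep supervision).

Training uses AdamW (decoupled weight decay; no decay on biases or
normalization parameters), cosine annealing with warm restarts, batches of 4
sequences, Dice epsilon 1.0 (the stability term's size is otherwise
uncritical), and mesh-level augmentation only: per training case, 10 [2]
fixed rigid+scale transforms (rotation within ±45° about a random axis,
translation ±5 mm per axis read as millimetres, isotropic scale 0.8–1.2)
are applied to the already-aligned mesh before rendering; the rendered 2D
maps are never augmented. An optional tessellation augmentation
(`n_remesh`) adds locally remeshed copies of each training mesh — in the
spirit of the flip-based local remeshing used as augmentation in the
robustness protocol — which decouples learned features from the particular
triangulation. Cases split 4:1 into train and validation;
`val_fraction = 0` supports deliberate single-case overfitting.

Defaults follow the full-scale recipe (learning rate and weight decay 0.001,
restart period 10,000 iterations, 49 views at 256x256). The bundled *scaled
study* — what the acceptance checks and the test suite actually run — uses
widths [8,16,32], recurrent 8, 9 views at 96x96, 20 synthetic jaws (16
train / 4 validation), 2 augmentations, 250 iterations and learning rate
0.01: a 39k-parameter network converges in minutes on one CPU at that step
size, whereas 0.001 would need thousands of iterations to reach the same
loss. The overfit sanity run trains on a single case with `val_fraction = 0`.

### Normalization statistics at inference

The effective batch for every batch-normalization call is the set of views
of one sequence (gradient accumulation gives batch-of-4 optimizer steps, but
statistics are per sequence). Sequences differ systematically — a molar
sequence's depth statistics are unlike an incisor's — so weights learn to
rely on per-sequence normalization. Inference therefore also normalizes each
sequence by its own view statistics rather than by global running averages;
this is deterministic for a fixed input and matches the statistics regime
the weights were trained under; with global running averages instead, the
classic small-batch train/eval normalization mismatch appears and held-out
masks degrade sharply while training loss looks healthy.

### The pipeline operating point

`segment_case()` binarizes probability maps at 0.995 rather than 0.5. This
is a structural consequence of certainty voting, not a tuned constant: a
false-positive pixel in any single view claims its first-hit face for the
tooth (gingiva never accumulates competing certainty), while a
false-negative pixel is healed by the union over the remaining views.
Empirically, eroding ground-truth masks by one pixel leaves the voted
labeling perfect, while dilating them by one pixel costs roughly a third of
the mean W-IoU. With that asymmetry the right operating point sits at the
precision end of the mask ROC; any strongly precision-biased cutoff behaves
similarly, and `binarize()` keeps the conventional 0.5 for plain mask work.

## Numerical and implementation choices

* **Rendering** is a z-buffer rasterization of camera-space triangles with
  one sample per pixel center — mathematically the per-pixel first-hit
  orthographic ray cast, and tested against a brute-force ray caster. Ties
  within 1e-5 mm along the ray resolve to the lower face index in both
  implementations. Pixel centers sit at `(i + 0.5)/H` of the viewport; image
  row 1 is the +up edge. Face (flat) normals are used and flipped per pixel
  toward the camera, since input winding is untrusted; depth polarity makes
  nearer surfaces brighter with 0 reserved for background.
* **Viewport**: half-extent 10 mm (a crown plus its neighbourhood), depth
  range 40 mm, spiral `max_zenith` 60° and azimuth step the golden angle
  (137.508°) — all configuration, since only the 15 mm offset and the
  spiral idea are fixed by the method.
* **Voting semantics**: a face hit by many pixels within one view counts
  once (certainty is a ratio of views); visibility denominators are per
  tooth trajectory, and faces never visible for a class have certainty 0
  for it. Component ties break by face count, then total area, then lowest
  face index. Reassignment of discarded-component faces is a single pass to
  the next-highest-certainty class whose retained region is edge-adjacent,
  else gingiva — iterating would risk ping-ponging between classes for no
  measurable gain.
* **Metrics**: W-IoU weights faces by area, so tessellation density does not
  bias the score (subdividing a region leaves the value unchanged). The
  boundary metric takes label-transition vertices of ground truth and
  prediction and reports the maximum over both directions of the 95th
  percentile (linear interpolation) of nearest-neighbour distances; a pooled
  variant is available (`pooled = TRUE`). Case values average over
  ground-truth teeth, unweighted; teeth missing from the prediction score
  W-IoU 0 with the boundary term flagged rather than fabricated.
* **Tessellation perturbations**: vertex displacement magnitudes are uniform
  on [0, 0.2] mm with directions uniform on the sphere (only the magnitude
  range is prescribed by the robustness protocol; the direction law is this
  package's choice). Flip optimization uses the min-angle criterion on the
  two incident triangles; isotropic remeshing uses the conventional 4/3 and
  4/5 split/collapse thresholds, valence-6 flips and tangential relaxation,
  with vertices re-projected onto the input surface afterwards; the 0.1 mm
  fidelity bound is a package-level guarantee checked on fixtures, not an
  external prescription.
* **The network stack is hand-built** (single-precision im2col/GEMM
  convolutions, explicit backpropagation, AdamW) and validated by
  directional finite-difference gradient checks and an overfit sanity test.
  `tanh` is evaluated via `expf` — the libm `tanhf` costs several times more
  and dominates ConvLSTM time otherwise.
* **Degenerate inputs**: faces with repeated vertices or zero area are
  dropped at load with a logged count (the method makes no mesh-quality
  assumptions and the ray casting tolerates holes, so repair would add risk
  for no benefit); meshes emptied by that rule are rejected. Landmark sets
  must have mesial/distal both finite or both infinite per slot; alignment
  needs at least four finite point pairs and rejects collinear
  configurations.

## The tessellation-robustness study

The robustness harness re-segments cases after random vertex displacement
(RVD, magnitudes uniform on [0, 0.2] mm), flip optimization (PFO) and
isotropic remeshing (ER). Two design points matter when reading its output:

* The 0.2 mm displacement bound is the error scale of intra-oral scanners,
  which presupposes scan-resolution tessellation; on coarse meshes the same
  displacement barely tilts face normals. The bundled study therefore runs
  the harness on finely tessellated cases (0.45 mm edges).
* On retessellated meshes (ER), ground truth must move too. Nearest-face
  transport — the right tool for real scans — carries boundary noise of
  about half an edge length, which can dominate the measured delta. For
  synthetic cases the harness can instead relabel the perturbed mesh
  exactly from the generator's analytic surface (`relabel = "generator"`),
  so the reported deltas measure the model, not the bookkeeping.

## Known limitations

* Faces invisible from every view of their tooth (deep interdental clefts on
  real scans) can never be claimed and default to gingiva; this is inherent
  to projection methods and is why the round-trip property is stated on
  visible faces.
* The generator's convex crowns make the binary masks easier to learn than
  real crown morphology; the scaled study's accuracy numbers should be read
  as machinery validation, not clinical performance.
* Single-precision training on one CPU is reproducible for a fixed seed with
  the same BLAS, but bitwise reproducibility across BLAS builds is not
  guaranteed.
* Binary PLY is not read; convert to ASCII PLY, OBJ or STL.
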