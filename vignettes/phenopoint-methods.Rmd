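---
title: "Methods: organ segmentation and trait extraction for tomato point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organ segmentation and trait extraction for tomato point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopoint)
```

## Scope and data model

`phenopoint` analyses colored 3D point clouds of greenhouse tomato seedlings
acquired by a single-view depth camera: coordinates in millimetres, 8-bit RGB
per point, and an optional integer organ label (stem = 0, growing point = 1,
leaf instances = 2..n, −1 = unlabeled noise). All stages consume and produce
the same `point_cloud` container, and PLY (ASCII or binary little-endian) is
the on-disk interchange format.

The pipeline has five stages: condition filtering and color denoising;
dataset expansion by rigid augmentation; downsampling; semantic organ
segmentation by a hierarchical point-set network; and geometric trait
extraction (leaf length, stem diameter). Each stage is usable on its own.

## Preprocessing

**Condition filtering** (`roi_filter`) keeps points inside closed per-axis
intervals. In the camera frame of a downward-facing sensor the plant
typically occupies a height window of roughly 500–650 mm and a working
distance window of 350–450 mm; both are configuration, not constants,
because the axes depend on the mounting geometry.

**Color denoising.** Time-of-flight sensors produce *flying pixels* at object
silhouettes, where one detector pixel mixes foreground and background
returns; the resulting points are spatially adjacent to the plant but
chromatically neutral. Two tools exploit that color gap:

* `kmeans_color_denoise` runs Lloyd's algorithm on the per-point RGB matrix
  (base R `stats::kmeans` under a deterministic greedy farthest-color
  initialization, so a seed fixes the result) and keeps the cluster(s) whose
  mean Excess Green Index exceeds the across-cluster mean — an
  operationalization of "keep the predominant green vegetation" that extends
  to k > 2. The number of clusters is either given or chosen by `choose_k`,
  which counts dominant modes of smoothed luminance and (saturation-gated)
  hue densities and clamps to \[2, 4\]; ambiguous evidence defaults to 2.
* `exg_segment` thresholds the Excess Green Index, ExG = 2G − R − B
  (range −510…510). The threshold is chosen per sample by
  `exg_auto_threshold`: histogram the values (default bin width 10, about a
  hundred bins over the full range), find the two highest-count modes
  (local maxima carrying at least 5% of the tallest mode's count, so stray
  tail bins never masquerade as peaks), and
  return the center of the lowest bin strictly between them — the valley
  separating the vegetation and background peaks. Unimodal inputs fall back
  to the midpoint between the mean and the maximum; constant inputs are an
  error because no separation exists.

K-means features are RGB only (no spatial coordinates): flying pixels are
embedded *inside* the plant's spatial extent, so geometry does not separate
them while color does.

## Augmentation and bookkeeping

`augment` expands each cloud into rigid variants: rotations about the
vertical axis through the centroid (default 0°–315° in 45° steps), each
optionally composed with a horizontal mirror. The default scheme emits
exactly 16 variants; a 97-plant corpus split 7:3 at plant level
(`split_plants`, nearest-integer rounding: 68/29) therefore yields
1,088 training and 464 testing samples, 1,552 in total. Augmentation is
applied after the split, independently per subset, so no rigid variant of a
test plant leaks into training. Coordinate inversion
(x, y, z → −x, −y, −z) is available as a separate opt-in operator
(`coordinate_inversion`); it is not part of the default scheme because
8 rotations × {identity, mirror} already accounts exactly for the 16-fold
expansion.

## Downsampling: voxel grid vs farthest point

`voxel_downsample` partitions space into cubes of edge *s* anchored at the
cloud's minimum corner (half-open cells; the global max corner is clamped
into the top cell against floating-point wobble) and emits one
representative per occupied voxel: the centroid (default, averaging
suppresses sensor noise), the voxel center, or the original point nearest
the centroid. `farthest_point_sample` is the greedy max–min alternative:
each next point maximizes the minimum squared distance to the selected set,
ties broken by lowest index, start at index 0 by default.

Their costs differ structurally, not just empirically. Every
`sampling_result` carries a `distance_ops` counter — the number of
point-to-point distance evaluations — as a hardware-independent cost
surrogate: FPS performs N updates per iteration, (m−1)·N in total, while
voxel-grid downsampling in centroid mode performs none (it only bins and
averages). At N = 2×10⁵ and m = 10⁴ that is a guaranteed ≥10³× gap, which
is what makes the voxel sampler attractive inside a network's sampling
layer. Wall-clock comparisons echo the counter gap on any machine; absolute
seconds are hardware-bound and are deliberately not part of any contract.

Because a set-abstraction layer needs an exact output count while a voxel
size only controls density indirectly, `match_voxel_size_to_count` bisects
the voxel size (geometrically, over \[~0, cloud diameter\], at most 50
steps), then forces exactness: surplus representatives are dropped by a
seeded uniform draw, deficits padded by duplicating seeded random
representatives.

## The segmentation network

The network is the standard hierarchical point-set encoder/decoder for
semantic segmentation: three set-abstraction (SA) levels, each = sampling
layer → ball-query grouping → shared-MLP encoder, followed by three
feature-propagation (FP) steps back to full resolution and a dropout
classification head over the three semantic organ classes. Its defining
modification is the sampling layer: voxel-grid downsampling matched to the
target centroid count replaces farthest point sampling (`sampler = "vgds"`
vs `"fps"`, a pure toggle — all downstream tensor shapes are identical).

The encoder for one group evaluates γ(max_i h(x_i)): a shared per-point MLP
*h* over the group members (relative coordinates, normalized by the ball
radius, concatenated with the members' features), a coordinate-wise max over
the group, then an MLP γ. The max makes the encoding a symmetric function —
exactly invariant to permutation or duplication of group members — which is
the property that lets an order-free network consume unordered points. The
decoder interpolates coarse features onto finer positions by
inverse-squared-distance weights over the 3 nearest centroids (a coincident
point inherits its centroid's feature exactly), concatenates the fine
level's own encoder features (skip link), and applies a shared MLP.

Implementation: there is no deep-learning framework in the package's
dependency set, and none is needed at this scale — the network is plain R
matrix algebra with hand-derived backpropagation (verified against central
finite differences in the test suite) and an Adam optimizer. The geometric
scaffolding of a cloud (sampling indices, groups, interpolation weights) is
fixed by the cloud and seed, so it is precomputed once per cloud; training
then only re-runs dense/max layers and their adjoints over that fixed
structure.

**Normalization.** Each cloud is centered on its centroid and scaled to unit
maximum radius *before* resampling, which makes the whole pipeline —
including the voxel grid anchored at the normalized min corner — exactly
invariant to rigid translation, and the per-point input features are the
normalized coordinates themselves (RGB can be added via `use_colors`; off by
default since the geometry alone identifies the organs and color palettes
vary with lighting).

**Loss and imbalance.** Leaf points dominate real canopies (roughly 60%),
so the cross-entropy is weighted per class by inverse support (weights
normalized to mean one). Support weighting in the *metrics* direction
(weights ∝ N_k) answers a different question — how good is the labeling
overall — and is kept in the metrics module; using those same proportions as
loss weights would further amplify the majority class, the opposite of what
training under imbalance needs.

**Training defaults** follow the reference configuration: Adam, initial
learning rate 10⁻⁴, weight decay 10⁻⁴, learning-rate halving every 20
epochs, dropout 0.5, batch size 7, 100 epochs, 20,000 input points, early
stopping on validation mean IoU (best-validation weights restored).

**Desk preset.** The configuration the test suite exercises is deliberately
small: 1,024 input points; 256/64/16 centroids; grouping radii 0.1/0.2/0.4
of the cloud diameter with K = 48/32/16; encoder widths 48-48-96,
96-96-160, 160-160-160; decoder widths 160, 96, (64, 32); per-cloud Adam
updates at learning rate 3×10⁻³ halved every 25 epochs, dropout 0.3, at
most 60 epochs. At 1,024 points the reference radii (0.05/0.1/0.2 of the
diameter) leave level-1 balls nearly empty, hence the doubled radii; the
larger learning rate matches the much smaller parameter count. Trained on
four synthetic plants it reaches ≥95% training accuracy and ≥0.7 per-class
IoU on held-out synthetic plants within 60 epochs (pooled over the held-out
set; medians over three seeds) — an overfit-then-generalize sanity bar, not
a benchmark claim.

`predict` resamples any cloud to the model's input budget, scores it, and
propagates labels back to every original point through its nearest
resampled neighbor, so the output labeling always covers the full input.

## Leaf length by space-curve fitting

Single-view leaf clouds are non-closed surfaces, so mesh-based
skeletonization is unavailable. Instead the midrib is recovered as the
intersection of two extruded planar fits:

1. optional PCA pre-alignment rotates the leaf so its principal axis is the
   shared parameter axis y (on by default — it makes both projections
   single-valued functions and the estimate rigid-motion invariant);
2. the cloud is projected onto the XOY and YOZ planes;
3. each projection is fitted with a least-squares polynomial of degree m
   (default 3 — one bend, no oscillation; configurable 1–6). The
   independent variable is centered and scaled internally for conditioning
   and coefficients are reported in original units; the residual sum of
   squares at the solution is carried on the fit;
4. extruding the XOY fit along z and the YOZ fit along x gives two
   surfaces whose intersection is the parametric space curve
   r(y) = (f_xoy(y), y, f_yoz(y)) over the *observed* parameter extent (no
   extrapolation);
5. the leaf length is the curve's arc length: composite Simpson quadrature
   of the speed √(x′² + y′² + z′²) with analytic polynomial derivatives,
   1,000 subintervals by default, with the subinterval count doubled until
   the estimate moves by less than 10⁻¹⁰ relative (at most six doublings).

Known limitations are inherent to the construction: strongly curled leaves
whose projections are multi-valued in y are not representable, and the
observed-extent domain slightly underestimates leaves whose extreme tips are
unsampled. Degree-1 fits make the arc length exactly the chord length, the
lower bound it can never undershoot.

## Stem diameter

Stems taper, so the measurement height is fixed: 10 mm above the base (the
minimum height coordinate of the stem points), slab half-thickness 2.5 mm —
thick enough to populate a ring at typical sensor density, thin enough that
taper within the slab is negligible. The slab is rotated into the frame of
its oriented bounding box (principal axes of the covariance: eigenvector
columns ordered by decreasing eigenvalue, sign-fixed, determinant corrected
to +1 — an orthogonal approximation to the minimal-volume box that is exact
for the symmetric slabs at hand), projected onto a coordinate pair, and a
circle is fitted; the diameter is 2r.

The circle fit is the algebraic (Kåsa) solution: with c = r² − a² − b², the
squared-residual objective Σ\[(x−a)² + (y−b)² − r²\]² is linear least
squares in (a, b, c) and is minimized exactly in closed form — so the
"algebraic vs geometric" ambiguity is resolved in favor of the objective as
printed, with an optional Gauss–Newton refinement of the geometric distance
objective available behind `refine`.

The projection pair is chosen by fit quality (`projection = "auto"`): both
candidate pairs are fitted and the one with the smaller radius-relative RMS
residual wins. A maximum-spread rule fails exactly where it matters — on
single-view half rings, whose slab thickness can out-spread the ring's minor
axis. Single-view visibility also biases the estimate itself (half the arc
constrains the circle less well); the synthetic half-cylinder tests document
roughly a ≤10% error under moderate noise, against ≤2% for full-surround
sampling.

## Evaluation metrics

`confusion` tallies per-class TP/FP/FN over the three semantic classes;
`per_class_metrics` derives precision TP/(TP+FP), recall TP/(TP+FN),
F1 = 2PR/(P+R), IoU = TP/(TP+FP+FN), plus a per-class one-vs-rest accuracy
(TP+TN)/N — the latter flagged as an interpretation, since a per-label
"accuracy" is not otherwise derivable from the per-class counts. Any 0/0 is
reported as 0 and flagged (`degenerate`), so absent classes can never
silently inflate aggregates. `weighted_metrics` aggregates with support
weights w_k = N_k/ΣN_j and also reports the overall accuracy ΣTP_k/N. The
evaluation uses exactly three semantic classes; references to a fourth
label in some segmentation protocols (background) do not apply to these
fully-labeled canopies.

## The synthetic generator

Real labeled tomato canopies at this growth stage are not publicly
deposited, so the package ships a deterministic generator
(`generate_plant`, `generate_dataset`) whose outputs carry exact ground
truth — the test oracle for every downstream module:

* **stem**: cylinder-surface samples of known diameter (defaults span the
  4–13 mm range a caliper records on real seedlings);
* **growing point**: a dense ellipsoidal cluster at the apex;
* **leaves**: bands of half-width 8 mm around arched midribs
  (0, L·t, A·sin πt) attached along the stem in a spiral phyllotaxis; the
  true midrib arc length is computed by fine quadrature (10⁵ Simpson
  subintervals) on the generating curve;
* **colors**: per-organ Gaussian palettes (leaf green, green-brown stem,
  bright apical cluster, neutral-gray noise) under which leaf ExG ≈ 180 and
  noise ExG ≈ 0 — the separation the denoising stage relies on;
* **flying pixels**: gray points offset 5–30 mm outward from randomly chosen
  silhouette points, labeled −1, matching the mixed-return mechanism;
* **single view**: an optional half-space cull removes stem-surface points
  whose outward normal faces away from the camera.

One integer seed fixes a plant (or a whole corpus) bit-exactly. Default
density 0.35 points/mm² and sensor noise σ = 0.1 mm; the recovery tests use
σ = 1 mm for leaves to represent a pessimistic sensor.

What the generator does *not* emulate: pinnate leaflet structure (bands
model the main-axis length that defines the trait), occlusion between
organs, lighting-dependent color drift, laser bloom, and the long-tailed
noise of real ToF depth maps. Green tests therefore certify algorithmic
correctness and closed-loop recovery on idealized plants, not field
performance on real canopies.

## Problem sizes in the test suite

The suite is sized for a laptop CPU: the network runs its desk preset
(1,024 points, four training plants, two held-out, three seeds); sampling
oracle checks use 50 clouds of up to 200 points against an O(N²m)
brute-force reference plus one 2×10⁵-point complexity run; trait-recovery
loops use 20 seeded plants per trait; bookkeeping builds the full 97-plant
corpus at reduced density (0.02 points/mm²). The paper-scale network
configuration (20,000 points, full widths) is provided but not exercised by
the tests.
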