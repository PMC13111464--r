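# phenopoint

Organ-level analysis of colored 3D point clouds of greenhouse tomato
seedlings, for plant-phenotyping researchers who want leaf lengths and stem
diameters out of single-view depth-camera acquisitions without manual
measurement.

The package covers the full pipeline:

* **Preprocessing** — region-of-interest condition filtering on closed
  per-axis coordinate intervals; removal of time-of-flight *flying pixels*
  by K-means clustering in RGB space; vegetation segmentation by the Excess
  Green Index, ExG = 2G − R − B, with an automatic histogram-valley
  threshold per sample.
* **Dataset expansion** — a 16-variant rigid augmentation scheme (8
  rotations about the vertical axis × optional horizontal mirror) applied
  independently within a 7:3 plant-level train/test split, so 97 plants
  become 68/29 originals and 1,088/464 augmented samples (1,552 total).
* **Downsampling** — voxel-grid downsampling (VGDS) and greedy max–min
  farthest point sampling (FPS) with matched output counts and a
  hardware-independent `distance_ops` cost counter: FPS evaluates (m−1)·N
  distances to select m of N points, VGDS in centroid mode evaluates none.
* **Segmentation** — a compact hierarchical point-set network (three
  set-abstraction levels of sampling → ball-query grouping → shared-MLP
  encoder γ(maxᵢ h(xᵢ)), a feature-propagation decoder, dropout head) whose
  sampling layer is voxel-grid based; FPS can be swapped back in with a
  config toggle and identical tensor shapes. Implemented in plain R matrix
  algebra with hand-derived backpropagation and Adam; classes are stem /
  growing point / leaf.
* **Trait extraction** — leaf length as the arc length of the space curve
  r(y) = (f_xoy(y), y, f_yoz(y)) obtained by intersecting two extruded
  least-squares polynomial fits of the leaf's planar projections; stem
  diameter d = 2r from an algebraic (Kåsa) least-squares circle fit of an
  oriented-bounding-box-aligned slab sliced 10 mm above the stem base.
* **Metrics** — per-class precision, recall, F1, IoU and support-weighted
  aggregates (w_k = N_k/ΣN_j).
* **Synthetic data** — a deterministic generator of labeled tomato-like
  plants (stem cylinder, apical cluster, arched leaf bands, organ color
  palettes, silhouette flying pixels) whose ground-truth stem diameters and
  midrib arc lengths make every stage testable offline.

PLY (ASCII and binary little-endian) is the interchange format: float
`x,y,z` in millimetres, uchar `red,green,blue`, optional int `label`.

## Worked example

```r
library(phenopoint)

plant <- generate_plant(plant_spec(stem_diameter_mm = 8, leaf_count = 5,
                                   flying_pixel_count = 400, seed = 42))
cloud <- plant$cloud
print(cloud)
#> <point_cloud> 5786 points, 7 label classes
#>   extent (mm): x [-95.7, 110.8], y [-91.6, 114.8], z [-1.3, 196.9]

clean <- exg_segment(cloud)           # ExG valley threshold denoising
sum(clean$labels == -1L)              # flying pixels surviving: 3 of 400
clean <- clean[clean$labels >= 0L]

stem_diameter(clean[clean$labels == 0L])$diameter_mm
#> 8.081344        # truth: 8 mm

leaf_length(clean[clean$labels == 2L])$length_mm
#> 134.6884        # truth: 132.1 mm (generating midrib arc length)

res <- voxel_downsample(clean, voxel_config(5))
c(res$count, res$distance_ops)
#> 950 0           # 5381 -> 950 points, zero distance evaluations
```

The printed numbers mean: the 5,786-point synthetic plant (5 leaves + stem
+ growing point + 400 gray flying pixels) loses 402 points to the ExG
threshold — almost exactly the injected noise; the stem diameter is
recovered within 1% and the first leaf's midrib length within 2% of the
generator's ground truth; and a 5 mm voxel grid compresses the cloud ~6×
without a single point-to-point distance evaluation.

A command-line front end for the file-based steps is installed at
`exec/phenopoint` (`phenopoint synth`, `preprocess`, `denoise`, `augment`,
`downsample`, `benchmark`, `traits`, `evaluate`); training and prediction
are R-API workflows (`segmentation_model()`, `train_model()`, `predict()`).

## Vignette

`vignettes/phenopoint-methods.Rmd` documents the models and the numerical
choices: the ExG valley-threshold rule, the augmentation bookkeeping, the
voxel/FPS cost model, the network architecture, normalization and loss
weighting, the space-curve construction and its quadrature, the OBB/circle
fit conventions, and what the synthetic generator does and does not emulate.
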