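---
title: "Methods: mask-level grasp and cut point estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mask-level grasp and cut point estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumpkinpick)
```

# The problem

In trellis ("dome-type") pumpkin cultivation the fruits hang below the
canopy and each is attached to the vine by a short, thick stem (peduncle).
A harvesting robot with one gripper and one cutter needs three pixel
locations per pumpkin: two grasping points on the fruit and one cutting
point on the stem. Instance segmentation supplies per-instance masks of
two classes, *fruit* and *stem*; everything downstream of the network —
deciding which stem belongs to which fruit and where the keypoints sit —
is deterministic mask geometry. That deterministic layer is this package.

All coordinates are `(row, col)` with row 1 at the image top. This is the
one convention used everywhere; annotation files store the usual 0-based
`(x, y)` and the readers/writers convert.

# Fruit–stem matching

## Model and assumptions

Three priors of hanging cultivation justify the matcher:

1. *Adjacency* — the two masks of one pumpkin touch or nearly touch.
2. *Gravity* — the stem centroid is above the fruit centroid.
3. *Uniqueness* — one fruit has at most one stem.

Centroids are centers of mass: the arithmetic mean of set-pixel
coordinates. Adjacency is measured on the stem's *boundary* pixels (set
pixels with an unset 4-neighbour) against the Euclidean distance
transform of the fruit: the count of stem boundary pixels with distance
strictly below `dis_thr`. Restricting to the boundary makes the count a
length of contact zone, not an area, so it is resolution-stable and
O(perimeter). The distance transform comes from `EBImage::distmap()`
(exact Euclidean; cross-validated in the tests against an all-pairs scan).

A candidate pair must satisfy the gravity constraint strictly
(stem centroid row < fruit centroid row) and have an adjacency count
strictly greater than `num_thr`. Contested candidates are then resolved
one-to-one greedily in ascending order of the matching degree
`D = arctan(|Δcol| / |Δrow|)` — the angle of the centroid offset from the
vertical, 0 for a stem hanging straight above its fruit. Ties on `D`
prefer the larger adjacency count, then the smaller fruit and stem index,
so results are deterministic. The output always satisfies
`K ≤ min(M, N)` and never repeats a fruit or stem index; unmatched
instances are reported separately, which is exactly how badly occluded
pumpkins (only a fruit, or only a stem, visible) are filtered out of the
picking plan.

## Parameters

* `dis_thr` (pixels, default 2.0): a stem boundary pixel counts as
  adjacent below this Euclidean distance. 2.0 admits direct contact
  (distance 1) and one-pixel gaps with diagonal offsets (√2) while
  excluding two-pixel gaps.
* `num_thr` (count, default 5, strict `>`): minimum evidence of a real
  attachment. The defaults were chosen together so that an attachment
  with a contact segment of at least 6 pixels — what a realistically
  thick stem produces — passes, while single-pixel grazes do not. Both
  scale with image resolution and are exposed in `match_config()` and on
  the CLI.

The degree gate is deliberately absent: a lone candidate with a large
`D` is still accepted, since the printed-order greedy only uses `D` to
rank alternatives. Scenes where this matters (a stem far off-vertical yet
adjacent and above) are rare under gravity.

# Keypoint geometry

The line `l_p` through the fruit and stem centroids is stored in one of
two forms: *vertical* (`col = c`) when the centroid columns coincide
within 1e-9 px, else *sloped* (`row = k·col + b`). On each side of `l_p`,
the fruit pixel with maximum perpendicular distance to the line is a
grasping point; in the vertical case the distance is `|col − c|`. Pixels
exactly on the line (perpendicular distance ≤ 1e-9 px) belong to neither
side: an asymmetric ≤/> split would assign them arbitrarily, and an
on-line pixel can never be a side's maximizer in a non-degenerate scene,
so symmetric exclusion changes nothing while keeping the partition
well-defined. Among equidistant pixels the smallest row, then smallest
column wins — a pure determinism device that the exhaustive-oracle tests
rely on. A maximizer is always a boundary pixel of the fruit; the test
suite asserts this via the boundary-pixel set.

The cutting point is the stem's center of mass. A bent (L- or J-shaped)
stem can place its centroid off the mask, which is physically uncuttable,
so by default the point snaps to the nearest set pixel and reports the
snap distance; callers can disable the snap. Pairs with degenerate
geometry (coincident centroids, an empty side) are skipped with a warning
rather than failing the scene.

Grasp points are reported as pixel coordinates without any
gripper-clearance offset: end-effector geometry, depth, and robot-frame
transforms are out of scope.

# Point-rendering refinement

Segmentation errors concentrate at instance boundaries. The refinement
stage upsamples a coarse per-instance probability map and re-predicts only
the cells where the mask is least certain:

1. bilinearly upsample the map by `upsample_factor` (default 2);
2. select the `n_points` (default 28² = 784) cells with smallest
   `|p − 0.5|`, ties in row-major order;
3. overwrite those cells with the predictor's output;
4. repeat for `steps` (default 5) iterations: 7×7 → 224×224.

When a level holds fewer than `n_points` cells — the first ×2 level of the
default schedule is 14×14 = 196 — every cell is selected; a level cannot
yield more distinct points than it has cells, and reference
implementations of this inference clamp the selection count the same way.
The default run therefore issues 196 + 4·784 = 3332 predictor queries.

Bilinear upsampling uses the align-corners-false convention (output cell
centers mapped into input cell space, edges clamped), implemented as two
interpolation matrices so a run is a pair of matrix products. Outputs are
convex combinations of inputs, hence stay in [0, 1], and a constant map is
preserved exactly. With the identity predictor (each query answered with
the interpolated value already present) the refinement is *bitwise*
identical to pure repeated upsampling, which pins down the arithmetic
path.

The trained point head — in the source architecture an MLP over coarse
features concatenated with fine FPN features — is *not* reimplemented:
there are no public weights and no dataset. It is abstracted as
`function(coords, values)` receiving normalized `(row, col)` cell centers
in [0, 1]² plus the current interpolated values, returning probabilities.
The package ships the identity predictor and a ground-truth oracle
predictor; the oracle demonstrably improves the thresholded IoU of a
blurred disk over the pure-upsample baseline in the tests.

# Evaluation metrics

`precision = TP/(TP+FP)` and `recall = TP/(TP+FN)`; zero denominators
yield `NA` markers, never silent zeros. Matching evaluation counts per
ground-truth pair by exact `(image, fruit, stem)` identity. The reference
operating point quoted throughout (TP = 215, FP = 4, FN = 2 → 98.2% /
99.1%) is only consistent with the third count being *false negatives*,
although the source tabulates it under "TN"; the recall formula fixes the
reading and the package stores FN.

Average precision follows the COCO protocol: greedy score-descending
matching at each IoU threshold (each truth used once), all-point
interpolated precision–recall integration, averaged over the thresholds
0.50–0.95 in 0.05 steps. All-point interpolation (rather than 11-point)
matches the threshold set's provenance. Per-image detection caps are not
applied; desk-scale scenes are small.

# Synthetic scenes

The generator emulates, at mask level, the phenomena that drive matching
errors in canopy imagery:

* each pumpkin is a horizontally elongated ellipse (semi-major axis
  12–22 px on a 256×256 canvas, vertical flattening 0.6–0.8 — the
  flattened shape of dome-grown fruit) with a ribbon stem (length
  10–18 px, width 40% of length clamped to 6–8 px) attached at the top
  arc within `stem_angle_jitter` of vertical;
* lone fruits and lone stems act as distractors for the matcher,
  emulating instances whose partner was missed;
* occluders emulate leaves: a disk bite anchored on a boundary pixel
  (foliage covers an instance from its silhouette inward), radius
  0.2–0.35 of the instance's effective radius, abandoned if it would
  remove more than 40% of the pixels or split the mask.

Scenes are bit-reproducible from a seed, and the caller's RNG state is
untouched. Ground-truth keypoints are computed by an *independent*
brute-force implementation — explicit coordinate sums, per-pixel
distances, exhaustive nearest-pixel scans — never by the detection code,
so the generator and the detector cross-validate rather than sharing a
bug.

What the generator does **not** emulate: photometric variation,
segmentation noise along boundaries (masks are geometrically clean),
stems occluded *by their own fruit*, multi-pumpkin mask overlap beyond
placement adjacency, and the erroneous/missing detections a real network
produces. Passing on synthetic scenes therefore validates the geometry
and the algorithmic contracts, not robustness to real segmentation
artifacts.

One behavioral consequence worth knowing: the fruit–stem contact segment
is only as wide as the stem (≈ 6–8 px), so a leaf-scale bite that lands
on the junction removes *all* adjacency evidence and the matcher
(correctly) drops the pair. Under per-instance occlusion probability 0.3
this costs roughly a tenth of the pairs in recall while precision stays
at 1.0 — the same asymmetry the matcher shows on real degraded masks,
where errors come from the segmentation stage rather than the geometry.

# Numerical choices and problem sizes

* Rasterization: a pixel is set iff its center is inside the polygon
  under the even-odd rule, boundary-inclusive — deterministic and
  brute-force testable; independent of vertex order and orientation.
* Mask → polygon tracing emits the pixel-edge boundary and verifies the
  round trip bit-for-bit before returning; masks with holes or multiple
  components are routed to the COCO run-length dialect instead.
* Tolerances: 1e-9 px for vertical/coincident centroid detection and for
  the on-line pixel exclusion; centroid-line residuals are exact to
  floating point by construction.
* Test problem sizes: fuzzed scenes at 120–256 px, 100 oracle fruits at
  32–64 px, 200 + 200 scenes for recovery measurements, 50 maps at
  224×224 for selection checks — sizes at which exhaustive oracles are
  exact and the full suite runs in about a minute.

# Known limitations

* Matching is greedy, not a global assignment; it can differ from the
  minimum-total-degree matching in adversarial many-to-many geometries,
  though not in gravity-plausible ones (the tests include a contested
  case where greedy and exhaustive enumeration agree).
* The degree measure collapses at `Δrow = 0` (returns π/2 with a flag);
  the gravity gate makes such candidates impossible in practice.
* COCO run-length support covers uncompressed counts only.
* No 3-D localization: mapping pixel keypoints to robot coordinates
  requires depth and calibration, deliberately outside this package.
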