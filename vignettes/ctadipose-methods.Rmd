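---
title: "Automated SAT/VAT quantification from abdominal CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated SAT/VAT quantification from abdominal CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Abdominal obesity is assessed clinically by how much adipose tissue sits
*inside* the abdominal cavity (visceral adipose tissue, VAT) versus *under
the skin* (subcutaneous adipose tissue, SAT).  CT resolves both directly:
adipose tissue occupies a characteristic attenuation band of about -190 to
-30 Hounsfield units (HU), so *finding* fat is easy; the hard part is
*splitting* it into SAT and VAT, because the two compartments touch wherever
the abdominal-wall muscle layer is thin or interrupted.  Manual slice-by-slice
annotation of a whole abdominal series takes an expert tens of minutes per
study; `ctadipose` implements a fully automated pipeline that does it in
seconds and quantifies TAT (total), SAT and VAT in millilitres.

## The pipeline

The method is anatomy-driven rather than learned, and runs per axial slice
with one 3-D step (bone detection):

1. **Body detection** (`detect_body_region()`).  Voxels above the air
   threshold (default -1000 HU) form the foreground; a one-pixel opening
   removes noise speckle; 8-connected labeling keeps the largest component
   per slice (the body), discarding the scanner bed and sheets; interior
   holes such as bowel gas are filled.
2. **TAT detection** (`detect_tat()`).  Body voxels inside the inclusive fat
   band `[fat_low, fat_high]` = [-190, -30] HU.
3. **Non-fat segmentation** (`segment_nonfat()`).  Body minus TAT, opened
   with a disc of physical radius `opening_radius_mm` (default 3 mm) so the
   thin skin ring disappears while the muscle wall, organs and bone survive.
   Muscle is deliberately *not* segmented from organs: the separation
   boundary only depends on the outermost non-fat surface.
4. **Closed path** (`convex_hull_path()`).  The convex hull of the non-fat
   pixels of a slice is the shortest closed path enclosing them; it bridges
   the SAT–VAT connections at muscle gaps.
5. **Path correction** (`correct_closed_path()`).  The hull spans
   concavities, so parts of the path float in subcutaneous fat.  Every
   coordinate along the rasterized path is tested for *contact* (on or
   8-adjacent to a non-fat pixel); non-contact coordinates slide along their
   own image column toward the centroid of the non-fat region until they
   first make contact (coordinates whose column holds no non-fat pixel are
   deleted), and the corrected coordinates are re-chained
   nearest-neighbour-first from the lexicographically smallest one.
6. **Separation mask and split** (`build_separation_mask()`,
   `split_sat_vat()`).  Each corrected path is filled with a
   pixel-centre-in-polygon rule (boundary included); TAT outside the mask is
   SAT, TAT inside is VAT.
7. **Bone correction** (`detect_bones()`, `build_correction_mask()`,
   `apply_vat_correction()`).  Fatty marrow lies in the fat band and inside
   the separation mask, so it contaminates VAT.  Bones are grown in 3-D
   (26-connectivity) from all voxels above `bone_seed` (1000 HU), accepting
   neighbours above `bone_grow` (150 HU); each slice's 8-connected bone
   component gets its own corrected, filled hull (covering its marrow), and
   VAT inside those hulls is moved to a dedicated `removed_bone_fat`
   compartment.  Slices are classed by their bone configuration: lateral
   bone present (ribs/pelvis) means the cavity is bone-bounded on three
   sides and all component hulls act; spine-only slices act on the posterior
   hull alone.

The decomposition SAT + VAT + removed-bone-fat = TAT holds exactly at every
stage, which the test suite asserts on every volume it touches.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `fat_low`, `fat_high` | HU | -190, -30 | standard CT adipose band; bounds inclusive |
| `air` | HU | -1000 | air attenuation; body = strictly above |
| `bone_seed` | HU | 1000 | cortical bone floor; every voxel above it seeds growth, keeping the pipeline automatic |
| `bone_grow` | HU | 150 | approximate cortical/soft-tissue boundary, so growth fills the shell without leaking into muscle (~45 HU) |
| `opening_radius_mm` | mm | 3 | removes structures thinner than ~6 mm: skin (~2 mm) goes, abdominal wall (≥ 8 mm) stays |
| `min_area` | px | 100 | smallest credible body cross-section; smaller slices yield an empty mask and a warning |
| `slice_range` | – | none | restricts analysis to the abdominal range (diaphragm to coccyx) when a longer series is supplied |

All thresholds live in one validated `thresholds()` object
(`fat_low < fat_high < bone_grow <= bone_seed`, `air <= fat_low`); the equal
`bone_grow = bone_seed` configuration is legal and reduces region growing to
seeded connected-component labeling, which the tests exploit as an oracle.

## Geometric and numerical choices

* **Hull vertices include collinear boundary points.**  A pixel lying on a
  hull edge between two other foreground pixels is reported as a vertex.
  This matches the natural set-theoretic definition (a point not strictly
  inside any triangle of other points) and makes the vertex set directly
  comparable against a brute-force oracle.
* **Contact correction walks the whole path, not just the vertices.**  Hull
  vertices are foreground pixels and are therefore always in contact; the
  floating parts of the path are the rasterized *edge* coordinates spanning
  concavities.  The path is densified (Bresenham) before correction.
* **"Vertical" movement.**  A non-contact coordinate keeps its column and
  moves along rows only, toward the non-fat centroid.  The alternative
  (radial movement toward the centroid) is isolated behind the same
  predicate and could be swapped; the vertical reading reproduces the
  expected behaviour on the hand-traced C-shaped fixture and keeps the
  procedure exactly testable.
* **Re-chaining ties.**  The corrected coordinates are re-chained greedily by
  Euclidean distance; ties break toward the smaller row, then smaller
  column, and the chain starts at the lexicographically smallest coordinate,
  so identical inputs always produce identical paths.
* **Self-intersection.**  Greedy chaining can in principle produce a
  self-crossing polygon; such paths are filled with the even-odd rule and
  flagged with a warning rather than rejected.
* **Rasterization.**  A pixel belongs to a filled path if its centre is
  strictly inside (even-odd scanline parity, half-open row spans) or lies
  exactly on an edge (integer arithmetic, so the test is exact).  Boundary
  pixels count as inside, i.e. fat directly on the muscle surface is
  classified VAT-side; the opposite convention changes results by a
  one-pixel rim only.
* **Connectivity.**  2-D labeling uses 8-connectivity (diagonal contacts
  count); 3-D growth uses 26-connectivity.  4-connectivity would declare
  diagonal contacts "not in contact" and over-trigger path correction.
* **Per-component bone hulls.**  A joint hull of spine plus ribs would cover
  most of the visceral cavity and delete true VAT; each 8-connected bone
  component is corrected and filled on its own.
* **Posterior/lateral bone rule.**  A component is POSTERIOR when its
  centroid's lateral offset from the body midline is within 25% of the body
  half-width on that slice, otherwise LEFT/RIGHT: paraspinal structures sit
  well within 25%, costal and iliac structures well outside, so the rule is
  insensitive to the exact cut in between.
* **Degenerate inputs.**  Slices with fewer than 3 non-collinear non-fat
  pixels yield no path (empty separation there); bone components with fewer
  than 3 pixels contribute their raw pixels without a hull; a correction
  that leaves fewer than 3 coordinates falls back to the uncorrected hull
  with a warning; 0/0 metric ratios are reported as `NA`, never as 0.

## The phantom generator

No patient CT data ship with the package; `phantom_spec()` /
`generate_phantom()` build synthetic axial abdominal volumes with exact
voxel-level ground truth, and `default_suite()` fixes the five-geometry
battery used by the tests and the acceptance script: (a) clean convex body,
(b) muscle ring with two anterior gaps (the SAT–VAT connections that force
the hull/correction machinery to work), (c) spine-only slices, (d)
spine-plus-rib slices (lateral bone), (e) a noisy variant of (b).

The phantom nests elliptical compartments — skin (2 mm), subcutaneous fat
(15 mm), abdominal-wall muscle (8 mm) — around a visceral region holding
organ tissue, visceral fat blobs, a vertebra (cortical shell above the bone
seed threshold with fatty marrow inside the fat band — precisely the error
the correction mask must remove) and optional rib arcs, over an air
background with a scanner-bed slab.  Nominal attenuations (air -1000, bed
-600, skin 20, fat -100, muscle 45, organ 40, bone 1200, marrow -80 HU) sit
comfortably inside the threshold bands.  The default grid is 24 slices of
256 x 256 at (1.5, 1.5, 5) mm — the geometry of a 512-pixel clinical slice
at half resolution, sized so the whole battery segments in well under a
minute.  The visceral fat load (36 blobs with 10–24 mm semi-axes) is
calibrated so the truth VAT/SAT ratio lands near 0.7, the ratio reported for
adult abdominal cohorts; rib arcs are painted as short 12-degree segments,
two per side, as rib cross-sections appear in an axial plane.  Noise is
additive Gaussian; truth labels are defined pre-noise, so noisy tests
measure robustness of the pipeline, not label ambiguity.  Generation is a
deterministic function of the spec's seed and never calls segmentation code.

What the phantom does **not** emulate: realistic organ shapes and texture,
partial-volume blur at tissue interfaces, beam hardening and streak
artifacts, contrast phases, arms in the field of view, or anatomical
variation along the stack.  Passing the phantom battery therefore
demonstrates the correctness of the geometry and bookkeeping of the method —
thresholding, hull construction, correction, bone removal, conservation —
not clinical-grade performance on patient data.

## Problem sizes and test design

The unit tests run the pipeline on 4-slice 128 x 128 phantoms; the
end-to-end checks use the full 24 x 256 x 256 battery.  Independent oracles
back every geometric primitive: an O(n^4) triangle-containment brute force
for the hull (100 seeded point sets, n <= 50), an exhaustive
point-in-polygon loop for rasterization, an igraph connected-components
construction for 26-connected region growing (20 seeded 32^3 volumes), an
exhaustive voxel loop for confusion counts, and a hand-traced 9 x 9
C-shaped fixture for the path correction.  File formats round-trip through
their own readers plus an external cross-check of the DICOM writer.

## Known limitations

* The separation boundary is per-slice; strongly oblique muscle walls could
  be tracked better with 3-D continuity constraints.
* The column-wise correction cannot hollow a concave chain: the filled path
  of a long open arc necessarily covers the arc's mouth.  For bones this is
  mitigated by per-component hulls and realistic (short) rib cross-sections;
  for the muscle wall it is exactly the intended behaviour (the mouth *is*
  the visceral cavity).
* Intermuscular fat between the wall and the skin is counted as SAT, and
  fat exactly on the path boundary as VAT, each by one-pixel convention.
* The pelvic cavity is excluded only by choosing `slice_range`, not
  algorithmically.
* DICOM support covers uncompressed little-endian single-frame CT series;
  enhanced multi-frame objects and compressed transfer syntaxes are out of
  scope.
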