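---
title: "Measuring cartilage thickness from segmented knee MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cartilage thickness from segmented knee MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartthick)
```

## The problem

Cartilage thickness is the standard imaging surrogate for degenerative joint
disease: as osteoarthritis progresses, femorotibial cartilage thins. Once the
cartilage has been segmented from a knee MRI, "the" thickness of the tissue is
still not a uniquely defined quantity — it depends on where measurement rays
originate, in which direction they travel, and how the opposing surface is
represented. This package implements five automatic measurement methods on
segmented 3D label volumes, the standardized parcellation of the femorotibial
joint into 4 regions and 20 subregions, and the statistics used to compare the
methods against each other, so that method-induced differences can be
quantified rather than ignored.

Inputs are integer label volumes (MetaImage or NIfTI) on a fixed anatomical
frame: x runs anteroposterior (anterior at low x), y mediolateral, z
head-to-feet. Voxel indices are 0-based and a voxel center sits at
`index * spacing`. The default voxel spacing, (0.36, 0.7, 0.36) mm, matches a
sagittal DESS knee protocol: sagittal slices are indexed by y, so the coarse
0.7 mm axis is mediolateral. The default label encoding (1 femoral bone, 2
femoral cartilage, 3 tibial bone, 4 tibial cartilage) follows the published
OAI-ZIB segmentations; it is an assumption about the input data and is always
overridable.

Throughout, *distal* and *proximal* name the two cartilage surfaces of a
structure. For the tibia the distal surface is the cartilage–bone interface
(larger z, since z grows toward the feet) and the proximal surface the
cartilage–synovia interface; for the femur the anatomical names swap — its
distal (articular) surface faces the tibia. Geometrically both bones obey the
same extraction rule: per (x, y) voxel column, the highest-z voxel is distal
and the lowest-z voxel proximal, in the working frame of the surface. All
measurements originate on the distal surface and run distal → proximal.

## Parcellation

The tibial cartilage splits into medial and lateral plates at the midpoint of
the occupied y-range. Each plate gets a *central* subregion: a z-axis cylinder
about the plate's center of gravity whose radius is the smallest radius
enclosing at least 20% of the plate voxels (the 20th-percentile in-plane
distance, ties included — deterministic and equivalent to 20% of the volume
for uniform voxels). The remaining voxels fall into anterior, posterior,
internal, and external quadrants bounded by the ±45° diagonals through the
cylinder center; anterior faces −x and internal faces the intercondylar
midline. The exact quadrant boundary geometry is a convention of the
standardization this parcellation follows; the 45° diagonals are the simplest
reading and are isolated in one function.

The femoral cartilage splits at the trochlear sulcus. No algorithm for sulcus
detection is standard, so the package uses the simplest geometric reading: for
every y, the mean cartilage column height (run length × z-spacing) over the
anterior half of the femur is computed; the profile is smoothed with a 5-point
moving average; the sulcus is its interior minimum. If no interior minimum
exists (e.g. a flat test structure) the split falls back to mid-y with a
warning. Each femoral plate then divides along x: the *central* (weight-
bearing) band occupies exactly the x-interval spanned by the corresponding
central tibial subregion (the "vis-à-vis" rule, read literally as x-interval
equality); smaller x is anterior, larger x posterior. The central band is
further cut into three equal-width y-thirds — internal (toward the midline),
central, external.

Which y side is "medial" depends on whether a left or right knee was scanned
and cannot be inferred from the label volume; `medial_side` ("low-y" by
default) records that convention explicitly.

## The five measurement methods

**3D mesh normals (3D-MN).** Surface voxels become mesh vertices. Because the
vertices of a column-wise surface sit on the in-plane integer lattice, the
Delaunay triangulation of their footprint reduces to the lattice cell
triangulation (cocircular degeneracies resolved by a fixed diagonal); the
package triangulates only occupied cells, which, unlike hull-based Delaunay
implementations, does not span holes in the footprint. Per-vertex normals are
the normalized, area-weighted average of incident face normals, oriented
distal → proximal; each normal ray is intersected with the proximal mesh
(Möller–Trumbore, compiled code) and the distance to the first hit is the
thickness sample. Misses and isolated vertices are counted, not imputed.
Samples are unweighted by mesh element area.

**3D nearest neighbors (3D-NN).** For every distal surface voxel, the
Euclidean distance to its exact nearest proximal surface voxel, via a kd-tree
over all proximal voxels. This is by construction a lower envelope: at any
matched origin it cannot exceed the mesh-normal value when both target the
same proximal geometry, and on flat plates the bound is exact.

**3D ray tracing (3D-RT).** Eight origin spheres are placed per knee: one
below each tibial plate (plate centroid offset 10 mm bone-ward along +z) and
one near the center of curvature of each femoral subregion group (anterior,
central, posterior × medial, lateral), found by an algebraic least-squares
sphere fit to the group's distal surface; degenerate fits fall back to the
surface centroid plus a fixed offset. Each sphere is tessellated as a UV
sphere with 60 polar and 60 azimuthal vertex subdivisions — 2 poles plus
60 × 58 ring vertices = 3482 rays, each originating at a sphere-surface vertex
along the outward normal. Rays march in fixed steps of half the smallest
voxel spacing; a ray must enter its target (sub)region's voxel set within 100
iterations or it contributes nothing; thickness is the Euclidean distance
from the first sample inside to the first sample outside after entry. Samples
are assigned to the subregion of the entry voxel. The iteration unit is read
as one marching step; with the 2 mm sphere radius this gives a reach of about
20 mm from the sphere center, which constrains how far the fitted femoral
sphere centers may sit from the cartilage (the composite knee phantom's
femoral radius defaults to 14 mm for this reason).

**2D centerline normals (2D-CN).** Per sagittal slice, a least-squares cubic
`z(x)` is fitted through all cartilage pixels (degree three avoids edge
oscillations on outlines with at most two inflection points). At every integer
x position the centerline normal is marched in 0.1-pixel steps in both
directions; the two outline intersection points are the extreme pixels of the
contiguous occupied run containing (or nearest to) the centerline point, and
the thickness is their distance. The sample is assigned via the more distal
intersection point. Endpoints are pixel centers, so this method reads
slightly higher than the surface-fit methods — the marching endpoint lies in
the outermost pixel rather than on the inter-center plane.

**2D surface normals (2D-SN).** Per slice, separate cubics are fitted to the
distal and proximal outlines (per-column boundary pixels). The normal to the
distal fit at `(x, fd(x))` is intersected with the proximal cubic by exact
root finding (the composition is cubic in the ray parameter; `polyroot`).
Among real roots on the proximal side within the fit domain extended by a
2-pixel margin, the nearest intersection wins, with ties broken toward the
smaller |x − x₀|. Slices with fewer than five distinct x positions, or
rank-deficient fits, are skipped and counted.

On the femur, vertical columns and single-valued fits cannot represent the
hook-shaped posterior condyles, so posterior-subregion voxels are first
rotated 90° about the y-axis — an exact index permutation `(i, j, k) →
(k_ref − k, j, i)` that requires the equal x/z spacing of the sagittal
protocol — processed in the rotated frame, and mapped back. The same
treatment applies in-slice for the 2D methods. Columns that still intersect
the cartilage in more than two disjoint runs after rotation are skipped and
counted rather than split; this is conservative and logged.

All distances are computed in physical millimetres, so the anisotropic
mediolateral spacing never distorts in-plane measurements. Every method
discards (and counts) samples above a 15 mm plausibility cap, a guard against
runaway normals; cohort-level extremes are additionally screened by the 5-SD
rule below.

## Cohort statistics

Per knee, mean thickness is the unweighted arithmetic mean of samples
globally, per region (LT, MT, LF, MF), and per subregion. Outlier knees are
flagged subregionally: per subregion, the means of all methods and knees are
pooled; any knee with a value more than five pooled standard deviations from
the pooled mean is removed entirely, in a single pass (the pooled statistics
are computed once, outliers included; the rule is isolated in one function
because pooling across methods only, rather than methods and knees, is an
equally defensible reading).

Inter-method comparison per (sub)region uses one-way repeated-measures ANOVA
with knees as subjects, the Tukey-Kramer test on the within-subject error
term for multiplicity-adjusted pairwise p-values (studentized range
distribution), and a family-wise α of 0.01. Bland-Altman bias and 1.96-SD
limits of agreement (sample variance) and Lin's concordance correlation
coefficient (population 1/n moments, per Lin's original definition) complete
the pairwise picture. Degenerate inputs are handled explicitly: identical
methods give F = 0 and adjusted p = 1; a zero within-subject error with a
non-zero effect gives F = ∞; CCC is an error when both series are constant.

## Phantoms: what they validate, and what they do not

The phantom generators produce label volumes with analytically known
thickness so every method is testable end-to-end without any imaging data:

* `make_slab_phantom()` — a flat or tilted plate of constant normal
  thickness; the untilted slab anchors its lower surface on a voxel-center
  plane, so the voxelized plate has `floor(t/dz) + 1` layers and surface-to-
  surface methods measure exactly `(layers − 1) · dz` on it.
* `make_shell_phantom()` — a spherical shell sector of constant radial
  thickness. Its lateral boundary is cut parallel to the z-axis (a cylinder
  at ρ = R · sin θmax) rather than radially: a vertical face is invisible to
  column-wise surface extraction, so the boundary cannot masquerade as a
  proximal surface and corrupt the analytic truth near the rim.
* `make_knee_phantom()` — two flat tibial plates of distinct thickness plus a
  half-cylindrical femoral shell whose thickness dips at a configurable
  trochlear-sulcus trough, all in one volume, so the complete pipeline
  (splits, cylinder, vis-à-vis, thirds, rotation, all five methods) runs and
  populates all 20 subregions.

Voxelization includes a voxel when its center lies inside the continuous
solid — unbiased and consistent with the voxel-center coordinate convention.
Note that at a fixed resolution the voxelized volume of a non-commensurate
slab is quantized (a 2 mm slab at 0.36 mm spacing has 6 layers whether you
like it or not); volumes converge to the analytic value as spacing shrinks,
and the tests assert the convergence rather than a fixed-resolution identity.

Passing on phantoms demonstrates geometric correctness of each method and of
the parcellation under known truth. Phantoms do not emulate real cartilage's
surface fibrillation, denuded areas, partial-volume segmentation noise, or
inter-reader variability; method rankings on real data can differ in
magnitude even though the mechanisms (nearest-neighbor lower bound,
ray-tracing obliquity overestimation, centerline-vs-surface endpoint
conventions) carry over.

## Numerical choices and test problem sizes

Default tunables, all in physical units: ray march step 0.5 × min spacing
(0.18 mm); 100 marching iterations; sphere radius 2 mm; tibial sphere offset
10 mm; 2D-CN normal march 0.1 pixel; thickness cap 15 mm; polynomial degree
3; sample-to-subregion assignment by nearest labeled voxel within 2 voxel
spacings. Sphere fits use the linear (algebraic) least-squares formulation;
fits with radius above 100 mm are treated as degenerate (flat).

The test suite exercises the pipeline at deliberately modest problem sizes —
plates of 20–40 mm, shells of 10–35 mm radius, a composite knee of roughly
10⁵ cartilage voxels, and 500 simulated null cohorts for the type-I
calibration of the repeated-measures ANOVA — chosen so the full suite
documents every property while remaining quick to run on a laptop. The
acceptance script reports the ray-bundle cardinality (3482 at 60/60) and the
central-subregion volume fraction (20% within a one-voxel shell) recomputed
from scratch.

## Known limitations

* Sulcus detection assumes a single dominant trough; bicompartmental disease
  with severe flattening could defeat the interior-minimum criterion (the
  mid-y fallback is then used and warned about).
* The ray-tracing reach (radius + step × iterations ≈ 20 mm) must cover the
  distance from each fitted sphere center to its cartilage; strongly flattened
  femora fall back to centroid-offset spheres.
* Surface meshes are voxel-resolution height fields; no subvoxel surface
  reconstruction (e.g. marching cubes) or smoothing is attempted, matching
  the measurement model but limiting accuracy to the voxel scale.
* Medial/lateral naming is a user-supplied convention, not detected from
  anatomy.
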