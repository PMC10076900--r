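# cartthick

Automatic cartilage thickness measurement from segmented 3D knee MRI, with a
systematic comparison of five measurement methods.

After a knee MRI has been segmented into femoral and tibial cartilage, the
per-region mean thickness is the standard quantitative readout for
osteoarthritis studies — yet the number you get depends on *how* you measure.
`cartthick` implements five established measurement strategies on integer
label volumes:

* **3D-MN** — mesh normals: Delaunay-triangulated distal surface, per-vertex
  normals traced to the proximal surface mesh;
* **3D-NN** — nearest neighbors: kd-tree distance from every distal surface
  voxel to its closest proximal surface voxel;
* **3D-RT** — ray tracing: 3482 rays per origin sphere (two tibial, six
  femoral spheres), entry/exit chord lengths through the cartilage;
* **2D-CN** — centerline normals: per sagittal slice, normals to a cubic
  centerline fit, marched to the cartilage outline;
* **2D-SN** — surface normals: per slice, normals to the distal cubic outline
  fit, intersected exactly with the proximal cubic.

Around the methods it provides the standardized femorotibial parcellation
(medial/lateral splits, the 20%-volume central tibial cylinder with ±45°
quadrants, femoral anterior/central/posterior bands with central thirds — 4
regions, 20 subregions), MetaImage/NIfTI I/O, analytic phantoms with known
ground-truth thickness, and the full inter-method agreement toolkit: 5-SD
outlier screening, repeated-measures ANOVA with Tukey–Kramer post hoc tests
(family-wise α = 0.01), Bland–Altman limits of agreement, and Lin's
concordance correlation coefficient,

```
CCC = 2·cov(a,b) / (var(a) + var(b) + (mean(a) − mean(b))²).
```

Everything is tidyverse-native: thickness samples, summaries, and agreement
tables are tibbles; fitted reports support `tidy()`, `glance()`, and
`autoplot()`.

## Worked example

A composite knee phantom — two tibial plates of 2.5 mm (medial) and 1.5 mm
(lateral) true thickness plus a curved femoral shell of nominally 2 mm with a
trochlear-sulcus trough — run through all five methods:

```r
library(cartthick)
library(dplyr)

ph <- make_knee_phantom()
samples <- measure_thickness(ph, knee_id = "phantom-01")
summarize_thickness(samples) |>
  filter(level == "region") |>
  tidyr::pivot_wider(id_cols = name, names_from = method,
                     values_from = mean_thickness) |>
  mutate(across(where(is.numeric), ~round(.x, 2)))
#> # A tibble: 4 × 6
#>   name  `2D-CN` `2D-SN` `3D-MN` `3D-NN` `3D-RT`
#>   <chr>   <dbl>   <dbl>   <dbl>   <dbl>   <dbl>
#> 1 LF       1.9     1.64    1.66    1.55    2
#> 2 LT       1.76    1.44    1.44    1.44    2.02
#> 3 MF       1.87    1.61    1.63    1.52    1.97
#> 4 MT       2.48    2.16    2.16    2.16    2.76
```

The pattern these numbers show is the methodological story. On the flat
tibial plates, the three surface-to-surface methods (3D-MN, 3D-NN, 2D-SN)
agree exactly — they measure between surface-voxel centers, i.e.
`(layers − 1) × 0.36 mm`, hence 2.16 mm for the 2.5 mm medial plate and
1.44 mm for the 1.5 mm lateral one. 2D-CN reads ~0.3 mm higher because its
marching endpoints reach the outermost pixels rather than their centers.
3D-RT is the systematic overestimator: its chords cross the full voxelized
slab (and obliquely, at that), giving the largest values everywhere. 3D-NN is
never above 3D-MN — it is the lower bound by construction. On the curved
femur the same ordering holds with the curvature-induced spread.

Measurement counts per bone and method (3D-RT contributes far fewer samples
than rays fired):

```r
count_measurements(samples)
#> # A tibble: 10 × 3
#>    method structure n_measurements
#>    <chr>  <chr>              <int>
#>  1 2D-CN  femur               6503
#>  2 2D-CN  tibia               4032
#>  3 2D-SN  femur               6565
#>  4 2D-SN  tibia               4032
#>  5 3D-MN  femur               6500
#>  6 3D-MN  tibia               4032
#>  7 3D-NN  femur               6565
#>  8 3D-NN  tibia               4032
#>  9 3D-RT  femur               2697
#> 10 3D-RT  tibia               2072
```

For a cohort, `summarize_thickness()` output from several knees feeds
`compare_methods()`, which screens outlier knees (any subregional mean more
than 5 pooled SDs out removes the whole knee), then runs the
repeated-measures ANOVA, Tukey–Kramer, Bland–Altman, and CCC per (sub)region;
`tidy()` returns the pairwise table and `autoplot()` draws bias with limits
of agreement colored by CCC.

A command-line front end (`inst/cli/cartthick`) wraps the same functions as
`phantom`, `measure`, and `compare` subcommands with distinct exit codes for
configuration, data, and computation errors.

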