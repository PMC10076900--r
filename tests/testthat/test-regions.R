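test_that("tibial medial/lateral split partitions at the mid-y of the occupied range", {
  ph <- make_slab_phantom(2, extent = c(10, 20))
  pts <- extract_structure_points(ph$volume, "tibial cartilage")
  plates <- split_tibia_plates(pts)
  expect_identical(nrow(plates$MT) + nrow(plates$LT), nrow(pts))
  # brute-force split at the midpoint of the occupied y-range
  y_split <- (min(pts$y) + max(pts$y)) / 2
  expect_identical(nrow(plates$MT), sum(pts$y <= y_split))
  # symmetric phantom: equal plates up to the boundary row
  expect_lt(abs(nrow(plates$MT) - nrow(plates$LT)) / nrow(pts), 0.05)
  # medial_side convention flips the names, not the split
  flipped <- split_tibia_plates(pts, medial_side = "high-y")
  expect_identical(flipped$LT, plates$MT)
})

test_that("a single-sided block makes the tibial split fail loudly", {
  pts <- voxel_points(0:9, rep(3L, 10), 0:9, c(0.36, 0.7, 0.36))
  expect_error(split_tibia_plates(pts),
               class = "cartthick_empty_structure_error")
})

test_that("the central tibial cylinder holds 20% of plate voxels, quadrants match a brute-force oracle", {
  ph <- make_slab_phantom(2, extent = c(30, 24))
  pts <- extract_structure_points(ph$volume, "tibial cartilage")
  y_split <- max(pts$y) + 5   # midline beyond the plate: internal faces +y
  part <- partition_tibial_plate(pts, "MT", y_split)
  frac <- mean(part$subregion == "cMT")
  # one-voxel-shell tolerance around the cylinder radius
  ctr <- attr(part, "cylinder_center")
  r <- attr(part, "cylinder_radius")
  d <- sqrt((pts$x - ctr[1])^2 + (pts$y - ctr[2])^2)
  shell <- mean(d > r & d <= r + max(ph$volume$spacing[1:2]))
  expect_gte(frac, 0.20 - shell)
  expect_lte(frac, 0.20 + shell)
  # quadrants equal brute-force angular classification
  outer <- part$subregion != "cMT"
  expected <- paste0(quadrant_bruteforce(pts$x[outer], pts$y[outer],
                                         ctr[1], ctr[2], 1), "MT")
  expect_identical(part$subregion[outer], expected)
})

test_that("degenerate plates are handled: all voxels at one x extreme, too-small plates", {
  sp <- c(0.36, 0.7, 0.36)
  pts <- voxel_points(rep(0L, 40), rep(seq_len(10), 4), rep(1:4, each = 10), sp)
  part <- partition_tibial_plate(pts, "LT", y_split = 100)
  outer <- !part$subregion %in% "cLT"
  # a vertical line of voxels: non-central voxels fall in the i/e sectors
  expect_true(all(part$subregion[outer] %in% c("iLT", "eLT")))
  expect_error(partition_tibial_plate(pts[1:3, ], "LT", 0),
               class = "cartthick_too_small_error")
})

test_that("tibial central fraction approaches 20% as the grid is refined", {
  fracs <- vapply(c(1, 2), function(f) {
    ph <- make_slab_phantom(2, extent = c(24, 18),
                            spacing = c(0.36, 0.7, 0.36) / f)
    pts <- extract_structure_points(ph$volume, "tibial cartilage")
    part <- partition_tibial_plate(pts, "MT", y_split = 100)
    mean(part$subregion == "cMT")
  }, numeric(1))
  expect_lte(abs(fracs[2] - 0.20), abs(fracs[1] - 0.20) + 1e-12)
  expect_lt(abs(fracs[2] - 0.20), 0.01)
})

test_that("femoral split recovers a planted trochlear sulcus and falls back on flat profiles", {
  ph <- small_knee_phantom(sulcus_frac = 0.45)
  fem <- extract_structure_points(ph$volume, "femoral cartilage")
  plates <- split_femur_plates(fem)
  expect_lt(abs(attr(plates, "sulcus_y") - ph$params$sulcus_y),
            ph$volume$spacing[2] + 1e-9)
  expect_false(attr(plates, "sulcus_fallback"))
  # plate share follows the trough position (brute-force count at the split)
  share <- nrow(plates$MF) / nrow(fem)
  expect_lt(abs(share - 0.45), 0.06)
  # a flat uniform structure has no interior minimum: mid-y fallback, warned
  flat <- make_slab_phantom(2, extent = c(12, 10),
                            structure = "femoral cartilage")
  fpts <- extract_structure_points(flat$volume, "femoral cartilage")
  expect_warning(fb <- split_femur_plates(fpts), "falling back")
  expect_lt(abs(attr(fb, "sulcus_y") - (min(fpts$y) + max(fpts$y)) / 2), 0.71)
  expect_true(attr(fb, "sulcus_fallback"))
})

test_that("femoral plates split into a/c/p by the vis-a-vis rule with equal-width central thirds", {
  sp <- c(0.36, 0.7, 0.36)
  # synthetic femoral slab spanning x indices 0..59, y indices 0..29
  grid <- expand.grid(i = 0:59, j = 0:29)
  fem <- voxel_points(grid$i, grid$j, rep(5L, nrow(grid)), sp)
  # tibial central reference occupying x indices 20..39
  tib_c <- voxel_points(20:39, rep(0L, 20), rep(0L, 20), sp)
  part <- partition_femoral_plate(fem, "LF", tib_c, y_split = 100)
  a <- 20 * sp[1]; b <- 39 * sp[1]
  expect_true(all(part$subregion[part$x < a - 1e-9] == "aLF"))
  expect_true(all(part$subregion[part$x > b + 1e-9] == "pLF"))
  cen <- part[part$x >= a & part$x <= b, ]
  expect_setequal(unique(cen$subregion), c("icLF", "ccLF", "ecLF"))
  # equal-width thirds: brute-force classification by y
  y0 <- min(cen$y); w <- (max(cen$y) - y0) / 3
  third <- pmin(2, floor((cen$y - y0) / w))
  # midline above the plate: internal = highest-y third
  expected <- c("ecLF", "ccLF", "icLF")[third + 1]
  expect_identical(cen$subregion, expected)
  # all-anterior degenerate case: central and posterior empty
  far <- voxel_points(200:220, rep(0L, 21), rep(0L, 21), sp)
  p2 <- partition_femoral_plate(fem, "LF", far, y_split = 100)
  expect_true(all(p2$subregion == "aLF"))
  expect_error(partition_femoral_plate(fem, "LF", tib_c[0, ], 0),
               class = "cartthick_config_error")
})

test_that("full parcellation yields a partition into 20 subregions and is translation invariant", {
  ph <- small_knee_phantom()
  parc <- parcellate_knee(ph)
  vox <- parc$voxels
  expect_identical(nrow(vox), sum(ph$volume$grid %in% c(2L, 4L)))
  expect_identical(anyDuplicated(vox[, c("structure", "i", "j", "k")]), 0L)
  expect_setequal(unique(vox$subregion), subregion_table()$subregion)
  expect_false(any(is.na(vox$subregion)))
  # translating the whole volume leaves per-subregion counts unchanged
  g <- ph$volume$grid
  g2 <- array(0L, dim(g) + c(3L, 2L, 4L))
  g2[3 + seq_len(dim(g)[1]), 2 + seq_len(dim(g)[2]), 4 + seq_len(dim(g)[3])] <- g
  parc2 <- parcellate_knee(label_volume(g2, ph$volume$spacing))
  c1 <- subregion_counts(parc)
  c2 <- subregion_counts(parc2)
  expect_identical(c1$n_voxels[order(c1$subregion)],
                   c2$n_voxels[order(c2$subregion)])
})

test_that("sample assignment matches a linear-scan nearest-voxel search", {
  ph <- small_knee_phantom()
  parc <- parcellate_knee(ph)
  vox <- parc$voxels
  # voxel centers map to their own label
  pick <- vox[as.integer(seq(1, nrow(vox), length.out = 25)), ]
  expect_identical(as.character(assign_samples(parc, pick[, c("x", "y", "z")])),
                   pick$subregion)
  # random nearby points match the brute-force oracle
  set.seed(42)
  idx <- sample(nrow(vox), 100)
  q <- cbind(vox$x[idx] + runif(100, -0.3, 0.3),
             vox$y[idx] + runif(100, -0.3, 0.3),
             vox$z[idx] + runif(100, -0.3, 0.3))
  got <- as.character(assign_samples(parc, q))
  nearest <- vapply(seq_len(100), function(ii) {
    d2 <- (vox$x - q[ii, 1])^2 + (vox$y - q[ii, 2])^2 + (vox$z - q[ii, 3])^2
    vox$subregion[which.min(d2)]
  }, character(1))
  # ties at equal distance are legitimate disagreements; require distance match
  d_got <- vapply(seq_len(100), function(ii) {
    sel <- vox$subregion == got[ii]
    min((vox$x[sel] - q[ii, 1])^2 + (vox$y[sel] - q[ii, 2])^2 +
          (vox$z[sel] - q[ii, 3])^2)
  }, numeric(1))
  d_best <- vapply(seq_len(100), function(ii) {
    min((vox$x - q[ii, 1])^2 + (vox$y - q[ii, 2])^2 + (vox$z - q[ii, 3])^2)
  }, numeric(1))
  expect_equal(d_got, d_best, tolerance = 1e-10)
  expect_identical(sum(got != nearest & abs(d_got - d_best) > 1e-10), 0L)
  # far-away points stay unassigned and are counted
  far <- assign_samples(parc, rbind(c(-50, -50, -50)))
  expect_true(is.na(far[1]))
  expect_identical(attr(far, "n_unassigned"), 1L)
})

test_that("parcellation exports as a label volume with stable subregion codes", {
  ph <- small_knee_phantom()
  parc <- parcellate_knee(ph)
  sv <- subregion_volume(parc)
  expect_identical(dim(sv$grid), dim(ph$volume$grid))
  counts <- subregion_counts(parc)
  tab <- subregion_table()
  for (s in c("cMT", "icLF", "pLT")) {
    expect_identical(sum(sv$grid == tab$code[tab$subregion == s]),
                     counts$n_voxels[counts$subregion == s])
  }
})
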