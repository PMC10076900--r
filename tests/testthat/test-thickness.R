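sp <- c(0.36, 0.7, 0.36)

flat_surface <- function(k, ni = 10, nj = 8) {
  g <- expand.grid(i = seq_len(ni) - 1L, j = seq_len(nj) - 1L)
  s <- voxel_points(g$i, g$j, rep(as.integer(k), nrow(g)), sp)
  s$ox <- s$x; s$oy <- s$y; s$oz <- s$z
  s
}

test_that("3D-MN: parallel flat meshes give exactly the plane separation", {
  distal <- flat_surface(10)
  proximal <- flat_surface(4)
  mn <- thickness_mesh_normals(build_mesh(distal), build_mesh(proximal))
  expect_equal(mn$thickness, rep(6 * 0.36, nrow(mn)), tolerance = 1e-9)
  expect_identical(nrow(mn), nrow(distal))
})

test_that("3D-MN recovers slab and shell thickness within one voxel", {
  ph <- make_slab_phantom(2, extent = c(20, 15))
  pts <- extract_structure_points(ph$volume, "tibial cartilage")
  pair <- extract_surfaces_tibia(pts)
  mn <- thickness_mesh_normals(build_mesh(pair$distal), build_mesh(pair$proximal))
  # slab surfaces are aligned on voxel-center planes: exactly (layers-1)*dz
  layers <- floor(2 / 0.36) + 1
  expect_equal(mean(mn$thickness), (layers - 1) * 0.36, tolerance = 1e-9)
  expect_lt(abs(mean(mn$thickness) - 2), 0.36)
  # concentric shell
  sh <- make_shell_phantom(20, 2, theta_max_deg = 50)
  spts <- extract_structure_points(sh$volume, "femoral cartilage")
  spair <- extract_surfaces_femur(spts, rep(FALSE, nrow(spts)))$anterior_central
  smn <- thickness_mesh_normals(build_mesh(spair$distal),
                                build_mesh(spair$proximal))
  expect_lt(abs(mean(smn$thickness) - 2), 0.36)
})

test_that("3D-NN matches a brute-force all-pairs minimum and trivial limits", {
  # identical surfaces: all distances zero
  s <- flat_surface(5)
  pair <- cartthick:::surface_pair(s, s, "tibia", spacing = sp)
  nn <- thickness_nearest_neighbors(pair)
  expect_true(all(nn$thickness == 0))
  # parallel voxel planes at separation t
  pair <- cartthick:::surface_pair(flat_surface(10), flat_surface(4), "tibia",
                                   spacing = sp)
  nn <- thickness_nearest_neighbors(pair)
  expect_equal(nn$thickness, rep(6 * 0.36, nrow(nn)), tolerance = 1e-12)
  # 500 random points against the O(n^2) oracle
  set.seed(11)
  a <- matrix(runif(1500, 0, 20), ncol = 3)
  b <- matrix(runif(1500, 0, 20), ncol = 3)
  mk <- function(m) {
    s <- tibble::tibble(i = 0L, j = 0L, k = 0L, x = m[, 1], y = m[, 2],
                        z = m[, 3], ox = m[, 1], oy = m[, 2], oz = m[, 3])
    s
  }
  pair <- cartthick:::surface_pair(mk(a), mk(b), "tibia", spacing = sp)
  nn <- thickness_nearest_neighbors(pair, max_thickness = Inf)
  expect_equal(nn$thickness, nn_bruteforce(a, b), tolerance = 1e-10)
})

test_that("the UV-sphere ray bundle has the specified cardinality and symmetry", {
  cfg <- ray_sphere_config(list(LT = c(0, 0, 0)))
  rays <- sphere_ray_bundle(cfg)
  expect_identical(nrow(rays), 2L + 60L * (60L - 2L))  # 3482
  small <- ray_sphere_config(list(LT = c(0, 0, 0)), n_polar = 3, n_azimuthal = 3)
  expect_identical(nrow(sphere_ray_bundle(small)), 5L)
  d <- as.matrix(rays[, c("dx", "dy", "dz")])
  expect_equal(sqrt(rowSums(d^2)), rep(1, nrow(d)), tolerance = 1e-12)
  expect_equal(colMeans(d), c(dx = 0, dy = 0, dz = 0), tolerance = 1e-3)
  expect_error(ray_sphere_config(list(LT = c(0, 0, 0)), n_polar = 2),
               class = "cartthick_config_error")
})

test_that("3D-RT chords follow the oblique closed form and the shell limit", {
  ph <- make_slab_phantom(2, extent = c(30, 20))
  vol <- ph$volume
  pts <- extract_structure_points(vol, "tibial cartilage")
  base <- c(mean(range(pts$x)), mean(range(pts$y)), max(pts$z) + 10)
  cfg <- ray_sphere_config(list(LT = base), step = 0.18)
  rt <- thickness_ray_tracing(vol, cfg)
  # voxelized slab occupies 6 z-layers = 2.16 mm of voxel extent
  extent_z <- 6 * 0.36
  ang <- acos(abs(rt$z - base[3]) /
                sqrt((rt$x - base[1])^2 + (rt$y - base[2])^2 +
                       (rt$z - base[3])^2))
  # perpendicular rays: chord = voxel extent, quantized by one marching step
  perp <- ang < 5 * pi / 180
  expect_true(any(perp))
  expect_true(all(abs(rt$thickness[perp] - extent_z) <= cfg$step + 1e-9))
  expect_lt(abs(mean(rt$thickness[perp]) - 2), 0.36)
  # oblique rays: chord = extent / cos(angle) up to step + staircase slop
  obl <- ang > 17 * pi / 180 & ang < 38 * pi / 180
  expect_true(all(abs(rt$thickness[obl] - extent_z / cos(ang[obl])) <= 0.2))
  # sphere at the center of a shell: radial rays recover the thickness
  sh <- make_shell_phantom(10, 2, theta_max_deg = 60)
  cfg2 <- ray_sphere_config(list(cLF = sh$center), step = 0.18)
  rt2 <- thickness_ray_tracing(sh$volume, cfg2)
  ctr <- sh$center
  rho <- sqrt((rt2$x - ctr[1])^2 + (rt2$y - ctr[2])^2)
  interior <- rho < 10 * sin(50 * pi / 180) & (rt2$z - ctr[3]) > 0
  v <- rt2$thickness[interior]
  expect_lt(abs(mean(v) - 2), 0.36)
  expect_gt(mean(abs(v - 2) <= 0.36), 0.85)
  expect_lt(nrow(rt2), nrow(sphere_ray_bundle(cfg2)))
})

test_that("ray-origin spheres: fitted center recovers a sphere, tibial centers sit bone-ward", {
  sh <- make_shell_phantom(12, 2, theta_max_deg = 55)
  pts <- extract_structure_points(sh$volume, "femoral cartilage")
  pair <- extract_surfaces_femur(pts, rep(FALSE, nrow(pts)))$anterior_central
  fit <- cartthick:::fit_sphere(as.matrix(pair$distal[, c("x", "y", "z")]))
  expect_lt(sqrt(sum((fit$center - sh$center)^2)), max(sp))
  expect_lt(abs(fit$radius - 14), 0.5)   # distal = outer surface
  fx <- knee_measurement_fixture()
  parc <- parcellate_knee(fx$phantom)
  cfg <- place_ray_spheres(parc)
  expect_identical(names(cfg$centers),
                   c("LT", "MT", "aLF", "aMF", "cLF", "cMF", "pLF", "pMF"))
  expect_identical(length(cfg$centers), 8L)
  # flat tibial plate: sphere directly below (larger z) the plate centroid
  mt <- parc$voxels[parc$voxels$region == "MT", ]
  expect_equal(cfg$centers$MT[1:2], c(mean(mt$x), mean(mt$y)), tolerance = 1e-9)
  expect_equal(cfg$centers$MT[3], mean(mt$z) + 10, tolerance = 1e-9)
})

test_that("cubic slice fits recover exact polynomials and reject degenerate slices", {
  x <- seq(0, 10, by = 0.25)
  cf <- c(1.5, -0.3, 0.02, 0.004)
  z <- cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3
  fit <- fit_slice_polynomial(x, z, "centerline")
  expect_equal(fit$coefficients, cf, tolerance = 1e-8)
  expect_equal(predict(fit, 3.7), sum(cf * 3.7^(0:3)), tolerance = 1e-8)
  # horizontal band: centerline is the constant mid-height
  px <- expand.grid(x = seq(0, 5, by = 0.36), z = c(1, 1.36, 1.72))
  fit <- fit_slice_polynomial(px$x, px$z, "centerline")
  expect_equal(predict(fit, 2.5), 1.36, tolerance = 1e-8)
  # noise inflation stays bounded (regression oracle)
  set.seed(5)
  xn <- seq(0, 10, length.out = 100)
  zn <- 2 + 0.1 * xn - 0.01 * xn^3 + rnorm(100, 0, 0.1)
  fitn <- fit_slice_polynomial(xn, zn, "distal")
  rms <- sqrt(mean((zn - predict(fitn, xn))^2))
  expect_lt(rms, 0.1 * 1.2)
  expect_condition(fit_slice_polynomial(c(1, 2, 3, 4), c(1, 1, 1, 1)),
                   class = "cartthick_slice_skip")
})

test_that("2D-CN measures bands by normal distance, including tilted and curved bands", {
  # horizontal band of thickness 2 mm (6 pixel rows)
  g <- expand.grid(i = 0:40, j = 0:2, k = 10:15)
  band <- voxel_points(g$i, g$j, g$k, sp)
  cn <- thickness_centerline_2d(band)
  expect_true(all(abs(cn$thickness - 2) <= 0.36))
  # 30-degree tilted band: normal distance stays t (not t / cos 30)
  th <- 30 * pi / 180
  g <- expand.grid(i = 0:80, k = 0:60)
  d <- (g$k * sp[3] - g$i * sp[1] * tan(th)) * cos(th)
  sel <- d >= 0 & d <= 2
  tilted <- voxel_points(g$i[sel], rep(0L, sum(sel)), g$k[sel], sp)
  cn <- thickness_centerline_2d(tilted)
  mid <- cn[cn$x > 5 & cn$x < 22, ]   # away from the cut ends
  expect_lt(abs(mean(mid$thickness) - 2), 0.36)
  expect_lt(mean(mid$thickness), 2 / cos(th) - 0.15)
  # annular band of radial thickness 2
  g <- expand.grid(i = 0:120, k = 0:60)
  r <- sqrt((g$i * sp[1] - 21.6)^2 + (g$k * sp[3])^2)
  sel <- r >= 14 & r <= 16 & g$k * sp[3] > 3
  ann <- voxel_points(g$i[sel], rep(0L, sum(sel)), g$k[sel], sp)
  cn <- thickness_centerline_2d(ann)
  expect_lt(abs(mean(cn$thickness) - 2), 0.4)
})

test_that("2D-SN intersects distal normals with the proximal cubic exactly", {
  # two parallel horizontal pixel lines: samples equal the separation
  two <- voxel_points(c(0:30, 0:30), rep(0L, 62),
                      c(rep(12L, 31), rep(2L, 31)), sp)
  sn <- thickness_surface_normals_2d(two)
  expect_equal(sn$thickness, rep(10 * 0.36, nrow(sn)), tolerance = 1e-9)
  # flat distal over a 45-degree proximal line: closed-form gap along the
  # (vertical) distal normal
  i <- 0:30
  prox_k <- i            # z = x exactly on pixel centers (sx = sz)
  dist_k <- rep(40L, 31)
  both <- voxel_points(c(i, i), rep(0L, 62), c(dist_k, prox_k), sp)
  sn <- thickness_surface_normals_2d(both, max_thickness = 20)
  expected <- 40 * 0.36 - sn$x   # fd - fp at the origin x
  expect_equal(sn$thickness, expected, tolerance = 1e-6)
  # concentric arc outlines of radial separation 2, one pixel per column and
  # arc so each cubic fits a clean outline
  i <- 33:87
  dx <- i * sp[1] - 21.6
  k_outer <- as.integer(round(sqrt(16^2 - dx^2) / sp[3]))
  k_inner <- as.integer(round(sqrt(14^2 - dx^2) / sp[3]))
  arcs <- voxel_points(c(i, i), rep(0L, 2 * length(i)),
                       c(k_outer, k_inner), sp)
  sn <- thickness_surface_normals_2d(arcs)
  inner <- sn[abs(sn$x - 21.6) < 8, ]
  expect_lt(abs(mean(inner$thickness) - 2), 0.4)
})

test_that("thickness invariants hold on the composite knee phantom", {
  fx <- knee_measurement_fixture()
  s <- fx$samples
  expect_true(all(s$thickness >= 0))
  expect_true(all(s$thickness <= 15))
  expect_setequal(unique(s$method), thickness_methods())
  # per-column methods produce comparable sample counts; ray tracing fewer
  counts <- dplyr::count(tibble::as_tibble(s), method)
  n_rt <- counts$n[counts$method == "3D-RT"]
  n_cols <- counts$n[counts$method == "3D-NN"]
  expect_lt(n_rt, 8 * 3482)
  expect_lt(n_rt, n_cols)
  per_col <- counts$n[counts$method %in% c("3D-MN", "3D-NN", "2D-CN", "2D-SN")]
  expect_lt(diff(range(per_col)) / max(per_col), 0.1)
  # subregional means approximate the constructed plate thicknesses
  summ <- summarize_thickness(s)
  mt <- summ[summ$level == "region" & summ$name == "MT" &
               summ$method == "3D-MN", ]
  lt <- summ[summ$level == "region" & summ$name == "LT" &
               summ$method == "3D-MN", ]
  expect_lt(abs(mt$mean_thickness - 2.5), 0.4)
  expect_lt(abs(lt$mean_thickness - 1.5), 0.4)
})

test_that("3D-NN never exceeds 3D-MN at matched origins on a slab", {
  ph <- make_slab_phantom(2, extent = c(20, 15))
  pts <- extract_structure_points(ph$volume, "tibial cartilage")
  pair <- extract_surfaces_tibia(pts)
  mn <- thickness_mesh_normals(build_mesh(pair$distal), build_mesh(pair$proximal))
  nn <- thickness_nearest_neighbors(pair)
  joined <- dplyr::inner_join(
    tibble::as_tibble(mn)[, c("x", "y", "z", "thickness")],
    tibble::as_tibble(nn)[, c("x", "y", "z", "thickness")],
    by = c("x", "y", "z"), suffix = c("_mn", "_nn"))
  expect_identical(nrow(joined), nrow(mn))
  expect_true(all(joined$thickness_nn <= joined$thickness_mn + 1e-9))
})
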