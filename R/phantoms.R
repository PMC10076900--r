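#' Flat or tilted slab phantom with known thickness
#'
#' Voxelizes a plate of constant normal thickness `t` into a label volume, the
#' simplest stand-in for a tibial cartilage plate. The slab normal lies in the
#' x-z plane, tilted by `tilt_deg` about the y-axis (0 = surfaces are
#' constant-z planes). A voxel is included when its center lies inside the
#' continuous solid. For the untilted slab the lower surface is aligned with a
#' voxel-center plane, so the voxelized plate has `floor(t / dz) + 1` voxel
#' layers.
#'
#' @param thickness Slab thickness in mm, measured along the slab normal.
#'   Must be at least `2 * max(spacing)` to be resolvable.
#' @param extent Length-2, in-plane extent (mm) along x and y.
#' @param spacing Voxel spacing (mm); default matches the source MRI protocol
#'   (0.36 mm in-plane sagittal, 0.7 mm through-plane mediolateral).
#' @param tilt_deg Tilt of the slab normal about the y-axis, degrees.
#' @param structure Structure name used for the slab label.
#' @param roughness_sd Optional Gaussian jitter (mm, per column) on the distal
#'   surface; 0 disables it.
#' @param seed Seed used only when `roughness_sd > 0`.
#' @return A `cart_phantom`: list with `volume` ([label_volume()]), `truth`
#'   (function of (x, y) returning the analytic thickness), `thickness`, and
#'   geometry parameters.
#' @export
#' @examples
#' ph <- make_slab_phantom(2, extent = c(10, 8))
#' sum(ph$volume$grid != 0)
make_slab_phantom <- function(thickness, extent = c(40, 30),
                              spacing = c(0.36, 0.7, 0.36), tilt_deg = 0,
                              structure = "tibial cartilage",
                              roughness_sd = 0, seed = 1L) {
  spacing <- assert_spacing(spacing)
  if (thickness < 2 * max(spacing)) {
    stop_cartthick("slab thickness below the resolvable limit (2 * max spacing).",
                   "cartthick_config_error")
  }
  th <- tilt_deg * pi / 180
  pad <- 2
  # extra z room for the tilt-induced height variation across the footprint
  zspan <- thickness / cos(th) + extent[1] * abs(tan(th))
  nx <- ceiling((extent[1] + 2 * pad) / spacing[1]) + 1L
  ny <- ceiling((extent[2] + 2 * pad) / spacing[2]) + 1L
  nz <- ceiling((zspan + 2 * pad) / spacing[3]) + 1L
  xc <- (seq_len(nx) - 1L) * spacing[1]
  yc <- (seq_len(ny) - 1L) * spacing[2]
  zc <- (seq_len(nz) - 1L) * spacing[3]
  x0 <- pad
  # anchor the lower boundary plane on a voxel-center z level
  z0 <- round(pad / spacing[3]) * spacing[3] + max(0, (extent[1] - x0) * tan(th))
  n_hat <- c(sin(th), cos(th))      # slab normal in the x-z plane
  xmask <- xc >= x0 & xc <= x0 + extent[1]
  ymask <- yc >= pad & yc <= pad + extent[2]
  d2d <- outer((xc - x0) * n_hat[1], (zc - z0) * n_hat[2], "+")
  jitter <- 0
  if (roughness_sd > 0) {
    set.seed(seed)
    # per-x-column distal surface jitter, constant along z
    jitter <- matrix(stats::rnorm(nx, sd = roughness_sd), nx, nz)
  }
  occ2d <- d2d >= -1e-9 & d2d <= thickness + jitter + 1e-9
  occ2d[!xmask, ] <- FALSE
  grid <- array(0L, c(nx, ny, nz))
  lab <- default_label_map()[[structure]]
  occ_idx <- which(occ2d, arr.ind = TRUE)
  if (nrow(occ_idx) > 0) {
    for (j in which(ymask)) grid[cbind(occ_idx[, 1], j, occ_idx[, 2])] <- lab
  }
  ph <- list(volume = label_volume(grid, spacing),
             truth = function(x, y) rep(thickness, length(x)),
             thickness = thickness, tilt_deg = tilt_deg, extent = extent,
             structure = structure, geometry = "slab",
             origin = c(x0, pad, z0))
  class(ph) <- "cart_phantom"
  ph
}

#' Spherical-shell phantom with known radial thickness
#'
#' Voxelizes a spherical shell sector between radii `radius` and
#' `radius + thickness`, opening toward larger z (head-to-feet axis), limited
#' laterally to the cylinder of radius `radius * sin(theta_max_deg)` about
#' the vertical axis. This emulates the curved femoral cartilage; the
#' analytic thickness is `thickness` everywhere, measured radially. The
#' lateral boundary is deliberately cut parallel to the z-axis: a vertical
#' cut face is invisible to column-wise surface extraction, so the phantom
#' exposes no artificial face that could masquerade as a distal or proximal
#' cartilage surface (a radial cone cut would, and would corrupt the analytic
#' truth near the rim).
#'
#' @param radius Inner radius (mm); must exceed `thickness`.
#' @param thickness Radial shell thickness (mm).
#' @param theta_max_deg Half-opening angle of the cap, degrees (0, 90].
#' @param spacing Voxel spacing (mm).
#' @param structure Structure name for the shell label.
#' @return A `cart_phantom` with `center` (physical mm, may have negative
#'   components) and `radius` recorded for cross-checks.
#' @export
make_shell_phantom <- function(radius, thickness, theta_max_deg = 60,
                               spacing = c(0.36, 0.7, 0.36),
                               structure = "femoral cartilage") {
  spacing <- assert_spacing(spacing)
  if (radius <= thickness) {
    stop_cartthick("shell radius must exceed its thickness.",
                   "cartthick_config_error")
  }
  if (theta_max_deg <= 0 || theta_max_deg > 90) {
    stop_cartthick("theta_max_deg must lie in (0, 90].", "cartthick_config_error")
  }
  tm <- theta_max_deg * pi / 180
  r_out <- radius + thickness
  rho_max <- radius * sin(tm)
  pad <- 1.5
  half_xy <- rho_max + pad
  cx <- half_xy
  cy <- half_xy
  # place the shell band just above z = 0; the center itself may fall outside
  cz <- pad - radius * cos(tm)
  nx <- ceiling(2 * half_xy / spacing[1]) + 1L
  ny <- ceiling(2 * half_xy / spacing[2]) + 1L
  nz <- ceiling((cz + r_out + pad) / spacing[3]) + 1L
  xc <- (seq_len(nx) - 1L) * spacing[1]
  yc <- (seq_len(ny) - 1L) * spacing[2]
  zc <- (seq_len(nz) - 1L) * spacing[3]
  rho2 <- outer((xc - cx)^2, (yc - cy)^2, "+")
  grid <- array(0L, c(nx, ny, nz))
  lab <- default_label_map()[[structure]]
  for (k in seq_len(nz)) {
    dz <- zc[k] - cz
    if (dz <= 0) next
    r2 <- rho2 + dz^2
    occ <- r2 >= radius^2 & r2 <= r_out^2 & rho2 <= rho_max^2
    if (any(occ)) grid[, , k][occ] <- lab
  }
  if (!any(grid != 0)) {
    stop_cartthick("degenerate shell sector: no voxels.", "cartthick_config_error")
  }
  ph <- list(volume = label_volume(grid, spacing),
             truth = function(x, y) rep(thickness, length(x)),
             thickness = thickness, radius = radius,
             center = c(cx, cy, cz), theta_max_deg = theta_max_deg,
             structure = structure, geometry = "shell")
  class(ph) <- "cart_phantom"
  ph
}

#' Composite knee phantom: two tibial plates plus a curved femoral shell
#'
#' Builds one label volume holding two flat tibia-like plates with distinct
#' constant thicknesses and a femur-like shell above them (a half-cylindrical
#' twin-condyle shell whose thickness dips at a trochlear-sulcus trough at a
#' known mediolateral position). Designed so that the full parcellation,
#' surface, and thickness pipeline can run end-to-end with analytically known
#' per-structure thickness.
#'
#' The sulcus trough position is `sulcus_frac` of the occupied femoral y-range,
#' so the mediolateral femoral split can be validated against construction.
#'
#' @param spacing Voxel spacing (mm).
#' @param tibial_thickness Named thickness (mm) for the `medial` and `lateral`
#'   plate.
#' @param femoral_radius Inner radius (mm) of the femoral shell; the default
#'   keeps the fitted ray-origin spheres within ray-marching reach of the
#'   cartilage at the default step length and iteration cap.
#' @param femoral_thickness Nominal femoral shell thickness (mm).
#' @param sulcus_frac Trough position as a fraction of the femoral y-extent.
#' @param sulcus_depth Fractional thickness reduction at the trough (0-1).
#' @param plate_extent Length-2, per-plate (x, y) extent in mm.
#' @param plate_gap Mediolateral gap between the plates (mm).
#' @param joint_space Synovial gap between femur and tibia (mm).
#' @param medial_side Which y side is medial: `"low-y"` (default) or `"high-y"`.
#' @return A `cart_phantom` whose `truth` element is a named list of
#'   per-structure analytic thickness functions of (x, y); `params` records
#'   construction coordinates (sulcus y, plate spans, shell center/radius).
#' @export
make_knee_phantom <- function(spacing = c(0.36, 0.7, 0.36),
                              tibial_thickness = c(medial = 2.5, lateral = 1.5),
                              femoral_radius = 14, femoral_thickness = 2,
                              sulcus_frac = 0.5, sulcus_depth = 0.5,
                              plate_extent = c(26, 20), plate_gap = 6,
                              joint_space = 2, medial_side = "low-y") {
  spacing <- assert_spacing(spacing)
  pad <- 1.5
  r_out <- femoral_radius + femoral_thickness
  # y layout: [pad][plate A][gap][plate B][pad]
  yA <- c(pad, pad + plate_extent[2])
  yB <- c(yA[2] + plate_gap, yA[2] + plate_gap + plate_extent[2])
  y_total <- yB[2] + pad
  x0 <- pad + r_out                      # shared anteroposterior center
  x_lo <- x0 - plate_extent[1] / 2
  x_hi <- x0 + plate_extent[1] / 2
  # z layout: femoral cylinder center z0 (top), plates below
  z0 <- pad
  z_plate <- (round((z0 + r_out + joint_space) / spacing[3]) + 1L) * spacing[3]
  t_max <- max(tibial_thickness)
  nx <- ceiling((x0 + r_out + pad) / spacing[1]) + 1L
  ny <- ceiling(y_total / spacing[2]) + 1L
  nz <- ceiling((z_plate + t_max + pad) / spacing[3]) + 1L
  xc <- (seq_len(nx) - 1L) * spacing[1]
  yc <- (seq_len(ny) - 1L) * spacing[2]
  zc <- (seq_len(nz) - 1L) * spacing[3]

  t_med <- tibial_thickness[["medial"]]
  t_lat <- tibial_thickness[["lateral"]]
  tA <- if (medial_side == "low-y") t_med else t_lat
  tB <- if (medial_side == "low-y") t_lat else t_med

  lm_ <- default_label_map()
  grid <- array(0L, c(nx, ny, nz))

  # tibial plates: top (proximal) surface anchored on a voxel-center z level
  xmask <- xc >= x_lo & xc <= x_hi
  for (plate in list(list(span = yA, t = tA), list(span = yB, t = tB))) {
    jm <- yc >= plate$span[1] & yc <= plate$span[2]
    km <- zc >= z_plate - 1e-9 & zc <= z_plate + plate$t + 1e-9
    grid[xmask, jm, km] <- lm_[["tibial cartilage"]]
  }

  # femoral shell: half-cylinder, axis along y at (x0, z0); thickness dips at
  # the sulcus trough
  y_f_lo <- yA[1]
  y_f_hi <- yB[2]
  sulcus_y <- y_f_lo + sulcus_frac * (y_f_hi - y_f_lo)
  sigma <- 1.5
  t_of_y <- function(y) {
    femoral_thickness * (1 - sulcus_depth * exp(-(y - sulcus_y)^2 / (2 * sigma^2)))
  }
  rho2 <- outer((xc - x0)^2, (zc - z0)^2, "+")   # nx x nz
  below <- outer(rep(TRUE, nx), zc >= z0)
  for (j in seq_len(ny)) {
    if (yc[j] < y_f_lo || yc[j] > y_f_hi) next
    r_in <- r_out - t_of_y(yc[j])
    occ <- rho2 >= r_in^2 & rho2 <= r_out^2 & below
    sl <- grid[, j, ]
    sl[occ] <- lm_[["femoral cartilage"]]
    grid[, j, ] <- sl
  }

  truth <- list(
    "tibial cartilage" = function(x, y) ifelse(y <= yA[2] + plate_gap / 2, tA, tB),
    "femoral cartilage" = function(x, y) t_of_y(y)
  )
  ph <- list(volume = label_volume(grid, spacing), truth = truth,
             params = list(sulcus_y = sulcus_y, plate_y = list(A = yA, B = yB),
                           plate_x = c(x_lo, x_hi), z_plate = z_plate,
                           shell_center = c(x0, z0), shell_radius = femoral_radius,
                           shell_outer_radius = r_out,
                           tibial_thickness = c(A = tA, B = tB),
                           femoral_thickness = femoral_thickness,
                           medial_side = medial_side),
             geometry = "knee_composite")
  class(ph) <- "cart_phantom"
  ph
}

#' @export
print.cart_phantom <- function(x, ...) {
  cat("<cart_phantom> geometry:", x$geometry, "\n")
  print(x$volume)
  invisible(x)
}
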