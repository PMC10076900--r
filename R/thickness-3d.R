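new_thickness_samples <- function(df, failures = NULL) {
  df <- tibble::as_tibble(df)
  attr(df, "failures") <- failures %||% c()
  class(df) <- c("thickness_samples", class(df))
  df
}

#' @export
print.thickness_samples <- function(x, ...) {
  NextMethod()
  f <- attr(x, "failures")
  if (length(f) > 0 && any(f > 0)) {
    cat("failed/skipped measurements:",
        paste(names(f), f, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

maybe_assign <- function(parc, origin) {
  if (is.null(parc)) rep(NA_character_, nrow(origin)) else
    as.character(assign_samples(parc, origin))
}

#' 3D mesh-normal thickness (3D-MN)
#'
#' Casts the surface normal of every distal mesh vertex toward the proximal
#' mesh and measures the distance from the vertex to the first intersection.
#' Vertices whose normal misses the proximal mesh, isolated vertices (zero
#' normal), and values above `max_thickness` yield no sample and are counted.
#'
#' @param distal_mesh,proximal_mesh Meshes from [build_mesh()], in the same
#'   working frame, with normals oriented distal to proximal (enforced here).
#' @param parc Optional [parcellate_knee()] result for subregion assignment.
#' @param max_thickness Maximum plausible thickness (mm); larger measurements
#'   are discarded and counted.
#' @return A `thickness_samples` tibble: `x, y, z` (origin, original frame,
#'   mm), `thickness` (mm), `subregion`; attribute `failures`.
#' @export
thickness_mesh_normals <- function(distal_mesh, proximal_mesh, parc = NULL,
                                   max_thickness = 15) {
  stopifnot(inherits(distal_mesh, "cart_mesh"), inherits(proximal_mesh, "cart_mesh"))
  nrm <- vertex_normals(distal_mesh, orient = "-z")
  zero <- rowSums(nrm^2) == 0
  hits <- ray_mesh_hits(distal_mesh$vertices, nrm,
                        proximal_mesh$vertices, proximal_mesh$faces,
                        t_max = max_thickness)
  ok <- !is.na(hits) & !zero
  if (!any(ok)) {
    stop_cartthick("no distal normal intersected the proximal mesh.",
                   "cartthick_method_failure_error")
  }
  origin <- distal_mesh$origin[ok, , drop = FALSE]
  colnames(origin) <- c("x", "y", "z")
  new_thickness_samples(
    tibble::tibble(x = origin[, 1], y = origin[, 2], z = origin[, 3],
                   thickness = hits[ok],
                   subregion = maybe_assign(parc, origin)),
    failures = c(no_intersection = sum(is.na(hits) & !zero),
                 zero_normal = sum(zero)))
}

#' 3D nearest-neighbor thickness (3D-NN)
#'
#' For every distal surface voxel, the Euclidean distance to its exact nearest
#' proximal surface voxel (kd-tree search over all proximal voxels), in
#' physical mm and in the original anatomical frame.
#'
#' @param surfaces A `surface_pair` (tibia) or `femur_surfaces` object.
#' @inheritParams thickness_mesh_normals
#' @return A `thickness_samples` tibble (one sample per distal voxel).
#' @export
thickness_nearest_neighbors <- function(surfaces, parc = NULL,
                                        max_thickness = 15) {
  sets <- surfaces_original_coords(surfaces)
  if (nrow(sets$proximal) == 0 || nrow(sets$distal) == 0) {
    stop_cartthick("empty surface set for nearest-neighbor search.",
                   "cartthick_method_failure_error")
  }
  nn <- RANN::nn2(as.matrix(sets$proximal), as.matrix(sets$distal), k = 1)
  d <- nn$nn.dists[, 1]
  ok <- d <= max_thickness
  origin <- as.matrix(sets$distal)[ok, , drop = FALSE]
  new_thickness_samples(
    tibble::tibble(x = origin[, 1], y = origin[, 2], z = origin[, 3],
                   thickness = d[ok],
                   subregion = maybe_assign(parc, origin)),
    failures = c(over_cap = sum(!ok)))
}

# Algebraic least-squares sphere fit (linear in center and radius).
fit_sphere <- function(pts) {
  A <- cbind(2 * pts[, 1], 2 * pts[, 2], 2 * pts[, 3], 1)
  b <- rowSums(pts^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  center <- sol[1:3]
  r2 <- sol[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(center = unname(center), radius = sqrt(r2))
}

#' Construct a ray-tracing sphere configuration
#'
#' @param centers Named list of 8 sphere centers (mm): `LT, MT, aLF, aMF,
#'   cLF, cMF, pLF, pMF`.
#' @param radius Sphere radius (mm) at whose surface the rays originate.
#' @param n_polar,n_azimuthal UV-sphere vertex subdivisions; vertex (= ray)
#'   count per sphere is `2 + n_azimuthal * (n_polar - 2)`.
#' @param max_steps Marching-iteration cap for finding the cartilage entry.
#' @param step Marching step length (mm).
#' @return A `ray_sphere_config`.
#' @export
ray_sphere_config <- function(centers, radius = 2, n_polar = 60,
                              n_azimuthal = 60, max_steps = 100, step = 0.18) {
  if (n_polar < 3 || n_azimuthal < 3) {
    stop_cartthick("sphere subdivisions must be at least 3.",
                   "cartthick_config_error")
  }
  structure(list(centers = centers, radius = radius, n_polar = n_polar,
                 n_azimuthal = n_azimuthal, max_steps = max_steps,
                 step = step),
            class = "ray_sphere_config")
}

#' Place the eight ray-origin spheres for one knee
#'
#' Two tibial spheres sit a fixed bone-ward distance below the plate centroids
#' (larger z = toward the tibial bone); six femoral spheres are placed at the
#' centers of least-squares spheres fitted to the distal surface of the
#' anterior, central (the three thirds pooled), and posterior subregions of
#' each femoral plate, i.e. near the focal point of the curved cartilage. A
#' degenerate (flat) femoral fit falls back to the surface centroid offset
#' bone-ward, with a warning.
#'
#' @param parc A [parcellate_knee()] result.
#' @param femur_surfaces Optional precomputed [extract_surfaces_femur()]
#'   output; computed from `parc` when missing.
#' @param radius Sphere radius (mm).
#' @param tibial_offset Bone-ward center offset for the tibial spheres (mm).
#' @param n_polar,n_azimuthal,max_steps Passed to [ray_sphere_config()].
#' @param step Marching step (mm); default half the smallest voxel spacing.
#' @return A `ray_sphere_config` with all 8 centers.
#' @export
place_ray_spheres <- function(parc, femur_surfaces = NULL, radius = 2,
                              tibial_offset = 10, n_polar = 60,
                              n_azimuthal = 60, max_steps = 100, step = NULL) {
  stopifnot(inherits(parc, "knee_parcellation"))
  vox <- parc$voxels
  step <- step %||% (0.5 * min(parc$spacing))
  centers <- list()
  for (side in c("LT", "MT")) {
    plate <- vox[vox$region == side, , drop = FALSE]
    if (nrow(plate) == 0) {
      stop_cartthick(paste0("tibial plate ", side, " is empty."),
                     "cartthick_empty_structure_error")
    }
    centers[[side]] <- c(mean(plate$x), mean(plate$y),
                         mean(plate$z) + tibial_offset)
  }
  if (is.null(femur_surfaces)) {
    fem <- vox[vox$structure == "femur", , drop = FALSE]
    attr(fem, "spacing") <- parc$spacing
    femur_surfaces <- extract_surfaces_femur(fem, fem$subregion)
  }
  # distal surface voxels in original coordinates, tagged by subregion
  dist_pts <- dplyr::bind_rows(lapply(
    Filter(Negate(is.null), unclass(femur_surfaces)), function(p) {
      tibble::tibble(x = p$distal$ox, y = p$distal$oy, z = p$distal$oz)
    }))
  dist_pts$subregion <- assign_samples(parc, dist_pts)
  groups <- list(a = "a", c = c("ic", "cc", "ec"), p = "p")
  for (side in c("LF", "MF")) {
    for (g in names(groups)) {
      subs <- paste0(groups[[g]], side)
      pts <- dist_pts[dist_pts$subregion %in% subs, c("x", "y", "z")]
      nm <- paste0(g, side)
      if (nrow(pts) == 0) {
        stop_cartthick(paste0("femoral subregion group ", nm, " is empty."),
                       "cartthick_empty_structure_error")
      }
      fit <- if (nrow(pts) >= 10) fit_sphere(as.matrix(pts)) else NULL
      degenerate <- is.null(fit) || fit$radius > 100 ||
        any(!is.finite(fit$center))
      if (degenerate) {
        warn(paste0("sphere fit degenerate for ", nm,
                    "; falling back to centroid offset."))
        centers[[nm]] <- c(mean(pts$x), mean(pts$y), mean(pts$z) - tibial_offset)
      } else {
        centers[[nm]] <- fit$center
      }
    }
  }
  ray_sphere_config(centers[c("LT", "MT", "aLF", "aMF", "cLF", "cMF",
                              "pLF", "pMF")],
                    radius = radius, n_polar = n_polar,
                    n_azimuthal = n_azimuthal, max_steps = max_steps,
                    step = step)
}

#' Evenly distributed rays from each sphere
#'
#' UV-sphere tessellation: two poles plus `n_azimuthal` vertices on each of
#' the `n_polar - 2` interior latitude rings, `2 + n_azimuthal * (n_polar -
#' 2)` vertices in total (3482 at the 60/60 default). Each vertex defines one
#' ray: origin on the sphere surface, direction the outward surface normal.
#'
#' @param config A [ray_sphere_config()].
#' @return Tibble with `sphere`, origin `ox, oy, oz` (mm) and unit direction
#'   `dx, dy, dz`.
#' @export
sphere_ray_bundle <- function(config) {
  stopifnot(inherits(config, "ray_sphere_config"))
  np <- config$n_polar
  na_ <- config$n_azimuthal
  theta <- pi * seq(1, np - 2) / (np - 1)
  phi <- 2 * pi * seq(0, na_ - 1) / na_
  grid <- expand.grid(theta = theta, phi = phi)
  dirs <- rbind(c(0, 0, 1),
                cbind(sin(grid$theta) * cos(grid$phi),
                      sin(grid$theta) * sin(grid$phi),
                      cos(grid$theta)),
                c(0, 0, -1))
  purrr::map_dfr(names(config$centers), function(nm) {
    ctr <- config$centers[[nm]]
    tibble::tibble(sphere = nm,
                   ox = ctr[1] + config$radius * dirs[, 1],
                   oy = ctr[2] + config$radius * dirs[, 2],
                   oz = ctr[3] + config$radius * dirs[, 3],
                   dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3])
  })
}

#' 3D ray-tracing thickness (3D-RT)
#'
#' Marches every ray of every sphere in fixed steps through the voxel grid and
#' records the first entry into and first subsequent exit from the sphere's
#' target (sub)region voxel set. Thickness is the Euclidean entry-exit
#' distance; rays that fail to enter within `max_steps` iterations yield no
#' value. Samples are assigned to the subregion of the voxel where the ray
#' first entered.
#'
#' @param x A [parcellate_knee()] result (targets default to: tibial spheres
#'   target their whole plate, femoral spheres their subregion group) or a
#'   [label_volume()] (targets default to all non-background voxels).
#' @param config A [ray_sphere_config()].
#' @param targets Optional named list: sphere name -> subregion ids (for a
#'   parcellation) or label integers (for a volume).
#' @param max_thickness Discard-and-count cap (mm).
#' @return A `thickness_samples` tibble; `failures` counts rays that never
#'   entered and entries without exit.
#' @export
thickness_ray_tracing <- function(x, config, targets = NULL,
                                  max_thickness = 15) {
  stopifnot(inherits(config, "ray_sphere_config"))
  tab <- subregion_table()
  if (inherits(x, "knee_parcellation")) {
    vol <- subregion_volume(x)
    code_of <- stats::setNames(tab$code, tab$subregion)
    if (is.null(targets)) {
      targets <- list()
      for (side in c("LT", "MT")) {
        targets[[side]] <- unname(code_of[tab$subregion[tab$region == side]])
      }
      groups <- list(a = "a", c = c("ic", "cc", "ec"), p = "p")
      for (side in c("LF", "MF")) for (g in names(groups)) {
        targets[[paste0(g, side)]] <- unname(code_of[paste0(groups[[g]], side)])
      }
    } else {
      targets <- lapply(targets, function(t)
        if (is.character(t)) unname(code_of[t]) else t)
    }
    name_of <- stats::setNames(tab$subregion, tab$code)
  } else {
    stopifnot(inherits(x, "label_volume"))
    vol <- x
    if (is.null(targets)) {
      targets <- stats::setNames(
        rep(list(sort(setdiff(unique(as.integer(vol$grid)), 0L))),
            length(config$centers)),
        names(config$centers))
    }
    name_of <- NULL
  }
  rays <- sphere_ray_bundle(config)
  sp <- vol$spacing
  dims <- dim(vol$grid)
  step <- config$step
  extra <- ceiling(max_thickness / step)
  out <- list()
  fail_enter <- 0L
  fail_exit <- 0L
  over_cap <- 0L
  for (nm in names(config$centers)) {
    rr <- rays[rays$sphere == nm, , drop = FALSE]
    tgt <- targets[[nm]]
    if (is.null(tgt) || length(tgt) == 0 || any(is.na(tgt))) next
    n <- nrow(rr)
    entry <- rep(NA_integer_, n)
    exit <- rep(NA_integer_, n)
    entry_code <- rep(NA_integer_, n)
    for (s in seq_len(config$max_steps + extra)) {
      t_s <- s * step
      px <- rr$ox + t_s * rr$dx
      py <- rr$oy + t_s * rr$dy
      pz <- rr$oz + t_s * rr$dz
      ii <- as.integer(round(px / sp[1])) + 1L
      jj <- as.integer(round(py / sp[2])) + 1L
      kk <- as.integer(round(pz / sp[3])) + 1L
      inb <- ii >= 1L & ii <= dims[1] & jj >= 1L & jj <= dims[2] &
        kk >= 1L & kk <= dims[3]
      code <- rep(0L, n)
      code[inb] <- vol$grid[cbind(ii[inb], jj[inb], kk[inb])]
      inside <- code %in% tgt & code != 0L
      if (s <= config$max_steps) {
        newly <- inside & is.na(entry)
        entry[newly] <- s
        entry_code[newly] <- code[newly]
      }
      exited <- !inside & !is.na(entry) & is.na(exit)
      exit[exited] <- s
      if (all(!is.na(exit) | is.na(entry)) && s > config$max_steps) break
    }
    fail_enter <- fail_enter + sum(is.na(entry))
    fail_exit <- fail_exit + sum(!is.na(entry) & is.na(exit))
    ok <- !is.na(entry) & !is.na(exit)
    if (!any(ok)) next
    val <- (exit[ok] - entry[ok]) * step
    keep <- val <= max_thickness
    over_cap <- over_cap + sum(!keep)
    idx <- which(ok)[keep]
    t_e <- entry[idx] * step
    sub <- if (is.null(name_of)) rep(NA_character_, length(idx)) else
      unname(name_of[as.character(entry_code[idx])])
    out[[nm]] <- tibble::tibble(
      sphere = nm,
      x = rr$ox[idx] + t_e * rr$dx[idx],
      y = rr$oy[idx] + t_e * rr$dy[idx],
      z = rr$oz[idx] + t_e * rr$dz[idx],
      thickness = val[keep],
      subregion = sub)
  }
  if (length(out) == 0) {
    stop_cartthick("no ray produced a thickness value for any sphere.",
                   "cartthick_method_failure_error")
  }
  new_thickness_samples(dplyr::bind_rows(out),
                        failures = c(never_entered = fail_enter,
                                     no_exit = fail_exit,
                                     over_cap = over_cap))
}
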