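#' Subregion nomenclature table
#'
#' The 20 standardized femorotibial subregions: five per tibial plate
#' (central, external, internal, anterior, posterior) and five per femoral
#' plate (anterior, posterior, and the internal/central/external thirds of the
#' weight-bearing central subregion), for the medial (MT/MF) and lateral
#' (LT/LF) compartments. Each subregion carries a stable integer code used
#' when exporting a parcellation as a label volume.
#'
#' @return Tibble with columns `subregion`, `region`, `structure`, `code`.
#' @export
subregion_table <- function() {
  tib <- expand.grid(prefix = c("c", "e", "i", "a", "p"),
                     side = c("LT", "MT"), stringsAsFactors = FALSE)
  fem <- expand.grid(prefix = c("a", "p", "ic", "cc", "ec"),
                     side = c("LF", "MF"), stringsAsFactors = FALSE)
  out <- tibble::tibble(
    subregion = c(paste0(tib$prefix, tib$side), paste0(fem$prefix, fem$side)),
    region = c(tib$side, fem$side),
    structure = rep(c("tibia", "femur"), each = 10)
  )
  out$code <- seq_len(nrow(out))
  out
}

region_of <- function(subregion) {
  substr(subregion, nchar(subregion) - 1L, nchar(subregion))
}

#' Split the tibial cartilage into medial and lateral plates
#'
#' The boundary is the midpoint of the occupied y-range (the mediolateral
#' axis). Which side is called medial is a dataset convention (it depends on
#' left vs right knee) set by `medial_side`.
#'
#' @param tibia Voxel point set (tibble from [extract_structure_points()]).
#' @param medial_side `"low-y"` or `"high-y"`.
#' @return Named list of two point sets, `MT` and `LT`, with attribute
#'   `y_split` (mm).
#' @export
split_tibia_plates <- function(tibia, medial_side = "low-y") {
  if (is.null(tibia) || nrow(tibia) == 0) {
    stop_cartthick("empty tibial point set.", "cartthick_empty_structure_error")
  }
  y_split <- (min(tibia$y) + max(tibia$y)) / 2
  low <- tibia[tibia$y <= y_split, , drop = FALSE]
  high <- tibia[tibia$y > y_split, , drop = FALSE]
  if (nrow(low) == 0 || nrow(high) == 0) {
    stop_cartthick("tibial medial/lateral split produced an empty plate.",
                   "cartthick_empty_structure_error")
  }
  out <- if (medial_side == "low-y") list(MT = low, LT = high) else
    list(MT = high, LT = low)
  for (nm in names(out)) attr(out[[nm]], "spacing") <- attr(tibia, "spacing")
  attr(out, "y_split") <- y_split
  out
}

# Mean cartilage column height (mm) per mediolateral position over the
# anterior portion of the femur; the trochlear sulcus shows up as an interior
# minimum of the smoothed profile.
detect_sulcus_y <- function(femur, smooth_window = 5L) {
  sp <- attr(femur, "spacing")
  x_mid <- (min(femur$x) + max(femur$x)) / 2
  ant <- femur[femur$x <= x_mid, , drop = FALSE]
  if (nrow(ant) == 0) ant <- femur
  cols <- dplyr::count(ant, .data$i, .data$j, name = "height")
  prof <- dplyr::summarise(dplyr::group_by(cols, .data$j),
                           h = mean(.data$height) * sp[3], .groups = "drop")
  prof <- prof[order(prof$j), ]
  if (nrow(prof) < 5) return(list(y = NA_real_, ok = FALSE))
  w <- min(smooth_window, nrow(prof))
  sm <- as.numeric(stats::filter(prof$h, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- prof$h[is.na(sm)]
  m <- which.min(sm)
  interior <- m > 1 && m < nrow(prof)
  list(y = prof$j[m] * sp[2], ok = interior)
}

#' Split the femoral cartilage into medial and lateral plates
#'
#' The split runs along the trochlear sulcus, detected as the interior minimum
#' of the smoothed mean column-height profile over the anterior femur. When no
#' interior minimum exists the split falls back to the midpoint of the
#' occupied y-range, with a warning.
#'
#' @inheritParams split_tibia_plates
#' @param femur Femoral voxel point set.
#' @return Named list `MF`, `LF` with attributes `sulcus_y` (mm) and
#'   `sulcus_fallback` (logical).
#' @export
split_femur_plates <- function(femur, medial_side = "low-y") {
  if (is.null(femur) || nrow(femur) == 0) {
    stop_cartthick("empty femoral point set.", "cartthick_empty_structure_error")
  }
  det <- detect_sulcus_y(femur)
  fallback <- !isTRUE(det$ok)
  y_split <- if (fallback) {
    warn("trochlear sulcus detection found no interior minimum; falling back to mid-y.")
    (min(femur$y) + max(femur$y)) / 2
  } else det$y
  low <- femur[femur$y <= y_split, , drop = FALSE]
  high <- femur[femur$y > y_split, , drop = FALSE]
  if (nrow(low) == 0 || nrow(high) == 0) {
    stop_cartthick("femoral medial/lateral split produced an empty plate.",
                   "cartthick_empty_structure_error")
  }
  out <- if (medial_side == "low-y") list(MF = low, LF = high) else
    list(MF = high, LF = low)
  for (nm in names(out)) attr(out[[nm]], "spacing") <- attr(femur, "spacing")
  attr(out, "sulcus_y") <- y_split
  attr(out, "sulcus_fallback") <- fallback
  out
}

#' Partition one tibial plate into its five subregions
#'
#' The central subregion collects the voxels inside a z-axis cylinder around
#' the plate's center of gravity whose radius is the smallest enclosing at
#' least 20% of the plate voxels (ties included). The remaining voxels fall
#' into anterior/posterior/internal/external quadrants bounded by the 45-degree
#' diagonals through the cylinder center in the x-y plane (anterior faces -x;
#' internal faces the intercondylar midline given by `y_split`). All distances
#' are in physical mm, so anisotropic spacing is handled correctly.
#'
#' @param plate Voxel point set of one tibial plate.
#' @param side `"MT"` or `"LT"`.
#' @param y_split Mediolateral split coordinate (mm) from
#'   [split_tibia_plates()]; defines the internal direction.
#' @param central_fraction Target central volume fraction (default 0.20).
#' @return The plate tibble with a `subregion` column; attributes
#'   `cylinder_center` (mm) and `cylinder_radius` (mm).
#' @export
partition_tibial_plate <- function(plate, side, y_split,
                                   central_fraction = 0.20) {
  if (nrow(plate) < 5) {
    stop_cartthick("tibial plate has fewer than 5 voxels.",
                   "cartthick_too_small_error")
  }
  cx <- mean(plate$x)
  cy <- mean(plate$y)
  d <- sqrt((plate$x - cx)^2 + (plate$y - cy)^2)
  r <- sort(d)[ceiling(central_fraction * nrow(plate))]
  central <- d <= r + 1e-9
  s <- if (y_split >= cy) 1 else -1
  dx <- plate$x - cx
  dyp <- (plate$y - cy) * s
  quad <- ifelse(abs(dx) >= abs(dyp),
                 ifelse(dx < 0, "a", "p"),
                 ifelse(dyp > 0, "i", "e"))
  plate$subregion <- paste0(ifelse(central, "c", quad), side)
  attr(plate, "cylinder_center") <- c(cx, cy)
  attr(plate, "cylinder_radius") <- r
  plate
}

#' Partition one femoral plate into its five subregions
#'
#' The central femoral subregion occupies the anteroposterior (x) interval
#' spanned by the corresponding central tibial subregion (the vis-a-vis,
#' weight-bearing rule); voxels anterior of that interval (smaller x) are
#' anterior, those posterior of it (larger x) are posterior. The central
#' subregion is further cut into three equal-width mediolateral thirds:
#' internal (toward the intercondylar midline `y_split`), central central, and
#' external.
#'
#' @param plate Voxel point set of one femoral plate.
#' @param side `"MF"` or `"LF"`.
#' @param tibial_central Point set of the matching compartment's central
#'   tibial subregion.
#' @param y_split Mediolateral midline coordinate (mm).
#' @return The plate tibble with a `subregion` column; attribute
#'   `central_x_interval` (mm).
#' @export
partition_femoral_plate <- function(plate, side, tibial_central, y_split) {
  if (nrow(plate) == 0) {
    stop_cartthick("empty femoral plate.", "cartthick_empty_structure_error")
  }
  if (is.null(tibial_central) || nrow(tibial_central) == 0) {
    stop_cartthick("no central tibial reference for the vis-a-vis rule.",
                   "cartthick_config_error")
  }
  a <- min(tibial_central$x)
  b <- max(tibial_central$x)
  zone <- ifelse(plate$x < a - 1e-9, "a",
                 ifelse(plate$x > b + 1e-9, "p", "c"))
  sub <- character(nrow(plate))
  sub[zone == "a"] <- paste0("a", side)
  sub[zone == "p"] <- paste0("p", side)
  cen <- zone == "c"
  if (any(cen)) {
    y0 <- min(plate$y[cen])
    y1 <- max(plate$y[cen])
    w <- (y1 - y0) / 3
    third <- pmin(2L, pmax(0L, as.integer(floor((plate$y[cen] - y0) / max(w, 1e-12)))))
    cy <- mean(plate$y)
    # internal third faces the midline
    order_names <- if (y_split >= cy) c("ec", "cc", "ic") else c("ic", "cc", "ec")
    sub[cen] <- paste0(order_names[third + 1L], side)
  }
  plate$subregion <- sub
  attr(plate, "central_x_interval") <- c(a, b)
  plate
}

#' Parcellate a segmented knee into the 20 standardized subregions
#'
#' Runs the full parcellation: tibial medial/lateral split at the mid-y of the
#' occupied range, femoral split at the trochlear sulcus, the 20%-volume
#' central tibial cylinder with quadrants, and the femoral
#' anterior/central/posterior bands with central thirds (vis-a-vis rule).
#'
#' @param vol A [label_volume()] containing femoral and tibial cartilage, or a
#'   `cart_phantom`.
#' @param medial_side `"low-y"` or `"high-y"`.
#' @return A `knee_parcellation`: list with `voxels` (tibble: `structure, i, j,
#'   k, x, y, z, subregion, region`), `spacing`, `dim`, `y_split`, `sulcus_y`,
#'   `cylinders` (per tibial plate center/radius), and `central_x` intervals.
#' @export
#' @examples
#' ph <- make_knee_phantom(plate_extent = c(16, 12), femoral_radius = 10)
#' parc <- parcellate_knee(ph)
#' table(parc$voxels$subregion)
parcellate_knee <- function(vol, medial_side = "low-y") {
  if (inherits(vol, "cart_phantom")) vol <- vol$volume
  stopifnot(inherits(vol, "label_volume"))
  tibia <- extract_structure_points(vol, "tibial cartilage")
  femur <- extract_structure_points(vol, "femoral cartilage")
  plates <- split_tibia_plates(tibia, medial_side)
  y_split <- attr(plates, "y_split")
  parts <- lapply(names(plates), function(s) {
    partition_tibial_plate(plates[[s]], s, y_split)
  })
  names(parts) <- names(plates)
  fplates <- split_femur_plates(femur, medial_side)
  sulcus_y <- attr(fplates, "sulcus_y")
  fparts <- lapply(names(fplates), function(s) {
    tib_side <- sub("F$", "T", s)
    tc <- parts[[tib_side]]
    tc <- tc[tc$subregion == paste0("c", tib_side), , drop = FALSE]
    partition_femoral_plate(fplates[[s]], s, tc, sulcus_y)
  })
  names(fparts) <- names(fplates)
  vox <- dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(parts), structure = "tibia"),
    dplyr::mutate(dplyr::bind_rows(fparts), structure = "femur")
  )
  vox$region <- region_of(vox$subregion)
  vox <- dplyr::select(vox, "structure", "i", "j", "k", "x", "y", "z",
                       "subregion", "region")
  structure(list(
    voxels = vox,
    spacing = vol$spacing,
    dim = dim(vol$grid),
    y_split = y_split,
    sulcus_y = sulcus_y,
    sulcus_fallback = attr(fplates, "sulcus_fallback"),
    cylinders = lapply(parts, function(p) list(
      center = attr(p, "cylinder_center"), radius = attr(p, "cylinder_radius"))),
    central_x = lapply(fparts, attr, "central_x_interval")
  ), class = "knee_parcellation")
}

#' @export
print.knee_parcellation <- function(x, ...) {
  cat("<knee_parcellation> ", nrow(x$voxels), " cartilage voxels, ",
      length(unique(x$voxels$subregion)), " subregions\n", sep = "")
  cat("  tibial y-split: ", format(x$y_split), " mm; femoral sulcus: ",
      format(x$sulcus_y), " mm\n", sep = "")
  invisible(x)
}

#' Per-subregion voxel counts
#'
#' @param parc A [parcellate_knee()] result.
#' @return Tibble with `structure`, `region`, `subregion`, `n_voxels`.
#' @export
subregion_counts <- function(parc) {
  dplyr::count(parc$voxels, .data$structure, .data$region, .data$subregion,
               name = "n_voxels")
}

#' Assign sample points to subregions by nearest labeled voxel
#'
#' Each query point receives the subregion of its nearest cartilage voxel
#' (exact match when the point is a voxel center). Points farther than two
#' voxel spacings from any labeled voxel are left unassigned (`NA`) and
#' counted in the `n_unassigned` attribute.
#'
#' @param parc A [parcellate_knee()] result, or any tibble with `x, y, z,
#'   subregion` columns.
#' @param points Matrix or data frame of query points (columns x, y, z, mm).
#' @param max_dist Maximum assignment distance in mm; default two times the
#'   largest voxel spacing.
#' @return Character vector of subregion ids (`NA` where unassigned), with
#'   attribute `n_unassigned`.
#' @export
assign_samples <- function(parc, points, max_dist = NULL) {
  vox <- if (inherits(parc, "knee_parcellation")) parc$voxels else parc
  sp <- if (inherits(parc, "knee_parcellation")) parc$spacing else
    attr(parc, "spacing") %||% c(0.36, 0.7, 0.36)
  max_dist <- max_dist %||% (2 * max(sp))
  pts <- as.matrix(as.data.frame(points)[, 1:3])
  nn <- RANN::nn2(as.matrix(vox[, c("x", "y", "z")]), pts, k = 1)
  out <- vox$subregion[nn$nn.idx[, 1]]
  out[nn$nn.dists[, 1] > max_dist] <- NA_character_
  attr(out, "n_unassigned") <- sum(is.na(out))
  out
}

#' Export a parcellation as an integer label volume
#'
#' Subregions are written with the stable codes from [subregion_table()], so
#' the result can be saved with [write_label_volume()] and inspected in any
#' viewer.
#'
#' @param parc A [parcellate_knee()] result.
#' @return A [label_volume()] whose label map is subregion -> code.
#' @export
subregion_volume <- function(parc) {
  tab <- subregion_table()
  codes <- stats::setNames(tab$code, tab$subregion)
  grid <- array(0L, parc$dim)
  grid[cbind(parc$voxels$i + 1L, parc$voxels$j + 1L, parc$voxels$k + 1L)] <-
    codes[parc$voxels$subregion]
  label_volume(grid, parc$spacing, label_map = codes)
}
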