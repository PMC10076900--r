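# Surface tibbles carry working-frame indices (i, j, k) and coordinates
# (x, y, z), plus the original-frame physical coordinates (ox, oy, oz). For
# the tibia and the anterior/central femur the two frames coincide; for the
# posterior femur the working frame is the 90-degree rotated one.

surface_pair <- function(distal, proximal, structure, rotated = FALSE,
                         n_skipped = 0L, spacing = NULL) {
  structure(list(distal = distal, proximal = proximal, structure = structure,
                 rotated = rotated, n_skipped_columns = n_skipped,
                 spacing = spacing),
            class = "surface_pair")
}

# Per-(i, j) column extremes plus a disjoint-run audit. `runs` counts the
# maximal contiguous voxel runs along z in each column.
column_extremes <- function(points) {
  dplyr::summarise(
    dplyr::group_by(points, .data$i, .data$j),
    k_min = min(.data$k), k_max = max(.data$k),
    runs = sum(diff(sort(.data$k)) > 1L) + 1L,
    .groups = "drop")
}

#' Extract distal and proximal tibial surface voxels
#'
#' Per (x, y) column of the tibial point set, the voxel with the highest z
#' (closest to bone, head-to-feet axis) becomes a distal surface voxel and the
#' one with the lowest z a proximal surface voxel. Where the cartilage is one
#' voxel thick the two surfaces share that voxel.
#'
#' @param points Tibial voxel point set.
#' @return A `surface_pair` with `distal` and `proximal` tibbles.
#' @export
extract_surfaces_tibia <- function(points) {
  if (is.null(points) || nrow(points) == 0) {
    stop_cartthick("empty tibial point set.", "cartthick_empty_structure_error")
  }
  sp <- attr(points, "spacing")
  cols <- column_extremes(points)
  mk <- function(kk) {
    s <- voxel_points(cols$i, cols$j, kk, sp)
    s$ox <- s$x; s$oy <- s$y; s$oz <- s$z
    s
  }
  surface_pair(mk(cols$k_max), mk(cols$k_min), "tibia", spacing = sp)
}

# 90-degree rotation about the y-axis as an exact index permutation:
# (i, j, k) -> (k_ref - k, j, i). Requires equal x and z spacing. Self-inverse
# composition: applying the map four times is the identity.
rotate_indices_90y <- function(i, k, k_ref) {
  list(i = k_ref - k, k = i)
}
unrotate_indices_90y <- function(i, k, k_ref) {
  list(i = k, k = k_ref - i)
}

#' Extract distal and proximal femoral surface voxels
#'
#' The anterior and central femoral cartilage is processed column-wise like
#' the tibia (per column, highest z = distal = articular surface; for the
#' femur the distal surface is the cartilage-synovia interface). Columns along
#' z would regularly cross the curved posterior subregions twice, so the
#' posterior voxels are first rotated by 90 degrees about the y-axis (an exact
#' index permutation, requiring equal x and z spacing), processed column-wise
#' in the rotated frame, and the resulting surface voxels mapped back.
#' Columns that still intersect the cartilage in more than two disjoint runs
#' after rotation are skipped and counted.
#'
#' @param points Femoral voxel point set.
#' @param posterior Logical vector along `points` rows, or a character vector
#'   of subregion ids (anything starting with `"p"` is posterior).
#' @return List of class `femur_surfaces` with `$anterior_central` and
#'   `$posterior` surface pairs (the posterior one in the rotated working
#'   frame with original coordinates in `ox, oy, oz`).
#' @export
extract_surfaces_femur <- function(points, posterior) {
  if (is.null(points) || nrow(points) == 0) {
    stop_cartthick("empty femoral point set.", "cartthick_empty_structure_error")
  }
  sp <- attr(points, "spacing")
  if (abs(sp[1] - sp[3]) > 1e-9) {
    warn("x and z spacing differ; the 90-degree posterior rotation is not an exact permutation.")
  }
  if (is.character(posterior)) posterior <- grepl("^p", posterior)
  stopifnot(length(posterior) == nrow(points))
  ac <- points[!posterior, , drop = FALSE]
  po <- points[posterior, , drop = FALSE]
  attr(ac, "spacing") <- sp; attr(po, "spacing") <- sp

  ac_pair <- NULL
  if (nrow(ac) > 0) {
    cols <- column_extremes(ac)
    skip <- cols$runs > 2L
    cols <- cols[!skip, , drop = FALSE]
    mk <- function(kk) {
      s <- voxel_points(cols$i, cols$j, kk, sp)
      s$ox <- s$x; s$oy <- s$y; s$oz <- s$z
      s
    }
    ac_pair <- surface_pair(mk(cols$k_max), mk(cols$k_min), "femur",
                            n_skipped = sum(skip), spacing = sp)
  }

  po_pair <- NULL
  if (nrow(po) > 0) {
    k_ref <- max(points$k)
    rot <- rotate_indices_90y(po$i, po$k, k_ref)
    po_r <- voxel_points(rot$i, po$j, rot$k, c(sp[3], sp[2], sp[1]))
    cols <- column_extremes(po_r)
    skip <- cols$runs > 2L
    cols <- cols[!skip, , drop = FALSE]
    mk <- function(kk) {
      s <- voxel_points(cols$i, cols$j, kk, c(sp[3], sp[2], sp[1]))
      un <- unrotate_indices_90y(s$i, s$k, k_ref)
      s$ox <- un$i * sp[1]; s$oy <- s$j * sp[2]; s$oz <- un$k * sp[3]
      s
    }
    po_pair <- surface_pair(mk(cols$k_max), mk(cols$k_min), "femur",
                            rotated = TRUE, n_skipped = sum(skip),
                            spacing = c(sp[3], sp[2], sp[1]))
    attr(po_pair, "k_ref") <- k_ref
  }
  structure(list(anterior_central = ac_pair, posterior = po_pair),
            class = "femur_surfaces")
}

# Combined distal/proximal surface voxels in original physical coordinates;
# used by the nearest-neighbor method, which is frame-agnostic.
surfaces_original_coords <- function(surf) {
  pairs <- if (inherits(surf, "surface_pair")) list(surf) else
    Filter(Negate(is.null), unclass(surf))
  grab <- function(which_side) {
    dplyr::bind_rows(lapply(pairs, function(p) {
      s <- p[[which_side]]
      tibble::tibble(x = s$ox, y = s$oy, z = s$oz)
    }))
  }
  list(distal = grab("distal"), proximal = grab("proximal"))
}

#' Triangulate a surface height field
#'
#' Surface voxels form a single-valued height field over the in-plane integer
#' lattice of their working frame. The mesh is the lattice triangulation of
#' the occupied unit cells (two triangles per fully occupied cell, one where
#' exactly three corners exist), which on the integer lattice is a Delaunay
#' triangulation and, unlike hull-based triangulation, never spans holes in
#' the surface footprint. Vertices are in physical mm.
#'
#' @param surface A surface tibble (one side of a `surface_pair`).
#' @return A `cart_mesh`: list with `vertices` (n x 3 mm, working frame),
#'   `faces` (m x 3 indices), `origin` (n x 3 mm, original frame).
#' @export
build_mesh <- function(surface) {
  n <- nrow(surface)
  if (n < 3) {
    stop_cartthick("need at least 3 surface points to mesh.",
                   "cartthick_mesh_error")
  }
  i0 <- min(surface$i); j0 <- min(surface$j)
  ni <- max(surface$i) - i0 + 1L
  nj <- max(surface$j) - j0 + 1L
  idmap <- matrix(NA_integer_, ni, nj)
  idmap[cbind(surface$i - i0 + 1L, surface$j - j0 + 1L)] <- seq_len(n)
  if (ni < 2 || nj < 2) {
    stop_cartthick("surface points are collinear; cannot mesh.",
                   "cartthick_mesh_error")
  }
  a <- idmap[-ni, -nj]   # (i, j)
  b <- idmap[-1L, -nj]   # (i+1, j)
  cc <- idmap[-ni, -1L]  # (i, j+1)
  d <- idmap[-1L, -1L]   # (i+1, j+1)
  present <- (!is.na(a)) + (!is.na(b)) + (!is.na(cc)) + (!is.na(d))
  full <- which(present == 4L)
  tri3 <- which(present == 3L)
  faces <- NULL
  if (length(full) > 0) {
    faces <- rbind(cbind(a[full], b[full], d[full]),
                   cbind(a[full], d[full], cc[full]))
  }
  if (length(tri3) > 0) {
    m3 <- cbind(a[tri3], b[tri3], d[tri3], cc[tri3])
    tri <- t(apply(m3, 1, function(r) r[!is.na(r)]))
    faces <- rbind(faces, tri)
  }
  if (is.null(faces) || nrow(faces) == 0) {
    stop_cartthick("surface footprint has no full lattice cell; cannot mesh.",
                   "cartthick_mesh_error")
  }
  structure(list(
    vertices = cbind(surface$x, surface$y, surface$z),
    faces = unname(faces),
    origin = cbind(surface$ox %||% surface$x, surface$oy %||% surface$y,
                   surface$oz %||% surface$z)
  ), class = "cart_mesh")
}

#' Per-vertex surface normals
#'
#' Normals are the normalized area-weighted average of incident face normals
#' (the cross-product accumulation weights faces by area automatically),
#' i.e. perpendicular to the local tangent plane. Orientation is fixed from
#' the distal toward the proximal surface, which in the working frame of every
#' surface here means a negative z component. Isolated vertices (no incident
#' face) get a zero normal and are excluded from measurement by callers.
#'
#' @param mesh A [build_mesh()] result.
#' @param orient `"-z"` (distal to proximal, default) or `"+z"`.
#' @return n x 3 matrix of unit normals (zero rows for isolated vertices).
#' @export
vertex_normals <- function(mesh, orient = c("-z", "+z")) {
  orient <- match.arg(orient)
  V <- mesh$vertices
  f <- mesh$faces
  e1 <- V[f[, 2], , drop = FALSE] - V[f[, 1], , drop = FALSE]
  e2 <- V[f[, 3], , drop = FALSE] - V[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  acc <- matrix(0, nrow(V), 3)
  for (col in 1:3) {
    rs <- rowsum(fn, group = f[, col])
    ids <- as.integer(rownames(rs))
    acc[ids, ] <- acc[ids, ] + rs
  }
  nrm <- normalize_rows(acc)
  sgn <- if (orient == "-z") -1 else 1
  flip <- sign(nrm[, 3]) == -sgn & nrm[, 3] != 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  nrm
}
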