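# Both 2D methods work on sagittal slices (fixed y): pixels (i, k) with
# physical in-plane coordinates (x, z) = (i * sx, k * sz). The posterior
# femoral part is rotated 90 degrees in-slice first (cubics cannot represent
# hook-shaped outlines), mirroring the 3D surface treatment.

polyval3 <- function(cf, x) cf[1] + x * (cf[2] + x * (cf[3] + x * cf[4]))
polyder3 <- function(cf, x) cf[2] + x * (2 * cf[3] + x * 3 * cf[4])

#' Fit a cubic to one sagittal cartilage cross-section
#'
#' Least-squares third-order polynomial `z(x)` in physical in-plane mm. For
#' `role = "centerline"` the fit runs through all cartilage pixels of the
#' slice; for the surface roles it runs through the per-column distal or
#' proximal boundary pixels. Degree three avoids the edge oscillations that
#' higher degrees produce on cartilage outlines.
#'
#' @param x,z Pixel-center coordinates (mm) of the points to fit.
#' @param role `"centerline"`, `"distal"`, or `"proximal"`.
#' @return A `slice_polyfit`: coefficients (ascending powers), fit domain
#'   `[x_min, x_max]`, role. Slices with fewer than 5 distinct x positions or
#'   rank-deficient fits raise a skip condition (`cartthick_slice_skip`).
#' @export
fit_slice_polynomial <- function(x, z, role = c("centerline", "distal",
                                                "proximal")) {
  role <- match.arg(role)
  if (length(unique(x)) < 5) {
    abort("fewer than 5 distinct x positions in slice.",
          class = c("cartthick_slice_skip", "cartthick_error"))
  }
  fit <- lm(z ~ x + I(x^2) + I(x^3))
  cf <- coef(fit)
  if (any(is.na(cf))) {
    abort("rank-deficient cubic fit in slice.",
          class = c("cartthick_slice_skip", "cartthick_error"))
  }
  structure(list(coefficients = unname(cf), domain = range(x), role = role),
            class = "slice_polyfit")
}

#' @export
predict.slice_polyfit <- function(object, x, ...) {
  polyval3(object$coefficients, x)
}

# Split a femoral voxel set into working parts exactly as the surface module
# does: anterior+central unrotated, posterior rotated 90 degrees about y.
# Returns a list of parts, each with points in its working frame plus a
# back-mapping closure to original physical coordinates.
slice_parts <- function(points, posterior = NULL) {
  sp <- attr(points, "spacing")
  if (is.null(posterior) || !any(posterior)) {
    return(list(list(points = points, spacing = sp,
                     to_original = function(x, y, z) cbind(x, y, z))))
  }
  if (is.character(posterior)) posterior <- grepl("^p", posterior)
  k_ref <- max(points$k)
  ac <- points[!posterior, , drop = FALSE]
  po <- points[posterior, , drop = FALSE]
  parts <- list()
  if (nrow(ac) > 0) {
    attr(ac, "spacing") <- sp
    parts$anterior_central <- list(points = ac, spacing = sp,
                                   to_original = function(x, y, z) cbind(x, y, z))
  }
  if (nrow(po) > 0) {
    rot <- rotate_indices_90y(po$i, po$k, k_ref)
    po_r <- voxel_points(rot$i, po$j, rot$k, c(sp[3], sp[2], sp[1]))
    parts$posterior <- list(
      points = po_r, spacing = c(sp[3], sp[2], sp[1]),
      # continuous inverse of the index rotation (equal x/z spacing)
      to_original = function(x, y, z) cbind(z, y, k_ref * sp[3] - x))
  }
  parts
}

# Occupancy lookup table for one slice part: logical matrix over (i, k).
slice_occupancy <- function(px) {
  i0 <- min(px$i); k0 <- min(px$k)
  M <- matrix(FALSE, max(px$i) - i0 + 1L, max(px$k) - k0 + 1L)
  M[cbind(px$i - i0 + 1L, px$k - k0 + 1L)] <- TRUE
  list(M = M, i0 = i0, k0 = k0)
}

#' 2D centerline-normal thickness (2D-CN)
#'
#' Per sagittal slice, fits a cubic centerline through all cartilage pixels
#' and, for every integer x position in the fit domain, marches along the
#' centerline normal in both directions in 0.1-pixel steps. The two outline
#' intersection points are the extreme cartilage pixels crossed by the normal
#' (the contiguous occupied run containing, or nearest to, the centerline
#' point); thickness is their distance. Samples are assigned via the more
#' distal intersection point.
#'
#' @param points Voxel point set of one cartilage structure.
#' @param parc Optional [parcellate_knee()] result for subregion assignment.
#' @param posterior Optional logical/subregion-id vector marking posterior
#'   femoral voxels (rotated in-slice before fitting).
#' @param max_thickness Marching range and discard cap (mm).
#' @param march_frac Marching step as a fraction of the in-plane pixel size.
#' @return A `thickness_samples` tibble; `failures` counts skipped slices and
#'   normals that never crossed cartilage.
#' @export
thickness_centerline_2d <- function(points, parc = NULL, posterior = NULL,
                                    max_thickness = 15, march_frac = 0.1) {
  parts <- slice_parts(points, posterior)
  res <- list()
  skipped_slices <- 0L
  no_cross <- 0L
  for (pi_ in seq_along(parts)) {
    part <- parts[[pi_]]
    sp <- part$spacing
    delta <- march_frac * sp[1]
    n_steps <- ceiling(max_thickness / (2 * delta))
    m_rel <- seq(-n_steps, n_steps) * delta
    ctr_idx <- n_steps + 1L
    for (px in split(part$points, part$points$j)) {
      fitres <- tryCatch(
        fit_slice_polynomial(px$i * sp[1], px$k * sp[3], "centerline"),
        cartthick_slice_skip = function(e) NULL)
      if (is.null(fitres)) { skipped_slices <- skipped_slices + 1L; next }
      occ <- slice_occupancy(px)
      yv <- px$j[1] * sp[2]
      for (ii in seq(min(px$i), max(px$i))) {
        x0 <- ii * sp[1]
        z0 <- polyval3(fitres$coefficients, x0)
        slope <- polyder3(fitres$coefficients, x0)
        u <- c(-slope, 1) / sqrt(1 + slope^2)
        xs <- x0 + m_rel * u[1]
        zs <- z0 + m_rel * u[2]
        ci <- as.integer(round(xs / sp[1])) - occ$i0 + 1L
        ck <- as.integer(round(zs / sp[3])) - occ$k0 + 1L
        inb <- ci >= 1L & ci <= nrow(occ$M) & ck >= 1L & ck <= ncol(occ$M)
        inside <- logical(length(m_rel))
        inside[inb] <- occ$M[cbind(ci[inb], ck[inb])]
        if (!any(inside)) { no_cross <- no_cross + 1L; next }
        r <- rle(inside)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        runs <- which(r$values)
        # the run containing the centerline point, else the nearest run
        hit <- runs[starts[runs] <= ctr_idx & ends[runs] >= ctr_idx]
        if (length(hit) == 0) {
          dist_to_ctr <- pmin(abs(starts[runs] - ctr_idx),
                              abs(ends[runs] - ctr_idx))
          hit <- runs[which.min(dist_to_ctr)]
        }
        a <- starts[hit[1]]
        b <- ends[hit[1]]
        p1 <- c(xs[a], zs[a])
        p2 <- c(xs[b], zs[b])
        val <- sqrt(sum((p1 - p2)^2))
        if (val > max_thickness) { no_cross <- no_cross + 1L; next }
        # more distal endpoint = larger z in the working frame
        pd <- if (p1[2] >= p2[2]) p1 else p2
        entry <- c(pd[1], yv, pd[2], val)
        if (length(parts) > 1) entry <- c(entry, pi_)
        res[[length(res) + 1L]] <- entry
      }
    }
  }
  if (length(res) == 0) {
    stop_cartthick("2D-CN produced no thickness samples.",
                   "cartthick_method_failure_error")
  }
  build_2d_samples(res, parts, parc,
                   c(skipped_slices = skipped_slices, no_crossing = no_cross))
}

# Shared assembly: res entries are (x_work, y, z_work, value) per part order;
# because parts are processed sequentially we re-map working coordinates to
# the original frame with each part's closure. To keep it simple the entries
# store working coords tagged by part index.
build_2d_samples <- function(res, parts, parc, failures) {
  m <- do.call(rbind, res)
  # part index was appended as 5th column when more than one part exists
  if (ncol(m) == 5) {
    orig <- matrix(NA_real_, nrow(m), 3)
    for (p in seq_along(parts)) {
      sel <- m[, 5] == p
      if (any(sel)) {
        orig[sel, ] <- parts[[p]]$to_original(m[sel, 1], m[sel, 2], m[sel, 3])
      }
    }
  } else {
    orig <- parts[[1]]$to_original(m[, 1], m[, 2], m[, 3])
  }
  colnames(orig) <- c("x", "y", "z")
  new_thickness_samples(
    tibble::tibble(x = orig[, 1], y = orig[, 2], z = orig[, 3],
                   thickness = m[, 4],
                   subregion = maybe_assign(parc, orig)),
    failures = failures)
}

#' 2D surface-normal thickness (2D-SN)
#'
#' Per sagittal slice, fits separate cubics to the distal and proximal
#' cartilage outlines (per-column boundary pixels) and, for every integer x
#' position, intersects the distal-fit normal with the proximal cubic by
#' exact cubic root finding. Among real roots on the proximal side of the
#' distal surface within the extended fit domain, the nearest intersection is
#' taken; thickness is the distance from `(x, fd(x))` to it.
#'
#' @inheritParams thickness_centerline_2d
#' @param domain_margin Allowed extrapolation beyond the fit domain for the
#'   intersection point, in pixels.
#' @return A `thickness_samples` tibble; `failures` counts skipped slices and
#'   normals without a usable real root.
#' @export
thickness_surface_normals_2d <- function(points, parc = NULL, posterior = NULL,
                                         max_thickness = 15,
                                         domain_margin = 2) {
  parts <- slice_parts(points, posterior)
  res <- list()
  skipped_slices <- 0L
  no_root <- 0L
  for (pi_ in seq_along(parts)) {
    part <- parts[[pi_]]
    sp <- part$spacing
    margin <- domain_margin * sp[1]
    for (px in split(part$points, part$points$j)) {
      cols <- dplyr::summarise(dplyr::group_by(px, .data$i),
                               k_min = min(.data$k), k_max = max(.data$k),
                               .groups = "drop")
      fd <- tryCatch(
        fit_slice_polynomial(cols$i * sp[1], cols$k_max * sp[3], "distal"),
        cartthick_slice_skip = function(e) NULL)
      fp <- tryCatch(
        fit_slice_polynomial(cols$i * sp[1], cols$k_min * sp[3], "proximal"),
        cartthick_slice_skip = function(e) NULL)
      if (is.null(fd) || is.null(fp)) { skipped_slices <- skipped_slices + 1L; next }
      yv <- px$j[1] * sp[2]
      dom <- c(min(cols$i) * sp[1] - margin, max(cols$i) * sp[1] + margin)
      for (ii in seq(min(cols$i), max(cols$i))) {
        x0 <- ii * sp[1]
        z0 <- polyval3(fd$coefficients, x0)
        slope <- polyder3(fd$coefficients, x0)
        nrm <- sqrt(1 + slope^2)
        u <- c(slope, -1) / nrm   # unit normal pointing toward proximal (-z)
        # fp(x0 + s*ux) - (z0 + s*uz) = 0, expanded as a cubic in s
        p1 <- c(x0, u[1])                      # X as linear poly in s
        p2 <- poly_mul(p1, p1)
        p3 <- poly_mul(p2, p1)
        cf <- fp$coefficients
        g <- numeric(4)
        g[1] <- cf[1] - z0
        g[2] <- -u[2]
        g[1:2] <- g[1:2] + cf[2] * p1
        g[1:3] <- g[1:3] + cf[3] * p2
        g[1:4] <- g[1:4] + cf[4] * p3
        s_int <- solve_poly_real(g)
        if (length(s_int) > 0) {
          x_int <- x0 + s_int * u[1]
          valid <- s_int > 1e-9 & s_int <= max_thickness &
            x_int >= dom[1] & x_int <= dom[2]
          s_int <- s_int[valid]
          x_int <- x_int[valid]
        }
        if (length(s_int) == 0) { no_root <- no_root + 1L; next }
        ord <- order(s_int, abs(x_int - x0))
        val <- s_int[ord[1]]
        entry <- c(x0, yv, z0, val)
        if (length(parts) > 1) entry <- c(entry, pi_)
        res[[length(res) + 1L]] <- entry
      }
    }
  }
  if (length(res) == 0) {
    stop_cartthick("2D-SN produced no thickness samples.",
                   "cartthick_method_failure_error")
  }
  build_2d_samples(res, parts, parc,
                   c(skipped_slices = skipped_slices, no_root = no_root))
}

# ascending-power polynomial product
poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# real roots of an ascending-power polynomial via polyroot, trimming
# negligible leading coefficients
solve_poly_real <- function(cf, tol = 1e-10) {
  scale <- max(abs(cf), 1e-300)
  while (length(cf) > 1 && abs(cf[length(cf)]) < tol * scale) {
    cf <- cf[-length(cf)]
  }
  if (length(cf) <= 1) return(numeric(0))
  r <- polyroot(cf)
  Re(r[abs(Im(r)) < 1e-6 * (1 + abs(r))])
}
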