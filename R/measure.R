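#' Thickness method names
#' @return Character vector of the five method identifiers.
#' @export
thickness_methods <- function() c("3D-MN", "3D-NN", "3D-RT", "2D-CN", "2D-SN")

#' Measure cartilage thickness across a whole knee
#'
#' Runs the selected measurement methods on a segmented knee containing both
#' femoral and tibial cartilage: parcellation, surface extraction (with the
#' posterior-femur rotation), then each method. Returns one tidy tibble of
#' per-point thickness samples ready for [summarize_thickness()].
#'
#' @param x A [label_volume()] with femoral and tibial cartilage, or a
#'   `cart_phantom` (e.g. [make_knee_phantom()]).
#' @param methods Subset of [thickness_methods()].
#' @param knee_id Identifier recorded in the `knee` column.
#' @param parc Optional precomputed [parcellate_knee()] result.
#' @param medial_side Passed to [parcellate_knee()].
#' @param max_thickness Discard-and-count cap (mm) applied by all methods.
#' @param rt_args Named list of overrides for [place_ray_spheres()] (e.g.
#'   `radius`, `tibial_offset`, `n_polar`).
#' @return A `thickness_samples` tibble with columns `knee, method, structure,
#'   subregion, region, x, y, z, thickness`; attribute `failures` is a named
#'   list (per method) of failed/skipped measurement counts.
#' @export
#' @examples
#' \donttest{
#' ph <- make_knee_phantom()
#' samples <- measure_thickness(ph, methods = c("3D-NN"))
#' dplyr::count(samples, method, region)
#' }
measure_thickness <- function(x, methods = thickness_methods(),
                              knee_id = "knee", parc = NULL,
                              medial_side = "low-y", max_thickness = 15,
                              rt_args = list()) {
  methods <- match.arg(methods, thickness_methods(), several.ok = TRUE)
  vol <- if (inherits(x, "cart_phantom")) x$volume else x
  stopifnot(inherits(vol, "label_volume"))
  parc <- parc %||% parcellate_knee(vol, medial_side)

  pts_of <- function(structure) {
    p <- parc$voxels[parc$voxels$structure == structure, , drop = FALSE]
    attr(p, "spacing") <- parc$spacing
    p
  }
  tibia <- pts_of("tibia")
  femur <- pts_of("femur")
  fem_posterior <- grepl("^p", femur$subregion)

  needs_surfaces <- any(c("3D-MN", "3D-NN") %in% methods)
  tib_surf <- fem_surf <- NULL
  if (needs_surfaces) {
    tib_surf <- extract_surfaces_tibia(tibia)
    fem_surf <- extract_surfaces_femur(femur, fem_posterior)
  }

  out <- list()
  failures <- list()
  add <- function(samples, method, structure) {
    samples$method <- method
    samples$structure <- structure
    out[[length(out) + 1L]] <<- samples
    f <- attr(samples, "failures")
    if (length(f) > 0) {
      failures[[method]] <<- c(failures[[method]], stats::setNames(
        as.integer(f), paste0(structure, ".", names(f))))
    }
  }

  if ("3D-MN" %in% methods) {
    mn_pair <- function(pair) {
      thickness_mesh_normals(build_mesh(pair$distal), build_mesh(pair$proximal),
                             parc, max_thickness)
    }
    add(mn_pair(tib_surf), "3D-MN", "tibia")
    fem_parts <- Filter(Negate(is.null),
                        list(fem_surf$anterior_central, fem_surf$posterior))
    fem_res <- lapply(fem_parts, mn_pair)
    fem_fail <- Reduce(`+`, lapply(fem_res, attr, "failures"))
    add(new_thickness_samples(dplyr::bind_rows(fem_res), fem_fail),
        "3D-MN", "femur")
  }
  if ("3D-NN" %in% methods) {
    add(thickness_nearest_neighbors(tib_surf, parc, max_thickness),
        "3D-NN", "tibia")
    add(thickness_nearest_neighbors(fem_surf, parc, max_thickness),
        "3D-NN", "femur")
  }
  if ("3D-RT" %in% methods) {
    config <- do.call(place_ray_spheres, c(list(parc = parc), rt_args))
    rt <- thickness_ray_tracing(parc, config, max_thickness = max_thickness)
    rt$structure <- ifelse(rt$sphere %in% c("LT", "MT"), "tibia", "femur")
    rt$sphere <- NULL
    for (st in unique(rt$structure)) {
      sub <- rt[rt$structure == st, , drop = FALSE]
      add(new_thickness_samples(sub[, c("x", "y", "z", "thickness", "subregion")],
                                NULL), "3D-RT", st)
    }
    failures[["3D-RT"]] <- attr(rt, "failures")
  }
  if ("2D-CN" %in% methods) {
    add(thickness_centerline_2d(tibia, parc, NULL, max_thickness),
        "2D-CN", "tibia")
    add(thickness_centerline_2d(femur, parc, fem_posterior, max_thickness),
        "2D-CN", "femur")
  }
  if ("2D-SN" %in% methods) {
    add(thickness_surface_normals_2d(tibia, parc, NULL, max_thickness),
        "2D-SN", "tibia")
    add(thickness_surface_normals_2d(femur, parc, fem_posterior, max_thickness),
        "2D-SN", "femur")
  }

  res <- dplyr::bind_rows(out)
  res$knee <- knee_id
  res$region <- ifelse(is.na(res$subregion), NA_character_,
                       region_of(res$subregion))
  res <- dplyr::select(res, "knee", "method", "structure", "subregion",
                       "region", "x", "y", "z", "thickness")
  new_thickness_samples(res, failures)
}
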