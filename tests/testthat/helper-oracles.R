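# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use the simplest possible implementation (linear scans, explicit formulas)
# so they stay independent of the package's vectorized/compiled code paths.

# Internal constructor used to build hand-crafted voxel point sets.
voxel_points <- cartthick:::voxel_points

# Brute-force nearest-neighbor distances: O(n * m) double loop.
nn_bruteforce <- function(from, to) {
  vapply(seq_len(nrow(from)), function(i) {
    min(sqrt((to[, 1] - from[i, 1])^2 + (to[, 2] - from[i, 2])^2 +
               (to[, 3] - from[i, 3])^2))
  }, numeric(1))
}

# Brute-force tibial quadrant classification by angle about the cylinder
# center (45-degree diagonals; anterior faces -x, internal faces the midline).
quadrant_bruteforce <- function(x, y, cx, cy, internal_sign) {
  vapply(seq_along(x), function(ii) {
    dx <- x[ii] - cx
    dyp <- (y[ii] - cy) * internal_sign
    if (abs(dx) >= abs(dyp)) {
      if (dx < 0) "a" else "p"
    } else {
      if (dyp > 0) "i" else "e"
    }
  }, character(1))
}

# Direct single-pass evaluation of the pooled 5-SD outlier rule.
outlier_bruteforce <- function(summary_df, n_sd = 5) {
  df <- summary_df[summary_df$level == "subregion", ]
  flagged <- character(0)
  for (nm in unique(df$name)) {
    v <- df[df$name == nm, ]
    m <- mean(v$mean_thickness)
    s <- sd(v$mean_thickness)
    if (is.na(s) || s == 0) next
    bad <- abs(v$mean_thickness - m) > n_sd * s
    flagged <- c(flagged, v$knee[bad])
  }
  unique(flagged)
}

# A small cohort of per-knee subregional summaries shaped like
# summarize_thickness() output, with a knee-level random effect.
make_null_cohort <- function(n_knees = 6, methods = c("A", "B", "C"),
                             subregions = c("cLT", "cMT"), sd_knee = 0.3,
                             sd_noise = 0.05, base = 2) {
  grid <- expand.grid(knee = paste0("k", seq_len(n_knees)), method = methods,
                      name = subregions, stringsAsFactors = FALSE)
  knee_effect <- stats::setNames(rnorm(n_knees, 0, sd_knee),
                                 paste0("k", seq_len(n_knees)))
  tibble::tibble(
    knee = grid$knee, method = grid$method, level = "subregion",
    name = grid$name,
    mean_thickness = base + knee_effect[grid$knee] +
      rnorm(nrow(grid), 0, sd_noise),
    n_samples = 100L)
}

# Small knee phantom used across tests (fast to generate and measure).
small_knee_phantom <- function(...) {
  make_knee_phantom(plate_extent = c(20, 14), femoral_radius = 12,
                    plate_gap = 5, ...)
}

# One full five-method knee measurement, computed once per test session.
.fixture_cache <- new.env(parent = emptyenv())
knee_measurement_fixture <- function() {
  if (is.null(.fixture_cache$knee)) {
    ph <- small_knee_phantom()
    .fixture_cache$knee <- list(
      phantom = ph,
      samples = measure_thickness(ph, knee_id = "fixture"))
  }
  .fixture_cache$knee
}
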