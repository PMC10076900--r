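#' Full inter-method agreement analysis over a cohort
#'
#' Applies the 5-SD outlier screen (whole-knee removal), then for every
#' (sub)region and the global level runs the repeated-measures ANOVA with
#' Tukey-Kramer post hoc tests at the family-wise alpha, and computes
#' Bland-Altman limits of agreement and Lin's CCC for every method pair on
#' the paired per-knee means. Regions with missing values use complete cases
#' for that region only.
#'
#' @param cohort_summary [summarize_thickness()] rows for >= 3 knees and
#'   >= 2 methods.
#' @param alpha Family-wise significance threshold (default 0.01).
#' @param n_sd Outlier threshold in pooled SDs (default 5).
#' @return An `agreement_report`: list with `anova` (per level/name omnibus
#'   results), `pairwise` (per level/name and method pair: Tukey-adjusted p,
#'   mean difference, Bland-Altman bias and limits, CCC), `outliers`,
#'   `alpha`, `n_knees_used`.
#' @export
compare_methods <- function(cohort_summary, alpha = 0.01, n_sd = 5) {
  knees <- unique(cohort_summary$knee)
  methods <- unique(cohort_summary$method)
  if (length(knees) < 3 || length(methods) < 2) {
    stop_cartthick("agreement analysis needs >= 3 knees and >= 2 methods.",
                   "cartthick_insufficient_data_error")
  }
  outliers <- detect_outlier_knees(cohort_summary, n_sd = n_sd)
  clean <- cohort_summary[!cohort_summary$knee %in% outliers, , drop = FALSE]
  groups <- unique(clean[, c("level", "name")])
  anova_rows <- list()
  pair_rows <- list()
  for (g in seq_len(nrow(groups))) {
    sub <- clean[clean$level == groups$level[g] & clean$name == groups$name[g], ]
    df <- tibble::tibble(knee = sub$knee, method = sub$method,
                         value = sub$mean_thickness)
    fit <- tryCatch(rm_anova_tukey(df),
                    cartthick_error = function(e) NULL)
    if (is.null(fit)) next
    anova_rows[[g]] <- dplyr::mutate(fit$anova,
                                     level = groups$level[g],
                                     name = groups$name[g],
                                     significant = .data$p.value < alpha)
    wide <- tidyr::pivot_wider(df, names_from = "method",
                               values_from = "value")
    wide <- wide[complete.cases(wide), , drop = FALSE]
    pw <- fit$pairwise
    ba <- purrr::map2_dfr(pw$method1, pw$method2, function(m1, m2) {
      res <- bland_altman(wide[[m1]], wide[[m2]])
      res$ccc <- tryCatch(lin_ccc(wide[[m1]], wide[[m2]]),
                          cartthick_error = function(e) NA_real_)
      res
    })
    pair_rows[[g]] <- dplyr::bind_cols(
      tibble::tibble(level = groups$level[g], name = groups$name[g]),
      pw, dplyr::select(ba, ba_bias = "bias", ba_lower = "lower",
                        ba_upper = "upper", "ccc"))
  }
  structure(list(
    anova = dplyr::bind_rows(anova_rows),
    pairwise = dplyr::bind_rows(pair_rows),
    outliers = as.character(outliers),
    outlier_details = attr(outliers, "details"),
    alpha = alpha,
    n_knees_used = length(setdiff(knees, outliers))
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> ", x$n_knees_used, " knees (",
      length(x$outliers), " outlier(s) removed), family-wise alpha = ",
      x$alpha, "\n", sep = "")
  cat("significant (sub)regions: ", sum(x$anova$significant), " of ",
      nrow(x$anova), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise agreement table
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return The per-(sub)region, per-method-pair tibble (Tukey-adjusted p,
#'   mean difference, Bland-Altman bias/limits, CCC).
#' @export
tidy.agreement_report <- function(x, ...) x$pairwise

#' One-row summary of an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return Tibble with knee/outlier counts, number of tested (sub)regions,
#'   number significant at the family-wise alpha, and the CCC range.
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(
    n_knees = x$n_knees_used,
    n_outliers = length(x$outliers),
    n_groups = nrow(x$anova),
    n_significant = sum(x$anova$significant),
    alpha = x$alpha,
    min_ccc = suppressWarnings(min(x$pairwise$ccc, na.rm = TRUE)),
    max_ccc = suppressWarnings(max(x$pairwise$ccc, na.rm = TRUE)))
}

#' Plot a thickness-sample map
#'
#' Scatter of sample origins in the sagittal (x-z) plane, colored by local
#' thickness, faceted by method when several are present. The z axis is
#' reversed so that head-to-feet runs downward, as in the scanner frame.
#'
#' @param object A `thickness_samples` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thickness_samples <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$z,
                                            colour = .data$thickness)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(name = "thickness (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (anteroposterior, mm)", y = "z (head-feet, mm)")
  if ("method" %in% names(object) && length(unique(object$method)) > 1) {
    p <- p + ggplot2::facet_wrap(~method)
  }
  p
}

#' Plot pairwise agreement (Bland-Altman bias and CCC)
#'
#' Bias points with limit-of-agreement bars per method pair, faceted by
#' (sub)region name, for the chosen level.
#'
#' @param object An `agreement_report`.
#' @param level Which summary level to show (default `"region"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, level = "region", ...) {
  df <- object$pairwise[object$pairwise$level == level, , drop = FALSE]
  df$pair <- paste(df$method1, "vs", df$method2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$ba_bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ba_lower,
                                          ymax = .data$ba_upper,
                                          colour = .data$ccc)) +
    ggplot2::scale_colour_viridis_c(name = "CCC", limits = c(-1, 1)) +
    ggplot2::facet_wrap(~name) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "bias and 95% limits of agreement (mm)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
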