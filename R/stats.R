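#' Summarize thickness samples globally, per region, and per subregion
#'
#' Unweighted arithmetic means of the per-point samples at three levels: the
#' entire joint (both bones pooled), the four regions (LT, MT, LF, MF), and
#' the twenty subregions. Samples without a subregion assignment contribute to
#' the global level only.
#'
#' @param samples A `thickness_samples` tibble (needs `method` and `thickness`
#'   columns; `knee` and `subregion` are used when present).
#' @return Tibble with `knee, method, level, name, mean_thickness, n_samples`.
#' @export
summarize_thickness <- function(samples) {
  df <- tibble::as_tibble(samples)
  if (nrow(df) == 0) {
    stop_cartthick("no thickness samples to summarize.",
                   "cartthick_insufficient_data_error")
  }
  if (!"knee" %in% names(df)) df$knee <- "knee"
  if (!"region" %in% names(df)) {
    df$region <- ifelse(is.na(df$subregion), NA_character_,
                        region_of(df$subregion))
  }
  glob <- dplyr::summarise(
    dplyr::group_by(df, .data$knee, .data$method),
    level = "global", name = "joint",
    mean_thickness = mean(.data$thickness), n_samples = dplyr::n(),
    .groups = "drop")
  reg <- dplyr::summarise(
    dplyr::group_by(df[!is.na(df$region), ], .data$knee, .data$method,
                    name = .data$region),
    level = "region",
    mean_thickness = mean(.data$thickness), n_samples = dplyr::n(),
    .groups = "drop")
  sub <- dplyr::summarise(
    dplyr::group_by(df[!is.na(df$subregion), ], .data$knee, .data$method,
                    name = .data$subregion),
    level = "subregion",
    mean_thickness = mean(.data$thickness), n_samples = dplyr::n(),
    .groups = "drop")
  dplyr::select(dplyr::bind_rows(glob, reg, sub),
                "knee", "method", "level", "name", "mean_thickness",
                "n_samples")
}

#' Count contributing measurements per bone and method
#'
#' @param samples A `thickness_samples` tibble.
#' @return Tibble with `method`, `structure`, `n_measurements`.
#' @export
count_measurements <- function(samples) {
  df <- tibble::as_tibble(samples)
  if (nrow(df) == 0) {
    return(tibble::tibble(method = character(), structure = character(),
                          n_measurements = integer()))
  }
  dplyr::count(df, .data$method, .data$structure, name = "n_measurements")
}

#' Screen a cohort for outlier knees (5-SD rule)
#'
#' For each subregion, the subregional mean thickness values of all methods
#' and all knees are pooled; a knee is flagged when any of its (method,
#' subregion) means lies more than `n_sd` standard deviations from the pooled
#' mean. Flagged knees are intended to be removed entirely from subsequent
#' analyses (single-pass semantics: the pooled statistics are computed once,
#' outliers included).
#'
#' @param cohort_summary [summarize_thickness()] rows for multiple knees.
#' @param n_sd Threshold in pooled standard deviations (default 5).
#' @return Character vector of flagged knee ids (empty when none); attribute
#'   `details` holds the offending rows with their z-scores.
#' @export
detect_outlier_knees <- function(cohort_summary, n_sd = 5) {
  df <- cohort_summary[cohort_summary$level == "subregion", , drop = FALSE]
  if (length(unique(df$knee)) < 2 || length(unique(df$method)) < 2) {
    stop_cartthick("need at least 2 knees and 2 methods for outlier screening.",
                   "cartthick_insufficient_data_error")
  }
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$name),
    pooled_mean = mean(.data$mean_thickness),
    pooled_sd = sd(.data$mean_thickness))
  df <- dplyr::ungroup(df)
  df$zscore <- ifelse(df$pooled_sd > 0,
                      (df$mean_thickness - df$pooled_mean) / df$pooled_sd, 0)
  bad <- df[abs(df$zscore) > n_sd, , drop = FALSE]
  out <- unique(bad$knee)
  attr(out, "details") <- bad
  out
}

#' One-way repeated-measures ANOVA with Tukey-Kramer post hoc tests
#'
#' Methods are the within-subject factor and knees the subjects. The omnibus
#' F uses the standard subject/method/error decomposition; the Tukey-Kramer
#' pairwise comparisons use the within-subject error term, with
#' multiplicity-adjusted p-values from the studentized range distribution.
#' Incomplete knees (missing any method) are dropped with a warning.
#'
#' @param df Tibble with columns `knee`, `method`, `value`.
#' @return An `rm_anova` object: list with `anova` (tibble: statistic, df,
#'   p.value, per-method means) and `pairwise` (tibble: method pair, mean
#'   difference, standard error, adjusted p).
#' @export
rm_anova_tukey <- function(df) {
  wide <- tidyr::pivot_wider(df[, c("knee", "method", "value")],
                             names_from = "method", values_from = "value")
  methods <- setdiff(names(wide), "knee")
  keep <- complete.cases(wide)
  if (any(!keep)) {
    warn(paste0(sum(!keep), " knee(s) dropped from ANOVA (incomplete methods)."))
    wide <- wide[keep, , drop = FALSE]
  }
  n <- nrow(wide)
  k <- length(methods)
  if (k < 2 || n < 3) {
    stop_cartthick("repeated-measures ANOVA needs >= 2 methods and >= 3 knees.",
                   "cartthick_insufficient_data_error")
  }
  m <- as.matrix(wide[, methods])
  grand <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_meth <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- max(ss_tot - ss_subj - ss_meth, 0)
  df1 <- k - 1L
  df2 <- (n - 1L) * (k - 1L)
  mse <- ss_err / df2
  if (ss_meth <= .Machine$double.eps * max(ss_tot, 1)) {
    f_stat <- 0
    p <- 1
  } else if (mse == 0) {
    f_stat <- Inf
    p <- 0
  } else {
    f_stat <- (ss_meth / df1) / mse
    p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  pairs <- utils::combn(methods, 2)
  cm <- colMeans(m)
  diffs <- cm[pairs[1, ]] - cm[pairs[2, ]]
  se <- sqrt(mse / n)
  if (se == 0) {
    p_adj <- ifelse(abs(diffs) > 0, 0, 1)
    q_stat <- ifelse(abs(diffs) > 0, Inf, 0)
  } else {
    q_stat <- abs(diffs) / se
    p_adj <- ptukey(q_stat, nmeans = k, df = df2, lower.tail = FALSE)
  }
  structure(list(
    anova = tibble::tibble(statistic = f_stat, df1 = df1, df2 = df2,
                           p.value = p, n_knees = n, n_methods = k,
                           ms_error = mse),
    means = tibble::tibble(method = methods, mean = unname(cm)),
    pairwise = tibble::tibble(method1 = pairs[1, ], method2 = pairs[2, ],
                              mean_diff = unname(diffs),
                              se = se, q = unname(q_stat),
                              p_adj = unname(p_adj))
  ), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures one-way ANOVA: F(", x$anova$df1, ", ", x$anova$df2,
      ") = ", format(x$anova$statistic, digits = 4), ", p = ",
      format.pval(x$anova$p.value, digits = 3), "\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' Bland-Altman agreement between two paired measurement series
#'
#' @param a,b Paired numeric vectors (e.g. per-knee mean thickness of two
#'   methods). Differences are `a - b`.
#' @param conf_mult Multiplier for the limits of agreement (1.96 for 95%).
#' @return One-row tibble: `bias`, `lower`, `upper` (limits of agreement),
#'   `sd_diff`, `n`.
#' @export
bland_altman <- function(a, b, conf_mult = 1.96) {
  if (length(a) != length(b)) {
    stop_cartthick("Bland-Altman requires paired series of equal length.",
                   "cartthick_pairing_error")
  }
  if (length(a) < 2) {
    stop_cartthick("Bland-Altman requires at least 2 pairs.",
                   "cartthick_insufficient_data_error")
  }
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  tibble::tibble(bias = bias, lower = bias - conf_mult * s,
                 upper = bias + conf_mult * s, sd_diff = s,
                 n = length(d))
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(a, b) / (var(a) + var(b) + (mean(a) - mean(b))^2)` with
#' population (1/n) moments, penalizing both dispersion and location shift.
#'
#' @param a,b Paired numeric vectors.
#' @return CCC in `[-1, 1]`.
#' @export
lin_ccc <- function(a, b) {
  if (length(a) != length(b)) {
    stop_cartthick("CCC requires paired series of equal length.",
                   "cartthick_pairing_error")
  }
  n <- length(a)
  if (n < 2) {
    stop_cartthick("CCC requires at least 2 pairs.",
                   "cartthick_insufficient_data_error")
  }
  va <- mean((a - mean(a))^2)
  vb <- mean((b - mean(b))^2)
  if (va == 0 && vb == 0) {
    stop_cartthick("CCC undefined: both series have zero variance.",
                   "cartthick_insufficient_data_error")
  }
  cab <- mean((a - mean(a)) * (b - mean(b)))
  2 * cab / (va + vb + (mean(a) - mean(b))^2)
}
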