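#' @useDynLib cartthick, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom stats lm coef predict sd var quantile pf ptukey complete.cases
#' @importFrom utils head
NULL

# Internal condition helpers: every user-facing failure carries a condition
# class so the CLI can map it to a distinct exit code.
stop_cartthick <- function(msg, class, ...) {
  abort(msg, class = c(class, "cartthick_error"), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unit-normalize rows of an n x 3 matrix; zero rows stay zero.
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

assert_spacing <- function(spacing) {
  if (!is.numeric(spacing) || length(spacing) != 3 || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop_cartthick("`spacing` must be three positive voxel sizes in mm (x, y, z).",
                   "cartthick_metadata_error")
  }
  as.numeric(spacing)
}
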