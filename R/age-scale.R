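#' Progressive percentile profile of the hypothetical reference
#'
#' The hypothetical (HYP) reference curve follows an age-increasing
#' percentile profile instead of a fixed centile: linear from the 0.5th
#' percentile at age 19 to the 99.5th percentile at age 99 (1.2375% per
#' year), held at those boundary percentiles over \[18, 19) and (99, 100\].
#' The profile is not defined, and not extrapolated, outside \[18, 100\].
#'
#' @param age Ages in years, within \[18, 100\].
#' @return Percentile(s) in \[0.005, 0.995\].
#' @export
#' @examples
#' hyp_percentile_profile(c(19, 59, 99)) # 0.005, 0.500, 0.995
hyp_percentile_profile <- function(age) {
  if (any(age < 18 | age > 100))
    stop("the hypothetical reference profile is only defined for ages ",
         "in [18, 100]", call. = FALSE)
  p <- 0.005 + (0.995 - 0.005) / (99 - 19) * (age - 19)
  pmin(pmax(p, 0.005), 0.995)
}

#' Build a monotone reference curve for EYOL computation
#'
#' Evaluates either the median (P50) of a fitted centile model or the
#' hypothetical composite (the model's quantile at
#' [hyp_percentile_profile()] for each age, pinned to IMMAX 0 at age 18 and
#' 1 at age 100) on a fine age grid, enforces monotonicity by isotonic
#' regression (pool-adjacent-violators), clips to \[0, 1\], and attaches
#' per-year extrapolation slopes estimated from the outer five grid-years.
#' NQR models cannot back a reference curve because their spline basis
#' does not extrapolate; the HYP composite needs the distributional (LMS)
#' model because it evaluates arbitrary percentiles.
#'
#' @param model A `centile_model` (LMS or LQR).
#' @param kind `"P50"` (default) or `"HYP"`.
#' @param age_grid Evaluation grid (default 18 to 100 by 0.1 years).
#' @return A `reference_curve` with fields `kind` (`LMS_P50`, `LQR_P50` or
#'   `HYP`), `age_grid`, `values`, `left_slope`, `right_slope`,
#'   `provenance`.
#' @export
build_reference <- function(model, kind = c("P50", "HYP"),
                            age_grid = seq(18, 100, by = 0.1)) {
  kind <- match.arg(kind)
  stopifnot(inherits(model, "centile_model"))
  if (model$algorithm == "NQR")
    stop("NQR models cannot define a reference curve: their spline ",
         "quantile curves cannot be extrapolated beyond the data range",
         call. = FALSE)
  if (is.unsorted(age_grid, strictly = TRUE) || length(age_grid) < 10L)
    stop("age_grid must be a strictly increasing grid of at least 10 ages",
         call. = FALSE)
  if (kind == "P50") {
    values <- as.numeric(predict_quantiles(model, age_grid, taus = 0.5))
    label <- paste0(model$algorithm, "_P50")
  } else {
    if (model$algorithm != "LMS")
      stop("the hypothetical (HYP) composite requires the distributional ",
           "(LMS) model to evaluate arbitrary percentiles", call. = FALSE)
    if (age_grid[1] < 18 || age_grid[length(age_grid)] > 100)
      stop("the HYP reference is only defined on [18, 100]", call. = FALSE)
    p <- hyp_percentile_profile(age_grid)
    values <- vapply(seq_along(age_grid),
                     function(i) lms_quantile(model, age_grid[i], p[i]), 0)
    values[age_grid == 18] <- 0
    values[age_grid == 100] <- 1
    label <- "HYP"
  }
  values <- pmin(pmax(stats::isoreg(age_grid, values)$yf, 0), 1)
  span <- 5
  li <- which.min(abs(age_grid - (age_grid[1] + span)))
  ri <- which.min(abs(age_grid - (age_grid[length(age_grid)] - span)))
  ref <- list(kind = label, age_grid = age_grid, values = values,
              left_slope = (values[li] - values[1]) / (age_grid[li] - age_grid[1]),
              right_slope = (values[length(values)] - values[ri]) /
                (age_grid[length(age_grid)] - age_grid[ri]),
              provenance = list(algorithm = model$algorithm, kind = kind,
                                age_range = model$age_range))
  class(ref) <- "reference_curve"
  ref
}

#' Equivalent years of life (EYOL)
#'
#' Inverts a monotone reference curve: the EYOL of an IMMAX value is the
#' chronological age at which the reference curve attains that value.
#' Within the curve's range the grid is linearly interpolated; on flat
#' segments the midpoint of the matching age interval is returned; values
#' beyond the curve's range are mapped by linear extrapolation with the
#' curve's boundary slopes and may legitimately fall above 100 or below 18
#' (even negative) years.
#'
#' @param ref A `reference_curve`.
#' @param immax IMMAX value(s) in \[0, 1\].
#' @return Age(s) in years.
#' @export
eyol <- function(ref, immax) {
  stopifnot(inherits(ref, "reference_curve"))
  if (any(immax < 0 | immax > 1))
    stop("immax must lie in [0, 1]", call. = FALSE)
  v <- ref$values; a <- ref$age_grid; n <- length(v)
  vapply(immax, function(x) {
    if (x < v[1]) {
      if (!is.finite(ref$left_slope) || ref$left_slope <= 0)
        stop("IMMAX ", format(x), " lies below the reference curve and the ",
             "left extrapolation slope is degenerate", call. = FALSE)
      return(a[1] - (v[1] - x) / ref$left_slope)
    }
    if (x > v[n]) {
      if (!is.finite(ref$right_slope) || ref$right_slope <= 0)
        stop("IMMAX ", format(x), " lies above the reference curve and the ",
             "right extrapolation slope is degenerate", call. = FALSE)
      return(a[n] + (x - v[n]) / ref$right_slope)
    }
    hits <- which(v == x)
    if (length(hits)) return((a[hits[1]] + a[hits[length(hits)]]) / 2)
    j <- findInterval(x, v)  # v[j] < x < v[j+1]
    a[j] + (x - v[j]) / (v[j + 1] - v[j]) * (a[j + 1] - a[j])
  }, 0)
}

#' Immunological age gap
#'
#' Difference between EYOL and chronological age: positive values mark
#' fast (accelerated), negative values slow (decelerated) immunological
#' aging relative to the reference population.
#'
#' @inheritParams eyol
#' @param age Chronological age(s) in years.
#' @return Age gap(s) in years, exactly `eyol(ref, immax) - age`.
#' @export
age_gap <- function(ref, immax, age) {
  eyol(ref, immax) - age
}

#' @export
print.reference_curve <- function(x, ...) {
  cat(sprintf("%s reference curve on [%.1f, %.1f] (IMMAX %.3f to %.3f)\n",
              x$kind, x$age_grid[1], x$age_grid[length(x$age_grid)],
              x$values[1], x$values[length(x$values)]))
  cat(sprintf("  extrapolation slopes: left %.5f, right %.5f per year\n",
              x$left_slope, x$right_slope))
  invisible(x)
}
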