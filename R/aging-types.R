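#' Rate subjects into the six immunological aging types
#'
#' Classifies each (age, IMMAX) pair against the five fitted percentile
#' curves of one model into the ordered categories 1 (slowest aging, below
#' P03) to 6 (fastest, at or above P97). Boundaries are half-open upward: a
#' value exactly on a curve belongs to the category above it, so a subject
#' sitting exactly on P50 is rated 4 (mildly fast).
#'
#' @param model A `centile_model` fitted at five taus.
#' @param age Ages in years.
#' @param y IMMAX values in \[0, 1\], same length as `age`.
#' @return Integer ratings in 1..6.
#' @export
rate_aging_type <- function(model, age, y) {
  stopifnot(inherits(model, "centile_model"))
  if (length(age) != length(y))
    stop("age and y must have equal length", call. = FALSE)
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]", call. = FALSE)
  Q <- predict_quantiles(model, age)
  as.integer(1L + rowSums(Q <= y))
}

#' Confusion matrix and rank correlation of two aging-type ratings
#'
#' Cross-tabulates two ratings of the same subjects as joint proportions
#' (summing to 1) over the 6 x 6 category grid, with Spearman's rank
#' correlation of the ordinal codes.
#'
#' @param a,b Integer ratings in 1..6, equal length, same subjects.
#' @return A list with `proportions` (6 x 6 matrix) and `rho`.
#' @export
rating_confusion <- function(a, b) {
  if (length(a) != length(b))
    stop("ratings must have equal length", call. = FALSE)
  if (any(c(a, b) < 1 | c(a, b) > 6))
    stop("ratings must be categories 1..6", call. = FALSE)
  tab <- table(factor(a, levels = 1:6), factor(b, levels = 1:6))
  rho <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
         else stats::cor(a, b, method = "spearman")
  list(proportions = unclass(tab / length(a)), rho = rho)
}

#' Krippendorff's alpha for aging-type agreement
#'
#' Chance-corrected agreement `alpha = 1 - D_o / D_e` between two or more
#' raters of the same units, where `D_o` is the observed disagreement over
#' all pairable values within units and `D_e` the disagreement expected if
#' codes were assigned by chance with the observed marginal frequencies.
#' Both are computed from the coincidence matrix; the ordinal difference
#' function weights a disagreement between categories c and k by the
#' squared mass of codes lying between them (cumulative marginals), the
#' nominal one scores all disagreements equally. Units with fewer than two
#' non-missing codes contribute nothing.
#'
#' @param codes Units x raters matrix (or data frame) of integer category
#'   codes, `NA` for missing ratings.
#' @param metric `"ordinal"` (default; the aging types are ordered) or
#'   `"nominal"`.
#' @return An `agreement_result` with `alpha`, `D_o`, `D_e`, `metric`, and
#'   empty CI slots (see [alpha_bootstrap_ci()]).
#' @export
#' @examples
#' codes <- cbind(r1 = c(1, 2, 3, 3), r2 = c(1, 2, 3, 4))
#' krippendorff_alpha(codes, metric = "nominal")$alpha # 32/46
krippendorff_alpha <- function(codes, metric = c("ordinal", "nominal")) {
  metric <- match.arg(metric)
  codes <- as.matrix(codes)
  if (ncol(codes) < 2L || nrow(codes) < 2L)
    stop("need at least 2 raters and 2 units", call. = FALSE)
  lev <- sort(unique(codes[!is.na(codes)]))
  o <- coincidence_matrix(codes, lev)
  nc <- rowSums(o)
  ntot <- sum(nc)
  if (ntot <= 1)
    stop("need at least one unit with two or more non-missing codes", call. = FALSE)
  d2 <- difference_matrix(nc, metric)
  D_o <- sum(o * d2) / ntot
  D_e <- sum(outer(nc, nc) * d2) / (ntot * (ntot - 1))
  if (D_e == 0)
    stop("expected disagreement is zero (all pairable codes identical): ",
         "agreement is undefined, not perfect", call. = FALSE)
  res <- list(alpha = 1 - D_o / D_e, D_o = D_o, D_e = D_e, metric = metric,
              ci_low = NA_real_, ci_high = NA_real_, B = NA_integer_)
  class(res) <- "agreement_result"
  res
}

# coincidence matrix over pairable values: each unit with m codes adds its
# ordered within-unit pairs with weight 1/(m-1)
coincidence_matrix <- function(codes, lev) {
  ncat <- length(lev)
  idx <- matrix(match(codes, lev), nrow = nrow(codes))
  R <- matrix(0, nrow(codes), ncat)
  for (c in seq_len(ncat))
    R[, c] <- rowSums(idx == c, na.rm = TRUE)
  m <- rowSums(R)
  keep <- m >= 2
  R <- R[keep, , drop = FALSE]
  w <- 1 / (rowSums(R) - 1)
  o <- crossprod(R * w, R)
  diag(o) <- diag(o) - colSums(R * w)
  o
}

difference_matrix <- function(nc, metric) {
  ncat <- length(nc)
  if (metric == "nominal") return(1 - diag(ncat))
  d2 <- matrix(0, ncat, ncat)
  cum <- cumsum(nc)
  for (c in seq_len(ncat - 1L)) {
    for (k in (c + 1L):ncat) {
      between <- cum[k] - cum[c] + nc[c] # sum of marginals from c to k
      d2[c, k] <- d2[k, c] <- (between - (nc[c] + nc[k]) / 2)^2
    }
  }
  d2
}

#' Percentile bootstrap CI for Krippendorff's alpha
#'
#' Resamples units with replacement `B` times and returns the percentile
#' interval of the recomputed alphas. Replicates whose expected
#' disagreement degenerates to zero are skipped and counted; more than 50%
#' degenerate replicates is an error.
#'
#' @inheritParams krippendorff_alpha
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; the interval is deterministic given it.
#' @param conf Coverage of the interval (default 0.95).
#' @return An `agreement_result` with `ci_low`/`ci_high` filled in.
#' @export
alpha_bootstrap_ci <- function(codes, metric = c("ordinal", "nominal"),
                               B = 1000L, seed = 1L, conf = 0.95) {
  metric <- match.arg(metric)
  if (B < 100L) stop("B: need at least 100 bootstrap replicates", call. = FALSE)
  codes <- as.matrix(codes)
  full <- krippendorff_alpha(codes, metric)
  set.seed(as.integer(seed))
  n <- nrow(codes)
  reps <- vapply(seq_len(B), function(b) {
    take <- sample.int(n, n, replace = TRUE)
    tryCatch(krippendorff_alpha(codes[take, , drop = FALSE], metric)$alpha,
             error = function(e) NA_real_)
  }, 0)
  bad <- sum(is.na(reps))
  if (bad > B / 2)
    stop("more than half of the bootstrap replicates had undefined agreement",
         call. = FALSE)
  qs <- stats::quantile(reps[!is.na(reps)],
                        c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  full$ci_low <- qs[1]; full$ci_high <- qs[2]; full$B <- as.integer(B)
  full
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Krippendorff's alpha (%s): %.4f  (D_o %.4f / D_e %.4f)\n",
              x$metric, x$alpha, x$D_o, x$D_e))
  if (!is.na(x$ci_low))
    cat(sprintf("  bootstrap 95%% CI: [%.4f, %.4f]  (B = %d)\n",
                x$ci_low, x$ci_high, x$B))
  invisible(x)
}
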