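#' Evaluate fitted percentile curves
#'
#' Returns the matrix of fitted quantiles (ages by taus) for any centile
#' model. Raw predictions are monotonically rearranged in tau at every age
#' (sorted), so the returned curves never cross, and are clipped to
#' \[0, 1\]. LQR curves extend linearly to any age and LMS curves freeze
#' their parameter values beyond the fitted range; NQR curves are only
#' defined on the observed age range and raise an error outside it.
#'
#' @param model A `centile_model` from [fit_lms()], [fit_lqr()] or
#'   [fit_nqr()].
#' @param ages Ages in years at which to evaluate the curves.
#' @param taus Probabilities to evaluate. The distributional LMS model
#'   accepts any probabilities; LQR/NQR models only the taus they were
#'   fitted at (the default).
#' @return A numeric matrix of dimension `length(ages) x length(taus)`,
#'   non-decreasing along each row.
#' @export
predict_quantiles <- function(model, ages, taus = model$taus) {
  stopifnot(inherits(model, "centile_model"))
  validate_taus(taus)
  raw <- switch(model$algorithm,
    LMS = {
      vapply(taus, function(tt) lms_quantile(model, ages, tt),
             numeric(length(ages)))
    },
    LQR = {
      j <- match_fitted_taus(taus, model$taus, "LQR")
      vapply(j, function(jj) model$coef[1, jj] + model$coef[2, jj] * ages,
             numeric(length(ages)))
    },
    NQR = {
      if (any(ages < model$age_range[1] | ages > model$age_range[2]))
        stop(sprintf(paste0("NQR curves are only defined on the fitted age ",
                            "range [%.2f, %.2f]; spline quantile curves ",
                            "cannot be extrapolated"),
                     model$age_range[1], model$age_range[2]), call. = FALSE)
      j <- match_fitted_taus(taus, model$taus, "NQR")
      B <- pspline_basis(ages, model$age_range[1], model$age_range[2],
                         model$basis_size)
      B %*% model$theta[, j, drop = FALSE]
    },
    stop("unknown algorithm: ", model$algorithm, call. = FALSE))
  raw <- matrix(raw, nrow = length(ages), ncol = length(taus))
  out <- if (length(taus) == 1L) raw else t(apply(raw, 1L, sort))
  out <- pmin(pmax(out, 0), 1)
  dimnames(out) <- list(NULL, paste0("tau_", taus))
  out
}

match_fitted_taus <- function(taus, fitted, alg) {
  j <- match(taus, fitted)
  if (anyNA(j))
    stop(alg, " models only provide the taus they were fitted at (",
         paste(fitted, collapse = ", "), ")", call. = FALSE)
  j
}
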