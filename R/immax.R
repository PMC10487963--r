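#' Fit the IMMAX index by principal-component regression
#'
#' Builds the composite immune age index from the five flow-cytometry
#' biomarkers: each ratio is log-transformed and the CD28neg fraction
#' logit-transformed (with clipping), the transformed markers are z-scored,
#' `k` principal axes are extracted, and the target is regressed on the
#' component scores by least squares. The sign of the first axis is aligned
#' so that it correlates positively with the memory:naive CD8 ratio, the
#' single marker most in step with composite immune age.
#'
#' @param biomarkers Data frame holding the five canonical biomarker
#'   columns (`nk_t_ratio`, `cd4_cd8_ratio`, `cd4_mem_naive_ratio`,
#'   `cd8_mem_naive_ratio`, `cd28neg_cd8_freq`); no missing values.
#' @param target Training values of the index in \[0, 1\], same length as
#'   `nrow(biomarkers)`.
#' @param k Number of principal components to retain (1 to 5; default 1).
#' @param logit_eps Clipping epsilon for the logit transform of the
#'   CD28neg fraction.
#' @return An object of class `immax_pcr` with the transform spec, centers,
#'   scales, loadings, regression coefficients and in-sample fitted values.
#' @export
#' @examples
#' coh <- generate_cohort(200, generator_params(seed = 3))
#' m <- fit_immax_pcr(coh[biomarker_columns()], coh$immax, k = 1)
#' cor(predict_immax(m, coh[biomarker_columns()]), coh$immax)
fit_immax_pcr <- function(biomarkers, target, k = 1L, logit_eps = 1e-4) {
  X <- transform_biomarkers(biomarkers, logit_eps)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > 5 || k != round(k))
    stop("k: number of components must be an integer between 1 and 5", call. = FALSE)
  if (length(target) != nrow(X))
    stop("target length must match the number of biomarker rows", call. = FALSE)
  if (any(target < 0 | target > 1))
    stop("target values must lie in [0, 1]", call. = FALSE)
  k <- as.integer(k)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl <= 0)) {
    bad <- colnames(X)[scl <= 0]
    stop("constant biomarker column (zero scale): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  Z <- scale(X, center = ctr, scale = scl)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  W <- pc$rotation[, seq_len(k), drop = FALSE]
  # orient PC1 so higher scores mean older immune age
  if (W["cd8_mem_naive_ratio", 1L] < 0) W[, 1L] <- -W[, 1L]
  S <- Z %*% W
  fit <- stats::lm.fit(cbind(1, S), target)
  m <- list(transform = c(rep("log", 4L), "logit"),
            logit_eps = logit_eps,
            center = ctr, scale = scl, loadings = W,
            regression_coefs = unname(fit$coefficients),
            fitted_raw = unname(fit$fitted.values))
  class(m) <- "immax_pcr"
  m
}

#' Predict IMMAX for new biomarker records
#'
#' Applies the stored transforms, standardization, loadings and regression
#' coefficients of a fitted [fit_immax_pcr()] model and clips the result to
#' \[0, 1\].
#'
#' @param model An `immax_pcr` model.
#' @param biomarkers Data frame with the five canonical biomarker columns.
#' @return Predicted IMMAX values in \[0, 1\].
#' @export
predict_immax <- function(model, biomarkers) {
  stopifnot(inherits(model, "immax_pcr"))
  X <- transform_biomarkers(biomarkers, model$logit_eps)
  Z <- scale(X, center = model$center, scale = model$scale)
  S <- Z %*% model$loadings
  raw <- as.numeric(cbind(1, S) %*% model$regression_coefs)
  pmin(pmax(raw, 0), 1)
}

transform_biomarkers <- function(biomarkers, logit_eps) {
  cols <- biomarker_columns()
  miss <- setdiff(cols, names(biomarkers))
  if (length(miss))
    stop("missing biomarker column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(biomarkers[cols])
  if (anyNA(X))
    stop("biomarker table contains missing values", call. = FALSE)
  for (cn in cols[1:4]) {
    v <- biomarkers[[cn]]
    if (any(v <= 0))
      stop("biomarker outside transform domain: ", cn,
           " must be strictly positive for the log transform", call. = FALSE)
  }
  fr <- biomarkers[["cd28neg_cd8_freq"]]
  if (any(fr < 0 | fr > 1))
    stop("biomarker outside transform domain: cd28neg_cd8_freq must lie in [0, 1]",
         call. = FALSE)
  X[, 1:4] <- log(X[, 1:4])
  X[, 5L] <- stats::qlogis(pmin(pmax(fr, logit_eps), 1 - logit_eps))
  X
}

#' @export
print.immax_pcr <- function(x, ...) {
  cat(sprintf("IMMAX principal-component regression (%d component%s)\n",
              ncol(x$loadings), if (ncol(x$loadings) > 1) "s" else ""))
  cat("  score coefficients:", format(x$regression_coefs, digits = 4), "\n")
  invisible(x)
}
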