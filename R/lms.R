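#' Location-scale-shape centile model on the logit scale
#'
#' Fits the distribution of IMMAX conditional on age in the LMS growth-chart
#' spirit: IMMAX is mapped to the real line by the logit (with epsilon
#' clipping) and modelled as sinh-arcsinh (shash) with penalized-spline age
#' smooths of the location, log-scale and skewness and a constant
#' tail-weight, estimated by penalized maximum likelihood through
#' [mgcv::gam()]. The fitted parameter curves are tabulated on a 0.1-year
#' grid; percentiles and centiles are obtained by evaluating (and, beyond
#' the observed age range, freezing) these curves, inverting the fitted
#' distribution and back-transforming, which keeps every curve inside
#' (0, 1).
#'
#' @inheritParams fit_lqr
#' @param eps_clip Clipping epsilon applied to `y` before the logit.
#' @param k Basis dimensions of the age smooths for location, log-scale and
#'   skewness.
#' @return A `centile_model` with `algorithm = "LMS"`, the tabulated
#'   parameter curves, and per-tau coverage diagnostics.
#' @export
#' @examples
#' coh <- generate_cohort(400, generator_params(seed = 11))
#' m <- fit_lms(coh$age_years, coh$immax)
#' predict_quantiles(m, c(30, 60, 90))
fit_lms <- function(age, y, taus = c(0.03, 0.15, 0.50, 0.85, 0.97),
                    eps_clip = 1e-4, k = c(10L, 10L, 5L)) {
  validate_taus(taus)
  if (length(age) != length(y)) stop("age and y must have equal length", call. = FALSE)
  if (any(y < 0 | y > 1))
    stop("y outside [0, 1]: the index must live on the unit interval", call. = FALSE)
  if (length(y) < 50L)
    stop("need at least 50 observations for a stable distributional fit", call. = FALSE)
  ystar <- stats::qlogis(pmin(pmax(y, eps_clip), 1 - eps_clip))
  dat <- data.frame(age = age, ystar = ystar)
  fam <- shash_family()
  fml <- list(ystar ~ s(age, k = k[1]), ~ s(age, k = k[2]),
              ~ s(age, k = k[3]), ~ 1)
  fit <- mgcv::gam(fml, family = fam, data = dat, method = "REML")
  conv <- fit$outer.info$conv
  if (!is.null(conv) && !identical(conv, "full convergence")) {
    stop("penalized-likelihood fit did not converge (", conv, ") after ",
         fit$outer.info$iter, " outer iterations; gradient ",
         paste(format(fit$outer.info$grad, digits = 3), collapse = ", "),
         call. = FALSE)
  }
  rng <- range(age)
  grid <- seq(rng[1], rng[2], by = 0.1)
  par_grid <- stats::predict(fit, newdata = data.frame(age = grid))
  model <- list(algorithm = "LMS", taus = taus, age_range = rng,
                eps_clip = eps_clip,
                grid = grid,
                par_grid = unname(as.matrix(par_grid)))
  class(model) <- "centile_model"
  fitted <- predict_quantiles(model, age, taus)
  model$diagnostics <- coverage_diagnostics(y, fitted, taus)
  model
}

# sinh-arcsinh family with a negligible scale-link floor so that the
# family's cdf/qf helpers (which invert the scale as exp(eta)) agree with
# the fitted link sigma = exp(eta) + b
shash_family <- function() mgcv::shash(b = 1e-6)

# linear interpolation of the tabulated parameter curves; constant
# (frozen) beyond the fitted age range
lms_params_at <- function(model, ages) {
  vapply(seq_len(ncol(model$par_grid)), function(j) {
    stats::approx(model$grid, model$par_grid[, j], xout = ages, rule = 2)$y
  }, numeric(length(ages)))
}

lms_quantile <- function(model, ages, tau) {
  eta <- lms_params_at(model, ages)
  fam <- shash_family()
  stats::plogis(fam$qf(tau, eta, wt = 1, scale = 1))
}

#' Individual centile under the distributional centile model
#'
#' Returns the fitted conditional cumulative probability `F(y | age)` of an
#' IMMAX value: the subject's position within the reference population of
#' its own age. Only the distributional (LMS) model supports this; the
#' quantile-regression models provide curves, hence category ratings, but
#' no full conditional distribution.
#'
#' @param model An LMS `centile_model` from [fit_lms()].
#' @param age Ages in years.
#' @param y IMMAX values in (0, 1), same length as `age` (or one of the two
#'   may have length 1).
#' @return Centiles in (0, 1), strictly increasing in `y` at fixed age.
#' @export
individual_centile <- function(model, age, y) {
  stopifnot(inherits(model, "centile_model"))
  if (model$algorithm != "LMS")
    stop("individual centiles need the distributional (LMS) model; ",
         model$algorithm, " fits provide category ratings only", call. = FALSE)
  if (any(y <= 0 | y >= 1))
    stop("y must lie strictly inside (0, 1)", call. = FALSE)
  n <- max(length(age), length(y))
  age <- rep_len(age, n); y <- rep_len(y, n)
  ystar <- stats::qlogis(pmin(pmax(y, model$eps_clip), 1 - model$eps_clip))
  eta <- lms_params_at(model, age)
  fam <- shash_family()
  as.numeric(fam$cdf(ystar, eta, wt = 1, scale = 1, logp = FALSE))
}
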