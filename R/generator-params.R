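#' Parameters of the synthetic cohort generator
#'
#' Bundles and validates every knob of the synthetic immune-aging cohort:
#' the adult age distribution (a mixture of uniform components), the
#' logit-scale location and scale of the IMMAX index as linear functions of
#' age, a sinh-arcsinh skewness parameter for the conditional noise, the
#' latent loadings and noise scales of the five flow-cytometry biomarkers,
#' the probit-scale drift of the latent centile at follow-up, and the seed.
#'
#' The defaults describe a pooled adult cohort aged 18-97 with a median
#' IMMAX rising near-linearly with age on the unit scale and an
#' age-increasing, mildly right-skewed conditional spread. Under these
#' defaults the conditional quantile function is an exact sinh-arcsinh
#' location-scale-shape model on the logit scale, so the package's LMS-type
#' centile fits are well specified.
#'
#' @param age_components Numeric matrix with columns `lower`, `upper`,
#'   `weight`: uniform age components of the cohort mixture. Weights must
#'   sum to 1 and bounds lie within \[18, 100\].
#' @param mu0,mu1 Intercept and slope (per year) of the logit-scale IMMAX
#'   median versus age.
#' @param sigma0,sigma1 Intercept and slope (per year) of the logit-scale
#'   conditional spread versus age; the spread must be positive over every
#'   age component.
#' @param skew Sinh-arcsinh skewness of the conditional noise; 0 means
#'   logit-normal, positive values give a right tail. The noise is centred
#'   so its median is exactly zero for any `skew`.
#' @param biomarker_loadings Named positive loadings of the five
#'   log/logit-scale biomarkers on the latent immune age (logit-IMMAX).
#' @param biomarker_noise_sd Named positive marker-specific noise SDs on the
#'   same transformed scales.
#' @param centile_drift_sd SD of the probit-scale perturbation of the latent
#'   centile at follow-up (0 preserves each subject's centile exactly).
#' @param seed Integer seed making every generated table reproducible.
#'
#' @return An object of class `generator_params`.
#' @seealso [generate_cohort()], [true_quantile()], [generate_followup()]
#' @export
#' @examples
#' p <- generator_params()
#' p$mu1 # per-year increase of the logit-scale IMMAX median
generator_params <- function(age_components = cbind(lower = c(18, 40, 65),
                                                    upper = c(40, 65, 97),
                                                    weight = c(0.45, 0.35, 0.20)),
                             mu0 = -0.8, mu1 = 0.014,
                             sigma0 = 0.05, sigma1 = 0.0007,
                             skew = 0.25,
                             biomarker_loadings = c(nk_t_ratio = 1.0,
                                                    cd4_cd8_ratio = 0.8,
                                                    cd4_mem_naive_ratio = 1.2,
                                                    cd8_mem_naive_ratio = 1.3,
                                                    cd28neg_cd8_freq = 1.1),
                             biomarker_noise_sd = c(nk_t_ratio = 0.28,
                                                    cd4_cd8_ratio = 0.34,
                                                    cd4_mem_naive_ratio = 0.25,
                                                    cd8_mem_naive_ratio = 0.22,
                                                    cd28neg_cd8_freq = 0.28),
                             centile_drift_sd = 0.15,
                             seed = 1L) {
  p <- list(age_components = as.matrix(age_components),
            mu0 = mu0, mu1 = mu1, sigma0 = sigma0, sigma1 = sigma1,
            skew = skew,
            biomarker_loadings = biomarker_loadings,
            biomarker_noise_sd = biomarker_noise_sd,
            centile_drift_sd = centile_drift_sd,
            seed = as.integer(seed))
  class(p) <- "generator_params"
  validate_generator_params(p)
  p
}

validate_generator_params <- function(p) {
  stopifnot(inherits(p, "generator_params"))
  ac <- p$age_components
  if (!is.matrix(ac) || ncol(ac) != 3L || nrow(ac) < 1L)
    stop("age_components: need a matrix with columns lower, upper, weight", call. = FALSE)
  if (any(ac[, 1] >= ac[, 2]))
    stop("age_components: every lower bound must be below its upper bound", call. = FALSE)
  if (any(ac[, 1:2] < 18) || any(ac[, 1:2] > 100))
    stop("age_components: bounds must lie within [18, 100]", call. = FALSE)
  if (abs(sum(ac[, 3]) - 1) > 1e-8 || any(ac[, 3] < 0))
    stop("age_components: weights must be nonnegative and sum to 1", call. = FALSE)
  for (fld in c("mu0", "mu1", "sigma0", "sigma1", "skew", "centile_drift_sd"))
    if (!is.numeric(p[[fld]]) || length(p[[fld]]) != 1L || !is.finite(p[[fld]]))
      stop(sprintf("%s: must be a single finite number", fld), call. = FALSE)
  ages <- range(ac[, 1:2])
  if (any(p$sigma0 + p$sigma1 * ages <= 0))
    stop("sigma0/sigma1: conditional spread must be positive over the age range", call. = FALSE)
  if (p$centile_drift_sd < 0)
    stop("centile_drift_sd: must be nonnegative", call. = FALSE)
  for (fld in c("biomarker_loadings", "biomarker_noise_sd")) {
    v <- p[[fld]]
    if (length(v) != 5L || !all(biomarker_columns() %in% names(v)))
      stop(sprintf("%s: need 5 values named %s", fld,
                   paste(biomarker_columns(), collapse = ", ")), call. = FALSE)
    if (any(v <= 0))
      stop(sprintf("%s: all entries must be positive", fld), call. = FALSE)
  }
  if (length(p$seed) != 1L || is.na(p$seed))
    stop("seed: must be a single integer", call. = FALSE)
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Synthetic immune-aging cohort parameters\n")
  cat(sprintf("  age mixture: %d uniform component(s) on [%g, %g]\n",
              nrow(x$age_components), min(x$age_components[, 1]),
              max(x$age_components[, 2])))
  cat(sprintf("  logit-IMMAX median: %.3f %+.4f * age;  spread: %.3f %+.5f * age; skew %.2f\n",
              x$mu0, x$mu1, x$sigma0, x$sigma1, x$skew))
  cat(sprintf("  centile drift SD (probit): %.3f;  seed %d\n",
              x$centile_drift_sd, x$seed))
  invisible(x)
}

#' Canonical biomarker column names
#'
#' The five flow-cytometry biomarker columns, in the order used
#' throughout the package.
#' @return Character vector of length 5.
#' @export
biomarker_columns <- function() {
  c("nk_t_ratio", "cd4_cd8_ratio", "cd4_mem_naive_ratio",
    "cd8_mem_naive_ratio", "cd28neg_cd8_freq")
}

# transformed-scale baselines giving realistic marker levels at logit-IMMAX 0
biomarker_baselines <- function() {
  c(nk_t_ratio = log(0.35), cd4_cd8_ratio = log(1.8),
    cd4_mem_naive_ratio = log(1.0), cd8_mem_naive_ratio = log(0.8),
    cd28neg_cd8_freq = stats::qlogis(0.25))
}
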