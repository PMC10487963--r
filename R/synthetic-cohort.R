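#' True conditional IMMAX quantile of the synthetic cohort
#'
#' Evaluates the generator's conditional quantile function
#' `inverse-logit(mu(age) + sigma(age) * z(u))`, where `mu` and `sigma` are
#' linear in age and `z` is a median-centred sinh-arcsinh standard quantile
#' with skewness `params$skew`. This is the oracle against which centile
#' fits are judged in parameter-recovery tests.
#'
#' @param u Latent centile(s), strictly inside (0, 1).
#' @param age Age(s) in years; 18 to 105 (ages above 100 arise only for
#'   follow-up visits of subjects enrolled near the upper age bound).
#' @param params A [generator_params()] object.
#' @return IMMAX value(s) in (0, 1), strictly increasing in `u` at fixed age.
#' @export
#' @examples
#' p <- generator_params(skew = 0)
#' true_quantile(0.5, 50, p) == plogis(p$mu0 + p$mu1 * 50)
true_quantile <- function(u, age, params) {
  validate_generator_params(params)
  if (any(u <= 0 | u >= 1))
    stop("u: latent centiles must lie strictly inside (0, 1)", call. = FALSE)
  if (any(age < 18 | age > 105))
    stop("age: must lie within [18, 105] years", call. = FALSE)
  m <- params$mu0 + params$mu1 * age
  s <- params$sigma0 + params$sigma1 * age
  stats::plogis(m + s * zskew(u, params$skew))
}

# median-centred sinh-arcsinh standard quantile: z(0.5) = 0 for any skew
zskew <- function(u, skew) {
  sinh(asinh(stats::qnorm(u)) + skew) - sinh(skew)
}

#' Generate a cross-sectional synthetic cohort
#'
#' Draws `n` subjects: ages from the uniform mixture in `params`, a latent
#' centile `u ~ Uniform(0,1)` kept as `true_centile`, IMMAX from
#' [true_quantile()], and the five flow-cytometry biomarkers as monotone
#' transforms (exponential for the four ratios, inverse-logit for the
#' CD28neg fraction) of `loading * logit(IMMAX) + marker noise`. The call is
#' deterministic given `params$seed`.
#'
#' @param n Number of subjects (>= 1).
#' @param params A [generator_params()] object.
#' @return A cohort `data.frame` with columns `subject_id`, `study`, `sex`,
#'   `age_years`, the five biomarkers, `immax`, `visit` (all `"baseline"`),
#'   and `true_centile`.
#' @export
#' @examples
#' coh <- generate_cohort(100, generator_params(seed = 7))
#' head(coh$immax)
generate_cohort <- function(n, params = generator_params()) {
  validate_generator_params(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n: need a positive integer number of subjects", call. = FALSE)
  n <- as.integer(n)
  set.seed(params$seed)
  ac <- params$age_components
  comp <- sample.int(nrow(ac), n, replace = TRUE, prob = ac[, 3])
  age <- stats::runif(n, ac[comp, 1], ac[comp, 2])
  u <- stats::runif(n)
  immax <- true_quantile(u, age, params)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  bm <- synth_biomarkers(immax, params, n)
  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                    study = "synthetic", sex = sex, age_years = age,
                    stringsAsFactors = FALSE)
  out <- cbind(out, bm)
  out$immax <- immax
  out$visit <- "baseline"
  out$true_centile <- u
  out
}

synth_biomarkers <- function(immax, params, n) {
  lat <- stats::qlogis(immax)
  base <- biomarker_baselines()
  cols <- biomarker_columns()
  bm <- lapply(cols, function(cn) {
    t <- base[[cn]] + params$biomarker_loadings[[cn]] * lat +
      stats::rnorm(n, 0, params$biomarker_noise_sd[[cn]])
    if (cn == "cd28neg_cd8_freq") stats::plogis(t) else exp(t)
  })
  names(bm) <- cols
  as.data.frame(bm)
}

#' Advance a synthetic baseline cohort to a follow-up visit
#'
#' Creates one follow-up record per baseline record: ages increase by `fpl`
#' years, each subject's latent centile is perturbed on the probit scale
#' with SD `params$centile_drift_sd` (clamped to (0.001, 0.999)), and IMMAX
#' is recomputed from [true_quantile()]. With `centile_drift_sd = 0` every
#' subject keeps its baseline centile exactly, so longitudinal change
#' reflects pure movement along the reference curves.
#'
#' @param baseline A cohort from [generate_cohort()] (must carry
#'   `true_centile`).
#' @param fpl Follow-up period length in years (> 0).
#' @param params A [generator_params()] object.
#' @param seed Seed for the drift draws; defaults to `params$seed + 1` so
#'   baseline and follow-up use distinct but reproducible streams.
#' @return A cohort `data.frame` of follow-up records (`visit = "followup"`).
#' @export
generate_followup <- function(baseline, fpl = 5, params = generator_params(),
                              seed = params$seed + 1L) {
  validate_generator_params(params)
  if (!is.numeric(fpl) || length(fpl) != 1L || fpl <= 0)
    stop("fpl: follow-up period length must be a positive number of years",
         call. = FALSE)
  if (is.null(baseline$true_centile) || anyNA(baseline$true_centile))
    stop("baseline lacks true_centile: only synthetic baselines generated ",
         "by this package can be advanced to follow-up", call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(baseline)
  u_new <- stats::pnorm(stats::qnorm(baseline$true_centile) +
                          stats::rnorm(n, 0, params$centile_drift_sd))
  u_new <- pmin(pmax(u_new, 0.001), 0.999)
  if (params$centile_drift_sd == 0) u_new <- baseline$true_centile
  fu <- baseline
  fu$age_years <- baseline$age_years + fpl
  fu$true_centile <- u_new
  fu$immax <- true_quantile(u_new, fu$age_years, params)
  fu[biomarker_columns()] <- synth_biomarkers(fu$immax, params, n)
  fu$visit <- "followup"
  fu
}

#' Age-stratified subsample of a cohort
#'
#' Partitions a cohort into a subsample of `n_out` records and the
#' remainder, allocating the subsample across half-open age bins of width
#' `stratum_width` (starting at 18) proportionally to stratum size with
#' largest-remainder rounding. Subsample and remainder are disjoint and
#' together restore the cohort; the draw is deterministic given `seed`.
#'
#' @param cohort A cohort `data.frame` with `age_years`.
#' @param n_out Size of the subsample; must be smaller than the cohort.
#' @param stratum_width Age bin width in years (default 10).
#' @param seed Integer seed for the within-stratum draws.
#' @return A list with elements `subsample` and `remainder`.
#' @export
stratified_subsample <- function(cohort, n_out, stratum_width = 10, seed = 1L) {
  n <- nrow(cohort)
  if (!is.numeric(n_out) || length(n_out) != 1L || n_out < 1 || n_out >= n)
    stop("n_out: must be at least 1 and smaller than the cohort size", call. = FALSE)
  if (stratum_width <= 0)
    stop("stratum_width: must be positive", call. = FALSE)
  n_out <- as.integer(n_out)
  breaks <- seq(18, max(cohort$age_years) + stratum_width, by = stratum_width)
  stratum <- findInterval(cohort$age_years, breaks)
  sizes <- tabulate(stratum, nbins = length(breaks))
  alloc <- largest_remainder(n_out * sizes / n, n_out, cap = sizes)
  set.seed(as.integer(seed))
  take <- integer(0)
  for (s in which(alloc > 0)) {
    idx <- which(stratum == s)
    take <- c(take, idx[sample.int(length(idx), alloc[s])])
  }
  take <- sort(take)
  list(subsample = cohort[take, , drop = FALSE],
       remainder = cohort[-take, , drop = FALSE])
}

# integer allocation by largest remainder, respecting per-cell caps
largest_remainder <- function(quota, total, cap) {
  base <- pmin(floor(quota), cap)
  left <- total - sum(base)
  while (left > 0) {
    rem <- quota - base
    rem[base >= cap] <- -Inf
    ord <- order(rem, decreasing = TRUE)
    k <- ord[seq_len(min(left, sum(is.finite(rem) & rem > -Inf & base < cap)))]
    base[k] <- base[k] + 1L
    left <- total - sum(base)
  }
  as.integer(base)
}
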