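# lazily built, cached fixtures shared across test files
fixture_env <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) assign(name, expr, envir = fixture_env)
  get(name, envir = fixture_env)
}

fx_params <- function() generator_params(seed = 42)
fx_cohort <- function() fx("cohort", generate_cohort(1600, fx_params()))
fx_lms <- function() fx("lms", fit_lms(fx_cohort()$age_years, fx_cohort()$immax))
fx_lqr <- function() fx("lqr", fit_lqr(fx_cohort()$age_years, fx_cohort()$immax))
fx_nqr <- function() fx("nqr", fit_nqr(fx_cohort()$age_years, fx_cohort()$immax))
fx_ratings <- function() fx("ratings", {
  coh <- fx_cohort()
  cbind(lms = rate_aging_type(fx_lms(), coh$age_years, coh$immax),
        lqr = rate_aging_type(fx_lqr(), coh$age_years, coh$immax),
        nqr = rate_aging_type(fx_nqr(), coh$age_years, coh$immax))
})
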