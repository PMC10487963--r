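make_pairs <- function(n = 40, seed = 3, drift = 0, fpl = 5) {
  p <- generator_params(seed = seed, centile_drift_sd = drift)
  bl <- generate_cohort(n, p)
  fu <- generate_followup(bl, fpl = fpl, p)
  list(p = p, bl = bl, fu = fu, paired = rbind(bl, fu))
}

test_that("an unchanged follow-up shifts the age gap by minus the follow-up period", {
  d <- make_pairs(30, seed = 14)
  fu <- d$bl
  fu$visit <- "followup"
  fu$age_years <- d$bl$age_years + 5
  ref <- build_reference(fit_lqr(d$bl$age_years, d$bl$immax), "P50")
  del <- change_from_baseline(rbind(d$bl, fu), references = list(LQR_P50 = ref))
  expect_identical(del$delta_immax, rep(0, 30))
  expect_identical(del$delta_eyol_LQR_P50, rep(0, 30))
  expect_equal(del$delta_age_gap_LQR_P50, rep(-5, 30))
})

test_that("drift-free synthetic pairs keep their centile and age by five years", {
  d <- make_pairs(400, seed = 26, drift = 0)
  lms <- fit_lms(d$bl$age_years, d$bl$immax)
  ref <- build_reference(fit_lqr(d$bl$age_years, d$bl$immax), "P50")
  del <- change_from_baseline(d$paired, lms, list(LQR_P50 = ref))
  expect_lt(abs(mean(del$delta_centile)), 0.02)
  expect_lt(abs(mean(del$delta_eyol_LQR_P50) - 5), 0.3)
  expect_equal(del$fpl, rep(5, 400))
})

test_that("the follow-up period identity is exact on every record", {
  d <- make_pairs(60, seed = 8, drift = 0.2, fpl = 3.5)
  ref1 <- build_reference(fit_lqr(d$bl$age_years, d$bl$immax), "P50")
  lms <- fx_lms()
  ref2 <- build_reference(lms, "P50")
  del <- change_from_baseline(d$paired, lms,
                              list(LQR_P50 = ref1, LMS_P50 = ref2))
  expect_identical(del$delta_eyol_LQR_P50 - del$delta_age_gap_LQR_P50, del$fpl)
  expect_identical(del$delta_eyol_LMS_P50 - del$delta_age_gap_LMS_P50, del$fpl)
})

test_that("pairing violations are reported with the offending subjects", {
  d <- make_pairs(10, seed = 4)
  lone <- d$fu[1, ]
  expect_error(change_from_baseline(rbind(d$paired, lone)), "duplicated")
  expect_error(change_from_baseline(rbind(d$bl, d$fu[-2, ])), "S00002")
  only_fu <- d$fu
  expect_error(change_from_baseline(only_fu), "unpaired|no baseline")
  noimm <- d$paired; noimm$immax[3] <- NA
  expect_error(change_from_baseline(noimm), "IMMAX")
})

test_that("uniformly positive changes give decisive signed-rank evidence", {
  d <- make_pairs(20, seed = 33, drift = 0)
  ref <- build_reference(fit_lqr(d$bl$age_years, d$bl$immax), "P50")
  del <- change_from_baseline(d$paired, references = list(LQR_P50 = ref))
  expect_true(all(del$delta_immax > 0))
  rep <- longitudinal_report(del)
  p_imm <- rep$tests$p_raw[rep$tests$comparison == "delta_immax vs 0"]
  expect_lt(p_imm, 0.01)
})

test_that("EYOL and age-gap changes are perfectly rank-correlated", {
  d <- make_pairs(50, seed = 12, drift = 0.15)
  ref <- build_reference(fit_lqr(d$bl$age_years, d$bl$immax), "P50")
  del <- change_from_baseline(d$paired, references = list(LQR_P50 = ref))
  rep <- longitudinal_report(del)
  expect_equal(rep$correlations["delta_eyol_LQR_P50",
                                "delta_age_gap_LQR_P50"], 1)
})

test_that("centile and age-gap changes track each other across references", {
  # score a mid-age longitudinal sample against the pooled-cohort fits, as
  # in the study design; the centile-to-IMMAX Jacobian varies with age, so
  # the near-perfect cross-sectional correlation attenuates for changes
  lms <- fx_lms()
  refs <- list(LMS_P50 = build_reference(lms, "P50"),
               LQR_P50 = build_reference(fx_lqr(), "P50"))
  pl <- generator_params(seed = 18, centile_drift_sd = 0.3,
                         age_components = cbind(25, 70, 1))
  bl <- generate_cohort(300, pl)
  fu <- generate_followup(bl, fpl = 5, pl)
  del <- change_from_baseline(rbind(bl, fu), lms, refs)
  expect_gt(cor(del$delta_centile, del$delta_age_gap_LMS_P50,
                method = "spearman"), 0.9)
  expect_gt(cor(del$delta_centile, del$delta_age_gap_LQR_P50,
                method = "spearman"), 0.9)
})

test_that("Holm adjustment is monotone and never below the raw p-values", {
  d <- make_pairs(40, seed = 29, drift = 0.1)
  lms <- fx_lms()
  refs <- list(LMS_P50 = build_reference(lms, "P50"),
               LQR_P50 = build_reference(fit_lqr(d$bl$age_years, d$bl$immax),
                                         "P50"),
               HYP = build_reference(lms, "HYP"))
  del <- change_from_baseline(d$paired, lms, refs)
  rep <- longitudinal_report(del)
  expect_true(all(rep$tests$p_adj >= rep$tests$p_raw - 1e-15, na.rm = TRUE))
  fam <- rep$tests[rep$tests$test == "wilcoxon_paired", ]
  expect_identical(nrow(fam), 3L)
  ord <- order(fam$p_raw)
  expect_true(all(diff(fam$p_adj[ord]) >= -1e-15))
})

test_that("degenerate all-zero deltas are reported, not raised", {
  d <- make_pairs(12, seed = 41)
  fu <- d$bl; fu$visit <- "followup"; fu$age_years <- fu$age_years + 5
  del <- change_from_baseline(rbind(d$bl, fu))
  rep <- longitudinal_report(del)
  row <- rep$tests[rep$tests$comparison == "delta_immax vs 0", ]
  expect_match(row$note, "degenerate")
  expect_true(is.na(row$p_raw))
})

test_that("sex comparisons are calibrated under label permutation", {
  d <- make_pairs(40, seed = 50, drift = 0.2)
  ref <- build_reference(fit_lqr(d$bl$age_years, d$bl$immax), "P50")
  del <- change_from_baseline(d$paired, references = list(LQR_P50 = ref))
  set.seed(60)
  pvals <- replicate(400, {
    del$sex <- sample(rep(c("F", "M"), each = 20))
    rep <- longitudinal_report(del)
    rep$tests$p_raw[rep$tests$comparison == "delta_immax: F vs M"]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})
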