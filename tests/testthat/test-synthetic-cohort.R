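test_that("generator parameters are validated field by field", {
  expect_s3_class(generator_params(), "generator_params")
  expect_error(generator_params(mu1 = NA), "mu1")
  expect_error(generator_params(sigma0 = -0.1), "sigma0")
  expect_error(generator_params(centile_drift_sd = -1), "centile_drift_sd")
  expect_error(generator_params(biomarker_noise_sd = c(nk_t_ratio = -1)),
               "biomarker_noise_sd")
  expect_error(generator_params(age_components = cbind(10, 40, 1)),
               "age_components")
  expect_error(generator_params(age_components = cbind(c(18, 40), c(40, 97),
                                                       c(0.5, 0.4))),
               "sum to 1")
})

test_that("true_quantile matches its closed form and is monotone in u", {
  p0 <- generator_params(skew = 0)
  ages <- c(20, 45, 70, 95)
  expect_equal(true_quantile(0.5, ages, p0),
               plogis(p0$mu0 + p0$mu1 * ages))
  # median centring holds for skewed noise too
  p <- generator_params()
  expect_equal(true_quantile(0.5, ages, p), plogis(p$mu0 + p$mu1 * ages))
  expect_error(true_quantile(0, 50, p), "u")
  expect_error(true_quantile(1, 50, p), "u")
  expect_error(true_quantile(0.5, 10, p), "age")
  # monotone in u at fixed age, many probed pairs
  set.seed(1)
  u1 <- runif(1000, 0.001, 0.998)
  u2 <- u1 + runif(1000, 1e-4, 1 - u1 - 1e-4)
  a <- runif(1000, 18, 100)
  expect_true(all(true_quantile(u2, a, p) > true_quantile(u1, a, p)))
  # strictly increasing median over an age grid
  med <- true_quantile(0.5, seq(20, 90, 5), p)
  expect_true(all(diff(med) > 0) && all(med > 0 & med < 1))
})

test_that("generate_cohort is seeded, validated, and structured", {
  expect_error(generate_cohort(0, generator_params()), "n")
  p <- generator_params(seed = 9)
  a <- generate_cohort(200, p)
  b <- generate_cohort(200, p)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(200, generator_params(seed = 10))))
  expect_true(all(a$age_years >= 18 & a$age_years <= 97))
  expect_true(all(a$immax > 0 & a$immax < 1))
  expect_true(all(a$true_centile > 0 & a$true_centile < 1))
  expect_identical(a$immax, true_quantile(a$true_centile, a$age_years, p))
})

test_that("binned IMMAX medians rise with age and biomarkers track their loadings", {
  coh <- generate_cohort(2000, generator_params(seed = 5))
  bins <- cut(coh$age_years, quantile(coh$age_years, 0:10 / 10),
              include.lowest = TRUE)
  med <- tapply(coh$immax, bins, median)
  mid <- tapply(coh$age_years, bins, median)
  expect_gt(cor(med, mid, method = "spearman"), 0.9)
  for (cn in biomarker_columns())
    expect_gt(cor(coh[[cn]], coh$immax, method = "spearman"), 0)
})

test_that("follow-up preserves centiles without drift and is centred with drift", {
  p <- generator_params(seed = 3, centile_drift_sd = 0)
  bl <- generate_cohort(300, p)
  fu <- generate_followup(bl, fpl = 5, p)
  expect_identical(fu$true_centile, bl$true_centile)
  expect_identical(fu$age_years, bl$age_years + 5)
  # rising median curve means every subject's IMMAX grows
  expect_true(all(fu$immax > bl$immax))
  pd <- generator_params(seed = 3, centile_drift_sd = 0.05)
  bl2 <- generate_cohort(500, pd)
  fu2 <- generate_followup(bl2, fpl = 5, pd)
  expect_lt(abs(mean(fu2$true_centile - bl2$true_centile)), 0.02)
  expect_true(all(fu2$true_centile >= 0.001 & fu2$true_centile <= 0.999))
  # determinism and error path
  expect_identical(fu2, generate_followup(bl2, fpl = 5, pd))
  bad <- bl; bad$true_centile <- NULL
  expect_error(generate_followup(bad, 5, p), "synthetic")
  expect_error(generate_followup(bl, fpl = 0, p), "fpl")
})

test_that("stratified subsampling partitions the cohort proportionally", {
  coh <- generate_cohort(1605, generator_params(seed = 17))
  sp <- stratified_subsample(coh, 25, stratum_width = 10, seed = 2)
  expect_identical(nrow(sp$subsample), 25L)
  expect_identical(nrow(sp$remainder), 1580L)
  expect_length(intersect(sp$subsample$subject_id, sp$remainder$subject_id), 0)
  recombined <- rbind(sp$subsample, sp$remainder)
  expect_setequal(recombined$subject_id, coh$subject_id)
  expect_identical(sp, stratified_subsample(coh, 25, stratum_width = 10, seed = 2))
  expect_error(stratified_subsample(coh, 1605, seed = 1), "n_out")

  # uniform ages: each decade receives its proportional share +/- 1
  unif <- coh[order(coh$age_years), ][1:1000, ]
  unif$age_years <- seq(18, 97.9, length.out = 1000)
  sp2 <- stratified_subsample(unif, 10, stratum_width = 10, seed = 4)
  decades <- table(cut(sp2$subsample$age_years, seq(18, 98, 10),
                       include.lowest = TRUE))
  share <- table(cut(unif$age_years, seq(18, 98, 10), include.lowest = TRUE)) *
    10 / 1000
  expect_true(all(abs(decades - share) <= 1))
})
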