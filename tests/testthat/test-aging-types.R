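test_that("ratings follow the half-open boundary-up convention", {
  m <- fx_lqr()
  age <- 50
  Q <- as.numeric(predict_quantiles(m, age))
  expect_identical(rate_aging_type(m, age, Q[1] - 0.01), 1L) # below P03
  expect_identical(rate_aging_type(m, age, Q[3]), 4L)        # exactly P50
  expect_identical(rate_aging_type(m, age, Q[1]), 2L)        # exactly P03
  expect_identical(rate_aging_type(m, age, Q[5] + 0.005), 6L)
  expect_identical(rate_aging_type(m, rep(age, 2), c(0, 1)), c(1L, 6L))
})

test_that("category frequencies reflect the tau spacings on a well-specified fit", {
  coh <- fx_cohort()
  r <- rate_aging_type(fx_lms(), coh$age_years, coh$immax)
  freq <- tabulate(r, nbins = 6) / length(r)
  expect_lt(max(abs(freq - c(0.03, 0.12, 0.35, 0.35, 0.12, 0.03))), 0.03)
})

test_that("confusion matrices capture identity, reversal and hand-counted mixes", {
  a <- c(1L, 2L, 3L, 4L, 5L, 6L)
  ident <- rating_confusion(a, a)
  expect_equal(sum(diag(ident$proportions)), 1)
  expect_equal(ident$rho, 1)
  rev <- rating_confusion(a, 7L - a)
  expect_equal(sum(rev$proportions[cbind(1:6, 6:1)]), 1)
  expect_equal(rev$rho, -1)
  # ten units, two discordant neighbours
  b <- rep(3L, 10); c2 <- b; c2[c(4, 9)] <- 4L
  mix <- rating_confusion(b, c2)
  expect_equal(mix$proportions[3, 4], 0.2)
  expect_equal(mix$proportions[3, 3], 0.8)
  expect_equal(sum(mix$proportions), 1)
  expect_error(rating_confusion(1:3, 1:4), "length")
})

test_that("alpha is 1 for perfect agreement and 0 for chance assignment", {
  perfect <- cbind(c(1, 3, 2, 5, 6, 4, 2), c(1, 3, 2, 5, 6, 4, 2))
  res <- krippendorff_alpha(perfect)
  expect_identical(res$alpha, 1)
  expect_identical(res$D_o, 0)
  set.seed(4)
  rand <- matrix(sample.int(6, 20000, replace = TRUE), ncol = 2)
  expect_lt(abs(krippendorff_alpha(rand, "ordinal")$alpha), 0.03)
  expect_lt(abs(krippendorff_alpha(rand, "nominal")$alpha), 0.03)
})

test_that("the worked nominal example matches its frozen coincidence value", {
  codes <- cbind(c(1, 2, 3, 3), c(1, 2, 3, 4))
  res <- krippendorff_alpha(codes, "nominal")
  expect_equal(res$alpha, 32 / 46, tolerance = 1e-12)
  expect_equal(res$alpha, 1 - res$D_o / res$D_e, tolerance = 1e-12)
})

test_that("alpha equals the pair-enumeration oracle on small random matrices", {
  set.seed(11)
  for (rep in 1:40) {
    codes <- matrix(sample.int(3, 8, replace = TRUE), ncol = 2)
    # punch a missing value into some replicates
    if (rep %% 3 == 0) codes[sample.int(8, 1)] <- NA
    res <- try(krippendorff_alpha(codes, "ordinal"), silent = TRUE)
    orc <- if (inherits(res, "try-error")) NULL else oracle_alpha(codes, "ordinal")
    if (is.null(orc)) next
    expect_equal(res$alpha, orc$alpha, tolerance = 1e-12)
    expect_equal(res$D_o, orc$D_o, tolerance = 1e-12)
    expect_equal(res$D_e, orc$D_e, tolerance = 1e-12)
    nom <- krippendorff_alpha(codes, "nominal")
    expect_equal(nom$alpha, oracle_alpha(codes, "nominal")$alpha,
                 tolerance = 1e-12)
  }
})

test_that("ordinal alpha dominates nominal alpha for adjacent disagreements", {
  set.seed(6)
  for (rep in 1:10) {
    base <- sample.int(5, 50, replace = TRUE)
    other <- base + sample(c(0L, 1L), 50, replace = TRUE, prob = c(0.8, 0.2))
    codes <- cbind(base, other)
    a_ord <- krippendorff_alpha(codes, "ordinal")$alpha
    a_nom <- krippendorff_alpha(codes, "nominal")$alpha
    expect_gte(a_ord, a_nom)
  }
})

test_that("degenerate agreement matrices are refused", {
  expect_error(krippendorff_alpha(cbind(c(2, 2, 2), c(2, 2, 2))), "undefined")
  expect_error(krippendorff_alpha(matrix(1:4, ncol = 1)), "raters")
  expect_error(krippendorff_alpha(cbind(c(1, NA), c(NA, 2))), "pairable|non-missing")
})

test_that("bootstrap intervals are seeded, degenerate-aware and cover the estimate", {
  perfect <- cbind(c(1, 3, 2, 5, 6, 4), c(1, 3, 2, 5, 6, 4))
  ci <- alpha_bootstrap_ci(perfect, B = 200, seed = 5)
  expect_identical(c(ci$ci_low, ci$ci_high), c(1, 1))
  set.seed(30)
  codes <- cbind(sample.int(6, 200, replace = TRUE), 0L, 0L)
  codes[, 2] <- pmin(codes[, 1] + sample(0:1, 200, TRUE), 6L)
  codes[, 3] <- pmax(codes[, 1] - sample(0:1, 200, TRUE), 1L)
  r1 <- alpha_bootstrap_ci(codes, B = 300, seed = 9)
  r2 <- alpha_bootstrap_ci(codes, B = 300, seed = 9)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  full <- krippendorff_alpha(codes)$alpha
  expect_true(r1$ci_low <= full && full <= r1$ci_high)
  expect_error(alpha_bootstrap_ci(codes, B = 50, seed = 1), "100")
})
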