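test_that("the logistic toxicity model reproduces hand-computed values", {
  expect_equal(ntcp(0), 1 / (1 + exp(6.362)), tolerance = 1e-12)
  expect_equal(ntcp(0), 0.00172, tolerance = 2e-3)

  # additivity on the logit scale: the diabetes coefficient exactly
  for (e in c(0, 30, 57, 80)) {
    d1 <- ntcp(e, diabetes = 1)
    d0 <- ntcp(e, diabetes = 0)
    expect_equal(qlogis(d1) - qlogis(d0), 0.608, tolerance = 1e-12)
  }
  # spec'd pair: NTCP without diabetes 0.154 -> with ~0.251
  e154 <- (qlogis(0.154) + 6.362) / 0.084
  expect_equal(ntcp(e154, diabetes = 1), plogis(qlogis(0.154) + 0.608),
               tolerance = 1e-12)
  expect_equal(ntcp(e154, diabetes = 1), 0.251, tolerance = 2e-3)

  expect_gt(ntcp(1000), 0.999999)
  expect_error(ntcp(57, diabetes = 2), "diabetes")
  expect_error(ntcp(-1), "Gy")
})

test_that("NTCP is strictly increasing in each predictor", {
  es <- seq(0, 100, by = 1)
  p <- ntcp(es)
  expect_true(all(diff(p) > 0))
  expect_gt(ntcp(50, baseline_gi = 1), ntcp(50))
  expect_gt(ntcp(50, high_risk = 1), ntcp(50))
})

test_that("plausible rectum doses give plausible probabilities", {
  # regression lock on the model orientation: E of 55-60 Gy without
  # diabetes sits in the 0.13-0.22 band
  p <- ntcp(c(55, 57.5, 60))
  expect_true(all(p > 0.13 & p < 0.22))
})

test_that("ntcp_pair shares the dosimetric predictor and orders correctly", {
  set.seed(3)
  d <- runif(120, 5, 66)
  pr <- ntcp_pair(d, 19)
  expect_equal(pr$e_gy, rectum_geud_eqd2(d, 19, 3), tolerance = 1e-12)
  expect_gt(pr$with_diabetes, pr$without_diabetes)
  expect_equal(qlogis(pr$with_diabetes) - qlogis(pr$without_diabetes),
               0.608, tolerance = 1e-12)
})

test_that("coefficients can be overridden with documented provenance", {
  co <- ntcp_coefficients(beta_d = 0)
  expect_equal(ntcp(50, diabetes = 1, coefficients = co),
               ntcp(50, diabetes = 0, coefficients = co))
})
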