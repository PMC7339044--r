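test_that("closed-form dosimetry identities hold exactly", {
  expect_equal(geud(rep(50, 40), 7.7), 50, tolerance = 1e-9)
  expect_equal(geud(c(10, 20, 30), 1), 20, tolerance = 1e-9)
  expect_equal(ltcp(rep(64.6, 10), 64.6, 0.8), 1, tolerance = 1e-12)
  expect_equal(eqd2(40, 20, 3), 40, tolerance = 1e-12)
  expect_equal(ltcp(c(57.76, 57.76 - log(2) / 1.4), 57.76, 1.4), 1.5,
               tolerance = 1e-9)
  # hand-evaluated two-voxel gEUD and LQ conversion
  expect_equal(geud(c(0, 60), 7.7), 60 * 2^(-1 / 7.7), tolerance = 1e-9)
  expect_equal(eqd2(57, 19, 3), 57 * 6 / 5, tolerance = 1e-12)
  expect_equal(eqd2(0, 19, 3), 0)
})

test_that("dvh curves are monotone, start at 100 and shift with dose", {
  d <- c(40, 60)
  curve <- dvh(d, 0.5)
  expect_equal(curve$volume_pct[1], 100)
  expect_true(all(diff(curve$volume_pct) <= 0))
  expect_equal(curve$volume_pct[nrow(curve)], 0)
  q <- curve$volume_pct[curve$dose_gy > 40 & curve$dose_gy <= 60]
  expect_true(all(q == 50))

  u <- dvh(rep(50, 10), 1)
  expect_true(all(u$volume_pct[u$dose_gy <= 50] == 100))
  expect_true(all(u$volume_pct[u$dose_gy > 50] == 0))

  # shifting all doses right shifts the curve by the same amount
  d2 <- runif(200, 10, 60)
  c1 <- dvh(d2, 0.1); c2 <- dvh(d2 + 5, 0.1)
  at <- function(cv, x) cv$volume_pct[which.min(abs(cv$dose_gy - x))]
  for (x in c(20, 35.5, 50))
    expect_equal(at(c1, x), at(c2, x + 5))
})

test_that("coverage counts voxels at or above the isodose", {
  pd <- 57.76
  expect_equal(coverage(rep(0.96 * pd, 7), pd), 100)
  expect_equal(coverage(rep(0.90 * pd, 7), pd), 0)
  d <- c(rep(pd, 990), rep(0.5 * pd, 10))
  expect_equal(coverage(d, pd), 99)
  expect_error(coverage(numeric(0), pd), "empty")
})

test_that("mean/max/min summaries are order-invariant", {
  expect_equal(unname(mean_max_dose(rep(30, 5))), c(30, 30, 30))
  expect_equal(unname(mean_max_dose(c(10, 20, 30))), c(20, 30, 10))
  d <- runif(50, 0, 70)
  expect_equal(mean_max_dose(d), mean_max_dose(rev(d)))
})

test_that("gEUD is a power mean: monotone in k, between mean and max", {
  set.seed(42)
  for (rep in 1:5) {
    d <- runif(60, 0, 70)
    vals <- vapply(c(1, 2, 7.7, 20), geud, numeric(1), dose = d)
    expect_true(all(diff(vals) >= -1e-9))
    expect_equal(vals[1], mean(d), tolerance = 1e-12)
    expect_lte(vals[4], max(d) + 1e-9)
  }
})

test_that("LTCP is convex around the prescription (AM-GM spot check)", {
  pd <- 57.76; a <- 1.4
  set.seed(1)
  for (rep in 1:5) {
    d <- runif(30, 45, 70)
    expect_gte(ltcp(d, pd, a) * ltcp(2 * pd - d, pd, a), 1 - 1e-12)
  }
  # limits of the exponential
  expect_gt(ltcp(rep(pd - 20, 5), pd, a), 1e10)
  expect_lt(ltcp(rep(pd + 20, 5), pd, a), 1e-10)
})

test_that("the rectum EQD2-gEUD predictor composes and is monotone", {
  set.seed(7)
  d <- runif(80, 0, 65)
  expect_equal(rectum_geud_eqd2(d, 19, 3),
               geud(eqd2(d, 19, 3), 7.7), tolerance = 1e-12)
  # uniform dose already at 2 Gy/fraction equals the physical dose
  expect_equal(rectum_geud_eqd2(rep(38, 10), 19, 3), 38, tolerance = 1e-9)
  # adding dose to any voxel never decreases the predictor
  base <- rectum_geud_eqd2(d, 19, 3)
  for (j in c(1, 40, 80)) {
    d2 <- d; d2[j] <- d2[j] + 5
    expect_gte(rectum_geud_eqd2(d2, 19, 3), base - 1e-12)
  }
  # masking order is irrelevant: restriction then transform = transform
  # then restriction
  sel <- seq(1, 80, by = 3)
  expect_equal(geud(eqd2(d[sel], 19, 3), 7.7),
               geud(eqd2(d, 19, 3)[sel], 7.7), tolerance = 1e-12)
})
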