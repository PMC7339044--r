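test_that("piecewise-linear NTCP interpolation honours its contract", {
  # midpoint of a segment
  expect_equal(interpolate_ntcp(c(99, 95), c(0.20, 0.16), 97), 0.18)
  # node values reproduced exactly
  expect_equal(interpolate_ntcp(c(99, 96, 93), c(0.2, 0.17, 0.1),
                                c(99, 96, 93)), c(0.2, 0.17, 0.1))
  # no extrapolation below the achieved range
  expect_true(is.na(interpolate_ntcp(c(99, 93), c(0.2, 0.1), 90)))
  expect_error(interpolate_ntcp(c(99, 99), c(0.2, 0.2), 95), "distinct")
})

fake_patient <- function(id, overlap, curve_with, curve_without,
                         levels = 99:90) {
  structure(list(id = id, overlap_pct = overlap, prv_margin_mm = 25,
                 curve = data.frame(coverage = levels,
                                    ntcp_with = curve_with,
                                    ntcp_without = curve_without)),
            class = "patient_tradeoff")
}

test_that("diabetes compensation finds the largest compensating level", {
  lv <- 99:90
  # with-diabetes curve crosses the no-diabetes clinical value (0.15) at
  # level 91 (values 0.25, 0.2367, ..., 0.1567 at 92, 0.1433 at 91)
  with_c <- seq(0.25, 0.13, length.out = 10)
  without_c <- seq(0.15, 0.08, length.out = 10)
  p <- fake_patient(1, 5, with_c, without_c)
  comp <- diabetes_compensation(p)
  expect_equal(comp$compensating_coverage, 91)
  expect_lte(comp$residual_gap, 0)

  # never compensates: returns NA plus the positive residual gap
  p2 <- fake_patient(2, 1, seq(0.3, 0.2, length.out = 10), without_c)
  comp2 <- diabetes_compensation(p2)
  expect_true(is.na(comp2$compensating_coverage))
  expect_gt(comp2$residual_gap, 0)

  # zero diabetes effect: compensation already at the clinical level
  p3 <- fake_patient(3, 5, without_c, without_c)
  expect_equal(diabetes_compensation(p3)$compensating_coverage, 99)
})

test_that("cohort summaries aggregate with the sample-SD convention", {
  lv <- 99:90
  mk <- function(id, ov, top, slope)
    fake_patient(id, ov, top - slope * (99 - lv), 0.6 * (top - slope * (99 - lv)))
  patients <- list(mk(1, 2, 0.20, 0.002), mk(2, 8, 0.24, 0.004))
  cs <- cohort_summary(patients)
  expect_equal(cs$levels$ntcp_with_mean[1], mean(c(0.20, 0.24)))
  expect_equal(cs$levels$ntcp_with_sd[1], sd(c(0.20, 0.24)))
  # reductions at a level: hand arithmetic, mean and range
  at95 <- cs$levels[cs$levels$coverage == 95, ]
  expect_equal(at95$reduction_with_mean, mean(c(0.002, 0.004) * 4))
  expect_equal(at95$reduction_with_min, 0.008)
  expect_equal(at95$reduction_with_max, 0.016)

  # perfectly collinear reduction-overlap points: R^2 = 1, slope > 0
  p3 <- mk(3, 5, 0.22, 0.003)
  cs3 <- cohort_summary(list(patients[[1]], patients[[2]], p3))
  reg <- cs3$regressions[cs3$regressions$coverage == 95, ]
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  expect_gt(reg$slope, 0)

  # identical overlaps: regression flagged degenerate
  pd1 <- mk(1, 3, 0.2, 0.002); pd2 <- mk(2, 3, 0.24, 0.004)
  pd3 <- mk(3, 3, 0.22, 0.003)
  csd <- cohort_summary(list(pd1, pd2, pd3))
  expect_true(all(csd$regressions$degenerate))
})

test_that("the seven-plan workflow has the required structure", {
  pt <- cached_workflow()
  expect_s3_class(pt, "patient_tradeoff")
  expect_length(pt$plans, 7L)
  expect_equal(nrow(pt$metrics), 7L)
  expect_equal(pt$metrics$plan[1], "clinical")
  expect_equal(pt$prv_margin_mm, select_prv_margin(pt$overlap_pct))
  # clinical plan meets the protocol's coverage requirements
  expect_gte(pt$metrics$ptv_low_coverage[1], 99)
  expect_gte(pt$metrics$ptv_high_coverage[1], 99)
  expect_equal(pt$metrics$ctv_high_coverage, rep(100, 7))
  expect_equal(pt$metrics$ctv_low_coverage, rep(100, 7))
  # curve levels are the integer ladder
  expect_equal(pt$curve$coverage, 99:90)
})

test_that("x_schedule must be strictly increasing", {
  inp <- test_patient_inputs()
  expect_error(run_patient(inp$phantom, dij = inp$dij,
                           x_schedule = c(2, 2, 3)),
               "increasing")
})
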