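test_that("phantom generation is a pure function of seed and params", {
  pp <- test_phantom_params()
  a <- generate_phantom(7, pp)
  b <- generate_phantom(7, pp)
  expect_identical(a$masks, b$masks)
  expect_identical(a$anatomy_params, b$anatomy_params)

  c <- generate_phantom(8, pp)
  expect_false(all(mapply(identical, a$masks, c$masks)))
})

test_that("phantom masks satisfy the anatomical invariants", {
  pp <- test_phantom_params()
  for (seed in c(1, 7, 23)) {
    ph <- generate_phantom(seed, pp)
    m <- ph$masks
    expect_true(all(m$CTV_High[m$CTV_High] & m$CTV_Low[m$CTV_High]))
    expect_false(any(m$CTV_High & m$rectum))
    for (nm in setdiff(names(m), "external")) {
      expect_true(any(m[[nm]]), label = paste(nm, "non-empty"))
      expect_true(all(m$external[m[[nm]]]),
                  label = paste(nm, "inside external"))
    }
  }
})

test_that("maximum rectum separation gives zero overlap potential", {
  pp <- test_phantom_params()
  pp$rectum_gap_mm <- c(11.9, 12)
  ph <- generate_phantom(3, pp)
  grown <- expand_mask(ph$masks$CTV_Low, ph$grid, 10)
  expect_false(any(grown & ph$masks$rectum))
})

test_that("degenerate parameters name the offending structure", {
  pp <- test_phantom_params()
  pp$bladder_rx <- pp$bladder_ry <- pp$bladder_rz <- c(200, 201)
  expect_error(generate_phantom(1, pp), "bladder")
})

test_that("cohorts are seeded, sized and reproducible", {
  pp <- test_phantom_params()
  expect_error(generate_cohort(0, 1, pp), "n")
  one <- generate_cohort(1, 1, pp)
  expect_length(one, 1L)
  a <- generate_cohort(5, 1, pp)
  b <- generate_cohort(5, 1, pp)
  expect_identical(lapply(a, `[[`, "masks"), lapply(b, `[[`, "masks"))
})

test_that("a default cohort spans several PRV-margin overlap classes", {
  pp <- test_phantom_params()
  cohort <- generate_cohort(30, 1, pp)
  ovs <- vapply(cohort, function(ph) {
    # overlap needs only PTV_Low, not the full planning structure set
    ptv_low <- expand_mask(ph$masks$CTV_Low, ph$grid, 9) &
      ph$masks$external
    100 * sum(ph$masks$rectum & ptv_low) / sum(ph$masks$rectum)
  }, numeric(1))
  classes <- unique(vapply(ovs, select_prv_margin, numeric(1)))
  expect_gte(length(classes), 3L)
  expect_true(any(ovs < 4))
  expect_true(any(ovs >= 4 & ovs < 6) || any(ovs >= 6))
  expect_true(any(ovs >= 7))
})

test_that("dose influence behaves like a physical beamlet model", {
  pp <- test_phantom_params()
  ph <- generate_phantom(7, pp)

  # sharp beamlets, no attenuation: every voxel on a ray gets equal dose
  dij0 <- compute_dose_influence(
    ph, beam_config(n_beams = 2, beamlet_width_mm = 8,
                    attenuation_coeff = 0, penumbra_sigma = 0))
  expect_true(all(dij0$matrix@x > 0))
  col1 <- dij0$matrix[, 1]
  expect_true(all(abs(col1[col1 > 0] - 1) < 1e-12))

  dij <- test_patient_inputs()$dij
  expect_true(all(dij$matrix@x > 0))
  expect_true(all(Matrix::colSums(dij$matrix) > 0))

  # linearity and homogeneity of the dose operator
  w1 <- runif(ncol(dij$matrix)); w2 <- runif(ncol(dij$matrix))
  d1 <- dose_from_weights(dij, w1)
  d2 <- dose_from_weights(dij, w2)
  expect_equal(dose_from_weights(dij, w1 + w2), d1 + d2, tolerance = 1e-12)
  expect_equal(dose_from_weights(dij, 2 * w1), 2 * d1, tolerance = 1e-12)
  expect_error(dose_from_weights(dij, -w1), "non-negative")

  # attenuation: dose decreases with depth along a beamlet's central ray
  cfg <- beam_config(n_beams = 2, beamlet_width_mm = 8,
                     attenuation_coeff = 0.01, penumbra_sigma = 0)
  dija <- compute_dose_influence(ph, cfg)
  v <- dija$matrix[, 1]
  rows <- which(v > 0)
  xyz <- voxel_coords(ph$grid)[dija$voxel_index[rows], , drop = FALSE]
  th <- dija$beam_angles[dija$beam_of_beamlet[1]]
  s <- xyz[, 1] * cos(th) + xyz[, 2] * sin(th)
  u <- -xyz[, 1] * sin(th) + xyz[, 2] * cos(th)
  central <- abs(u - dija$beamlet_u[1]) < 1e-6 &
    abs(xyz[, 3] - dija$beamlet_z[1]) < 1e-6
  ord <- order(s[central])
  expect_true(all(diff(v[rows][central][ord]) <= 1e-12))

  # cross-fire: mean target dose exceeds mean surface dose
  w <- rep(1, ncol(dij$matrix))
  d <- dose_from_weights(dij, w)
  tgt <- mean(d[structure_rows(dij, ph$masks$CTV_High)])
  depth <- distance_map(!ph$masks$external, ph$grid)
  surf <- d[depth[dij$voxel_index] <= max(ph$grid$spacing)]
  expect_gt(tgt / mean(surf), 1)
})
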