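test_that("percentage limits resolve to absolute Gy", {
  wl <- resolve_limits(build_clinical_wishlist())
  lim <- vapply(wl$constraints, `[[`, numeric(1), "limit_gy")
  expect_equal(lim[1], 1.05 * 64.6, tolerance = 1e-12)   # 67.83
  expect_equal(lim[5], 65.892, tolerance = 1e-12)        # rectum 102%
  expect_equal(lim[8], 0.95 * 64.6, tolerance = 1e-12)
  expect_equal(lim[9], 0.95 * 57.76, tolerance = 1e-12)
  # percent goals and absolute goals
  goals <- vapply(wl$objectives, `[[`, numeric(1), "goal_val")
  expect_equal(goals[5], 11.552, tolerance = 1e-12)      # 20% of PD_Low
  expect_equal(goals[13], 40)                            # hip, plain Gy
  # LTCP pd resolution: 99.5% of PD_High
  expect_equal(wl$objectives[[1]]$pd_gy, 0.995 * 64.6, tolerance = 1e-12)
  expect_error(pct_of(50, "PD_Mid"), "arg")
})

test_that("the clinical wish-list mirrors the planning protocol", {
  wl <- build_clinical_wishlist()
  expect_length(wl$constraints, 9L)
  prios <- vapply(wl$objectives, `[[`, integer(1), "priority")
  enabled <- vapply(wl$objectives, `[[`, logical(1), "enabled")
  expect_equal(prios[enabled], c(1L, 3L, 4L, 5L, 5L, 6L, 7L, 8L, 8L, 9L,
                                 10L, 10L))
  expect_false(enabled[prios == 2L])
  p1 <- wl$objectives[[1]]
  expect_equal(p1$kind, "ltcp")
  expect_equal(p1$alpha, 0.8)
  expect_equal(p1$goal, 0.8)
  expect_equal(p1$pd$value, 99.5)
  p3 <- wl$objectives[[which(prios == 3L)]]
  expect_equal(p3$structure, "PTV_Low")
  expect_equal(p3$goal, 0.4)
  expect_equal(p3$alpha, 1.4)
})

test_that("the reduced wish-list swaps the bladder objective for a constraint", {
  wl <- build_reduced_wishlist(x_value = 30, bladder_dmean_clinical = 44.2)
  expect_length(wl$constraints, 10L)
  bl <- wl$constraints[[10]]
  expect_equal(bl$structure, "bladder")
  expect_equal(bl$kind, "mean_dose")
  expect_equal(bl$limit, 44.2)
  prios <- vapply(wl$objectives, `[[`, integer(1), "priority")
  expect_false(9L %in% prios)
  expect_true(all(vapply(wl$objectives, `[[`, logical(1), "enabled")))
  p3 <- wl$objectives[[which(prios == 3L)]]
  expect_equal(p3$goal, 30)
  p2 <- wl$objectives[[which(prios == 2L)]]
  expect_equal(p2$structure, "PTV_Low_minus_RectumPRV")
  expect_equal(p2$goal, 0.4)
  expect_error(build_reduced_wishlist(x_value = 30), "bladder")
})

test_that("wish-lists round-trip through YAML", {
  wl <- build_clinical_wishlist()
  path <- tempfile(fileext = ".yaml")
  save_wishlist(wl, path)
  wl2 <- load_wishlist(path)
  r1 <- resolve_limits(wl)
  r2 <- resolve_limits(wl2)
  expect_equal(vapply(r1$constraints, `[[`, numeric(1), "limit_gy"),
               vapply(r2$constraints, `[[`, numeric(1), "limit_gy"))
  expect_equal(vapply(r1$objectives, `[[`, numeric(1), "goal_val"),
               vapply(r2$objectives, `[[`, numeric(1), "goal_val"))
  expect_equal(vapply(r1$objectives, `[[`, logical(1), "enabled"),
               vapply(r2$objectives, `[[`, logical(1), "enabled"))
  # idempotence: save(load(x)) is stable
  path2 <- tempfile(fileext = ".yaml")
  save_wishlist(wl2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("the shipped clinical wish-list loads and validates", {
  shipped <- system.file("extdata", "wishlist_clinical.yaml",
                         package = "prioplan")
  wl <- load_wishlist(shipped)
  expect_length(wl$constraints, 9L)
  prios <- vapply(wl$objectives, `[[`, integer(1), "priority")
  enabled <- vapply(wl$objectives, `[[`, logical(1), "enabled")
  expect_equal(prios[enabled],
               c(1L, 3L, 4L, 5L, 5L, 6L, 7L, 8L, 8L, 9L, 10L, 10L))

  # schema violations are rejected with location information
  y <- yaml::read_yaml(shipped)
  y$constraints[[3]]$bogus <- 1
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(y, bad)
  expect_error(load_wishlist(bad), "constraint 3")

  y <- yaml::read_yaml(shipped)
  y$constraints[[2]]$structure <- "no_such_organ"
  yaml::write_yaml(y, bad)
  inp <- test_patient_inputs()
  expect_error(load_wishlist(bad, inp$structures), "no_such_organ")
})

test_that("evaluate_cost dispatches to the dosimetry primitives", {
  inp <- test_patient_inputs()
  dij <- inp$dij
  ss <- inp$structures
  set.seed(11)
  w <- runif(ncol(dij$matrix), 0, 0.2)
  dose <- dose_from_weights(dij, w)
  wl <- resolve_limits(build_clinical_wishlist())

  rect <- dose[structure_rows(dij, ss$masks$rectum)]
  spec_max <- wl$constraints[[5]]
  expect_equal(evaluate_cost(spec_max, dose, ss, dij$voxel_index),
               max(rect), tolerance = 1e-12)
  o4 <- wl$objectives[[which(vapply(wl$objectives, `[[`, integer(1),
                                    "priority") == 4L)]]
  expect_equal(evaluate_cost(o4, dose, ss, dij$voxel_index),
               geud(rect, 7.7), tolerance = 1e-12)
  o1 <- wl$objectives[[1]]
  ph <- dose[structure_rows(dij, ss$masks$PTV_High)]
  expect_equal(evaluate_cost(o1, dose, ss, dij$voxel_index),
               ltcp(ph, 0.995 * 64.6, 0.8), tolerance = 1e-10)
  bad <- o1; bad$structure <- "nope"
  expect_error(evaluate_cost(bad, dose, ss, dij$voxel_index), "unknown")
})
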