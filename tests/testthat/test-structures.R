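test_that("mask expansion is an exact Euclidean dilation", {
  g <- grid_spec(c(25, 25, 13), c(2, 2, 2))
  m <- empty_mask(g); m[13, 13, 7] <- TRUE

  expect_identical(expand_mask(m, g, 0), m)
  expect_error(expand_mask(m, g, -1), "non-negative")

  # single seed voxel: expansion = ball of the margin radius
  for (r in c(4, 7)) {
    got <- expand_mask(m, g, r)
    xyz <- voxel_coords(g)
    centre <- xyz[which(m), ]
    dist <- sqrt(colSums((t(xyz) - centre)^2))
    expect_identical(as.vector(got), dist <= r + 1e-9)
  }

  # voxelised sphere expanded by 5 mm ~ sphere of summed radius
  sph <- array(sqrt(colSums((t(voxel_coords(g)))^2)) <= 10, g$shape)
  got <- expand_mask(sph, g, 5)
  dist <- sqrt(colSums(t(voxel_coords(g))^2))
  inner <- dist <= 15 - sqrt(sum(g$spacing^2))  # one voxel-diagonal slack
  outer <- dist <= 15 + sqrt(sum(g$spacing^2))
  expect_true(all(got[array(inner, g$shape)]))
  expect_true(all(!got[!array(outer, g$shape)]))

  # monotone in margin and in the mask
  expect_true(all(expand_mask(sph, g, 8)[expand_mask(sph, g, 5)]))
  sub <- sph & array(voxel_coords(g, 1) < 0, g$shape)
  expect_true(all(expand_mask(sph, g, 5)[expand_mask(sub, g, 5)]))

  # composition covers the summed margin within one voxel diagonal
  e1 <- expand_mask(expand_mask(sph, g, 4), g, 6)
  e2 <- expand_mask(sph, g, 10 - sqrt(sum(g$spacing^2)))
  expect_true(all(e1[e2]))
  expect_true(all(expand_mask(sph, g, 10)[e1]))  # and never overshoots it
})

test_that("planning structures satisfy their set relations", {
  inp <- test_patient_inputs()
  ss <- inp$structures
  m <- ss$masks
  expect_false(any(m$PTV_High & m$rectum))
  expect_true(all(m$PTV_High[m$CTV_High]))  # CTV_High never meets rectum
  expect_true(all(m$PTV_Low[m$CTV_Low]))
  expect_true(all(m$PTV_Low[m$PTV_Low_minus_expanded_PTV_High]))
  expect_true(all(m$PTV_Low[m$PTV_Low_minus_RectumPRV]))
  shells <- m[grep("^Shell", names(m))]
  for (i in seq_along(shells)) {
    expect_false(any(shells[[i]] & m$PTV_Low))
    expect_true(all(m$external[shells[[i]]]))
    for (j in seq_len(i - 1L))
      expect_false(any(shells[[i]] & shells[[j]]))
  }
  expect_false(any(m$EntranceDose & expand_mask(m$PTV_Low, ss$grid, 50)))

  # no-overlap phantom: PTV_High is the uncarved expansion
  pp <- test_phantom_params()
  pp$rectum_gap_mm <- c(11.5, 12)
  far <- generate_phantom(5, pp)
  ssf <- build_planning_structures(far)
  expect_identical(ssf$masks$PTV_High,
                   expand_mask(far$masks$CTV_High, far$grid, 5) &
                     far$masks$external)
})

test_that("overlap percentage uses the rectum volume as denominator", {
  g <- grid_spec(c(20, 10, 10), c(2, 2, 2))
  rectum <- empty_mask(g); rectum[1:10, 1:10, 1:10] <- TRUE  # 1000 voxels
  ptv <- empty_mask(g); ptv[1:11, 1:5, 1] <- TRUE
  ptv[1:5, 1, 2] <- TRUE  # 55 rectum voxels inside, plus 5 outside rectum? no
  ss <- structure(list(masks = list(rectum = rectum, PTV_Low = ptv),
                       grid = g), class = "structure_set")
  ov <- overlap_percentage(ss)
  expect_equal(ov$overlap_voxels, sum(rectum & ptv))
  expect_equal(ov$overlap_pct, 100 * sum(rectum & ptv) / 1000)
  expect_identical(ov$denominator_convention, "rectum")

  # constructed 5.5%: 55 of 1000 rectum voxels inside PTV_Low
  ptv2 <- empty_mask(g)
  ptv2[1:10, 1:5, 1] <- TRUE   # 50 voxels inside the rectum
  ptv2[1:5, 6, 1] <- TRUE      # plus 5 more
  ss$masks$PTV_Low <- ptv2
  expect_equal(overlap_percentage(ss)$overlap_pct, 5.5)

  ss$masks$PTV_Low <- empty_mask(g)
  expect_equal(overlap_percentage(ss)$overlap_pct, 0)
  ss$masks$PTV_Low <- array(TRUE, g$shape)
  expect_equal(overlap_percentage(ss)$overlap_pct, 100)
  ss$masks$rectum <- empty_mask(g)
  expect_error(overlap_percentage(ss), "empty")
})

test_that("the overlap-dependent PRV margin rule matches the protocol", {
  expect_equal(select_prv_margin(0), 25)
  expect_equal(select_prv_margin(2), 25)
  expect_equal(select_prv_margin(3.999), 25)
  expect_equal(select_prv_margin(4), 20)
  expect_equal(select_prv_margin(5), 20)
  expect_equal(select_prv_margin(6), 15)
  expect_equal(select_prv_margin(6.5), 15)
  expect_equal(select_prv_margin(7), 10)
  expect_equal(select_prv_margin(8), 10)
  expect_equal(select_prv_margin(100), 10)
  expect_error(select_prv_margin(-1), "0")
  expect_error(select_prv_margin(101), "100")
})

test_that("rectum PRV construction shrinks the covered target monotonically", {
  inp <- test_patient_inputs()
  ss <- build_planning_structures(inp$phantom)
  sizes <- vapply(c(10, 15, 20, 25), function(mm)
    sum(build_rectum_prv(ss, mm)$masks$PTV_Low_minus_RectumPRV),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))

  # zero overlap: nothing is subtracted
  pp <- test_phantom_params()
  pp$rectum_gap_mm <- c(11.5, 12)
  far <- build_planning_structures(generate_phantom(5, pp))
  far <- build_rectum_prv(far, 25)
  expect_identical(far$masks$PTV_Low_minus_RectumPRV, far$masks$PTV_Low)

  # zero margin subtracts exactly the overlap
  ss0 <- build_rectum_prv(ss, 0)
  expect_identical(ss0$masks$PTV_Low_minus_RectumPRV,
                   ss$masks$PTV_Low & !(ss$masks$rectum & ss$masks$PTV_Low))
})
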