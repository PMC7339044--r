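# Synthetic pelvic phantom generation. Geometry is a deliberately simple
# analog (ellipsoids, tubes, spheres) that preserves the one feature driving
# the coverage-toxicity trade-off: the posterior PTV_Low surface overlapping
# the anterior rectum wall by a patient-specific amount.

local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Anatomy sampling parameters for the synthetic pelvic phantom
#'
#' Ranges (mm) from which per-patient organ dimensions are drawn, plus the
#' rectum-proximity range controlling how far the anterior rectum surface
#' sits behind the posterior-most clinical target surface. Smaller gaps
#' produce larger PTV_Low-rectum overlap once the PTV margin is applied;
#' gaps above the PTV_Low margin give zero overlap.
#'
#' @param prostate_rx,prostate_ry,prostate_rz prostate semi-axis ranges.
#' @param vesicle_r seminal-vesicle lobe radius range.
#' @param bladder_rx,bladder_ry,bladder_rz bladder semi-axis ranges.
#' @param rectum_r rectum tube radius range.
#' @param anus_r anus tube radius range.
#' @param hip_r femoral-head sphere radius range.
#' @param rectum_gap_mm range of the rectum proximity parameter: mm of
#'   tissue between the posterior CTV_Low surface and the anterior rectum
#'   surface. Must stay > 0 so the clinical target never touches rectum.
#' @param grid \code{grid_spec} for the phantom (default 64 x 64 x 16
#'   voxels at 2.5 x 2.5 x 4 mm).
#' @return A list of class \code{phantom_params}.
#' @export
phantom_params <- function(prostate_rx = c(16, 20),
                           prostate_ry = c(12, 15),
                           prostate_rz = c(12, 15),
                           vesicle_r = c(8, 10),
                           bladder_rx = c(15, 19),
                           bladder_ry = c(12, 16),
                           bladder_rz = c(10, 14),
                           rectum_r = c(7, 10),
                           anus_r = c(5, 7),
                           hip_r = c(12, 15),
                           rectum_gap_mm = c(0.5, 14),
                           grid = grid_spec(c(64, 64, 16),
                                            c(2.5, 2.5, 4))) {
  p <- list(prostate_rx = prostate_rx, prostate_ry = prostate_ry,
            prostate_rz = prostate_rz, vesicle_r = vesicle_r,
            bladder_rx = bladder_rx, bladder_ry = bladder_ry,
            bladder_rz = bladder_rz, rectum_r = rectum_r, anus_r = anus_r,
            hip_r = hip_r, rectum_gap_mm = rectum_gap_mm, grid = grid,
            # fixed layout (mm): y+ is posterior, z+ superior
            prostate_center = c(0, -8, 0),
            vesicle_dx = 8, vesicle_dy = 10, vesicle_dz = 14,
            bladder_center = c(0, -27, 12),
            hip_x = 50, hip_z = 0,
            rectum_z = c(-14, 24), anus_z = c(-24, -14),
            external_ab = c(72, 58))
  for (nm in c("prostate_rx", "prostate_ry", "prostate_rz", "vesicle_r",
               "bladder_rx", "bladder_ry", "bladder_rz", "rectum_r",
               "anus_r", "hip_r", "rectum_gap_mm")) {
    r <- p[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop(sprintf("`%s` must be a (lo, hi) range", nm), call. = FALSE)
  }
  if (p$rectum_gap_mm[1] <= 0)
    stop("rectum_gap_mm must stay > 0 (CTV may never touch rectum)",
         call. = FALSE)
  class(p) <- "phantom_params"
  p
}

runif_range <- function(r) stats::runif(1, r[1], r[2])

ellipsoid_mask <- function(grid, center, radii) {
  x <- voxel_coords(grid, 1); y <- voxel_coords(grid, 2)
  z <- voxel_coords(grid, 3)
  ((x - center[1]) / radii[1])^2 + ((y - center[2]) / radii[2])^2 +
    ((z - center[3]) / radii[3])^2 <= 1
}

tube_mask <- function(grid, xy_center, radius, z_range) {
  x <- voxel_coords(grid, 1); y <- voxel_coords(grid, 2)
  z <- voxel_coords(grid, 3)
  ((x - xy_center[1])^2 + (y - xy_center[2])^2 <= radius^2) &
    z >= z_range[1] & z <= z_range[2]
}

check_fits <- function(name, bbox_lo, bbox_hi, grid) {
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1L) * grid$spacing
  if (any(bbox_lo < lo) || any(bbox_hi > hi))
    stop(sprintf("structure '%s' does not fit inside the phantom grid",
                 name), call. = FALSE)
}

#' Generate one seeded synthetic pelvic phantom
#'
#' Draws per-patient anatomy from \code{params}, voxelises it on the grid
#' and returns binary masks for CTV_High (prostate), CTV_Low (prostate plus
#' seminal-vesicle lobes), rectum, bladder, anus, both hips, and the
#' external contour. The same seed and parameters always reproduce the
#' identical phantom.
#'
#' @param seed integer RNG seed.
#' @param params a \code{phantom_params} object.
#' @return An object of class \code{phantom}: list with \code{grid},
#'   \code{masks}, \code{anatomy_params} (the sampled values) and
#'   \code{seed}.
#' @examples
#' ph <- generate_phantom(7)
#' sapply(ph$masks, sum)
#' @export
generate_phantom <- function(seed, params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  grid <- params$grid
  a <- local_seed(seed, list(
    prostate_r = c(runif_range(params$prostate_rx),
                   runif_range(params$prostate_ry),
                   runif_range(params$prostate_rz)),
    vesicle_r = runif_range(params$vesicle_r),
    bladder_r = c(runif_range(params$bladder_rx),
                  runif_range(params$bladder_ry),
                  runif_range(params$bladder_rz)),
    rectum_r = runif_range(params$rectum_r),
    anus_r = runif_range(params$anus_r),
    hip_r = runif_range(params$hip_r),
    rectum_gap = runif_range(params$rectum_gap_mm)))

  pc <- params$prostate_center
  # posterior-most CTV_Low surface (prostate dominates; vesicle lobes sit
  # slightly less posterior by construction)
  y_post <- max(pc[2] + a$prostate_r[2],
                pc[2] + params$vesicle_dy + a$vesicle_r)
  rect_xy <- c(0, y_post + a$rectum_gap + a$rectum_r)

  check_fits("prostate", pc - a$prostate_r, pc + a$prostate_r, grid)
  check_fits("bladder", params$bladder_center - a$bladder_r,
             params$bladder_center + a$bladder_r, grid)
  check_fits("rectum",
             c(rect_xy - a$rectum_r, params$rectum_z[1]),
             c(rect_xy + a$rectum_r, params$rectum_z[2]), grid)
  check_fits("hip_left",
             c(-params$hip_x - a$hip_r, -a$hip_r, params$hip_z - a$hip_r),
             c(-params$hip_x + a$hip_r, a$hip_r, params$hip_z + a$hip_r),
             grid)

  x <- voxel_coords(grid, 1); y <- voxel_coords(grid, 2)
  external <- (x / params$external_ab[1])^2 +
    (y / params$external_ab[2])^2 <= 1

  prostate <- ellipsoid_mask(grid, pc, a$prostate_r)
  lobes <-
    ellipsoid_mask(grid, pc + c(params$vesicle_dx, params$vesicle_dy,
                                params$vesicle_dz), rep(a$vesicle_r, 3)) |
    ellipsoid_mask(grid, pc + c(-params$vesicle_dx, params$vesicle_dy,
                                params$vesicle_dz), rep(a$vesicle_r, 3))
  ctv_low <- prostate | lobes
  rectum <- tube_mask(grid, rect_xy, a$rectum_r, params$rectum_z)
  anus <- tube_mask(grid, rect_xy, a$anus_r, params$anus_z)
  bladder <- ellipsoid_mask(grid, params$bladder_center, a$bladder_r)
  hip_l <- ellipsoid_mask(grid, c(-params$hip_x, 0, params$hip_z),
                          rep(a$hip_r, 3))
  hip_r <- ellipsoid_mask(grid, c(params$hip_x, 0, params$hip_z),
                          rep(a$hip_r, 3))

  masks <- list(CTV_High = prostate, CTV_Low = ctv_low, rectum = rectum,
                bladder = bladder, anus = anus, hip_left = hip_l,
                hip_right = hip_r)
  masks <- lapply(masks, function(m) m & external)
  masks$external <- external

  for (nm in names(masks))
    if (!any(masks[[nm]]))
      stop(sprintf("structure '%s' voxelised to an empty mask", nm),
           call. = FALSE)
  if (any(masks$CTV_High & masks$rectum))
    stop("generated CTV_High intersects rectum; increase rectum_gap_mm",
         call. = FALSE)

  structure(list(grid = grid, masks = masks, anatomy_params = a,
                 seed = as.integer(seed)),
            class = "phantom")
}

#' @exportS3Method base::print
print.phantom <- function(x, ...) {
  cat("<phantom> seed", x$seed, "grid",
      paste(x$grid$shape, collapse = "x"), "\n")
  v <- vapply(x$masks, sum, numeric(1))
  cat(paste(sprintf("  %-10s %6d vox", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

#' Generate a cohort of synthetic patients
#'
#' @param n number of phantoms (>= 1).
#' @param seed integer master seed; per-patient seeds are derived from it.
#' @param params a \code{phantom_params} object shared by the cohort.
#' @return List of \code{phantom} objects with independently sampled
#'   anatomy.
#' @export
generate_cohort <- function(n, seed, params = phantom_params()) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  seeds <- local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seeds, generate_phantom, params = params)
}
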