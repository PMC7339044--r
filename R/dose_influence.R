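# Simplified beamlet dose model: static equi-angular coplanar beams of
# finite rectangular beamlets, exponential depth attenuation and a
# Gaussian-blurred lateral profile. This emulates cross-firing photon
# delivery well enough to exercise the planning machinery; it is not a
# delivery or beam-physics model.

#' Beam configuration for the simplified dose-influence model
#'
#' @param n_beams number of equi-angular coplanar beam directions (>= 2).
#' @param beamlet_width_mm beamlet size (lateral and axial) in mm.
#' @param attenuation_coeff exponential attenuation per mm of tissue depth
#'   (>= 0; ~0.004/mm mimics megavoltage depth falloff).
#' @param penumbra_sigma Gaussian blur (mm) of the beamlet edge profile
#'   (>= 0; 0 gives sharp-edged rays).
#' @return An object of class \code{beam_config}.
#' @export
beam_config <- function(n_beams = 12L, beamlet_width_mm = 7,
                        attenuation_coeff = 0.004, penumbra_sigma = 2.5) {
  n_beams <- as.integer(n_beams)
  if (is.na(n_beams) || n_beams < 2L) stop("n_beams must be >= 2",
                                           call. = FALSE)
  if (!(beamlet_width_mm > 0)) stop("beamlet_width_mm must be > 0",
                                    call. = FALSE)
  if (attenuation_coeff < 0) stop("attenuation_coeff must be >= 0",
                                  call. = FALSE)
  if (penumbra_sigma < 0) stop("penumbra_sigma must be >= 0", call. = FALSE)
  structure(list(n_beams = n_beams, beamlet_width_mm = beamlet_width_mm,
                 attenuation_coeff = attenuation_coeff,
                 penumbra_sigma = penumbra_sigma),
            class = "beam_config")
}

# blurred top-hat edge profile: convolution of a width-w indicator with a
# Gaussian of sd sigma; reduces to the sharp indicator at sigma = 0
edge_profile <- function(x, w, sigma) {
  if (sigma == 0) return(as.numeric(abs(x) <= w / 2))
  stats::pnorm((x + w / 2) / sigma) - stats::pnorm((x - w / 2) / sigma)
}

#' Compute the dose-influence matrix for a phantom
#'
#' Ray-traces rectangular beamlets from \code{n_beams} equi-angular
#' coplanar directions through the external contour. Each beamlet deposits
#' \code{exp(-mu * depth)} per unit weight along its ray, spread laterally
#' and axially by the blurred-edge profile. The beamlet grid of each beam
#' covers the projection of the planning target region (CTV_Low expanded by
#' \code{target_margin_mm}).
#'
#' @param phantom a \code{phantom}.
#' @param config a \code{beam_config}.
#' @param target_margin_mm margin (mm) around CTV_Low defining the region
#'   the beamlet grids must cover (default 10, enclosing the eventual
#'   PTV_Low).
#' @return An object of class \code{dose_influence}: sparse
#'   voxels-inside-external x beamlets matrix (Gy per unit weight) plus
#'   beamlet bookkeeping (\code{beam_of_beamlet}, positions, angles,
#'   \code{voxel_index} mapping rows to grid voxels).
#' @export
compute_dose_influence <- function(phantom, config = beam_config(),
                                   target_margin_mm = 10) {
  stopifnot(inherits(phantom, "phantom"), inherits(config, "beam_config"))
  grid <- phantom$grid
  ext <- phantom$masks$external
  vox_idx <- which(ext)
  xyz <- voxel_coords(grid)[vox_idx, , drop = FALSE]
  target <- expand_mask(phantom$masks$CTV_Low, grid, target_margin_mm) & ext
  if (!any(target))
    stop("beamlet grid covers no target voxels", call. = FALSE)
  t_xyz <- voxel_coords(grid)[which(target), , drop = FALSE]

  w <- config$beamlet_width_mm
  sigma <- config$penumbra_sigma
  mu <- config$attenuation_coeff
  reach <- w / 2 + 2.5 * sigma
  angles <- 2 * pi * (seq_len(config$n_beams) - 1L) / config$n_beams

  # one extra beamlet row beyond the span so edge voxels sit under a flat
  # part of the outermost beamlet, not in its half-profile
  centers_covering <- function(vals) {
    k <- max(1L, ceiling((max(vals) - min(vals)) / w) + 1L)
    mid <- (max(vals) + min(vals)) / 2
    mid + (seq_len(k) - (k + 1) / 2) * w
  }
  z0s <- centers_covering(t_xyz[, 3])

  ii <- list(); jj <- list(); xx <- list()
  beam_of <- integer(0); b_u <- numeric(0); b_z <- numeric(0)
  col <- 0L
  du <- min(grid$spacing[1:2])
  for (b in seq_along(angles)) {
    th <- angles[b]
    v <- c(cos(th), sin(th)); p <- c(-sin(th), cos(th))
    u <- xyz[, 1] * p[1] + xyz[, 2] * p[2]
    s <- xyz[, 1] * v[1] + xyz[, 2] * v[2]
    zc <- xyz[, 3]
    # radiological depth: distance along the ray from the external surface,
    # per (lateral, axial) ray bin
    key <- as.integer(round(u / du)) - min(as.integer(round(u / du))) +
      1000L * match(zc, sort(unique(zc)))
    depth <- s - stats::ave(s, key, FUN = min)
    att <- if (mu > 0) exp(-mu * depth) else rep(1, length(depth))

    ut <- t_xyz[, 1] * p[1] + t_xyz[, 2] * p[2]
    u0s <- centers_covering(ut)
    for (z0 in z0s) {
      zsel <- which(abs(zc - z0) <= reach)
      if (length(zsel) == 0L) next
      tz <- abs(t_xyz[, 3] - z0) <= w / 2
      pz <- edge_profile(zc[zsel] - z0, w, sigma)
      for (u0 in u0s) {
        # keep only beamlets whose cell intersects the target projection
        if (!any(tz & abs(ut - u0) <= w / 2)) next
        usel <- which(abs(u[zsel] - u0) <= reach)
        if (length(usel) == 0L) next
        rows <- zsel[usel]
        val <- att[rows] * edge_profile(u[rows] - u0, w, sigma) * pz[usel]
        keep <- val > 2e-3
        if (!any(keep)) next
        col <- col + 1L
        ii[[col]] <- rows[keep]; jj[[col]] <- rep.int(col, sum(keep))
        xx[[col]] <- val[keep]
        beam_of[col] <- b; b_u[col] <- u0; b_z[col] <- z0
      }
    }
  }
  if (col == 0L)
    stop("beamlet grid covers no target voxels", call. = FALSE)
  m <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(vox_idx), col))
  structure(list(matrix = m, beam_of_beamlet = beam_of, beamlet_u = b_u,
                 beamlet_z = b_z, beam_angles = angles, config = config,
                 voxel_index = vox_idx, grid = grid),
            class = "dose_influence")
}

#' @exportS3Method base::print
print.dose_influence <- function(x, ...) {
  cat("<dose_influence>", nrow(x$matrix), "voxels x", ncol(x$matrix),
      "beamlets,", x$config$n_beams, "beams\n")
  invisible(x)
}

#' Row indices of a structure within a dose-influence matrix
#'
#' @param dij a \code{dose_influence}.
#' @param mask logical array on the same grid (must lie inside external).
#' @return Integer vector of row indices.
#' @export
structure_rows <- function(dij, mask) {
  which(mask[dij$voxel_index])
}
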