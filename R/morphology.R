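#' Euclidean distance map of a binary mask
#'
#' Exact, anisotropy-aware distance (mm) from every voxel centre to the
#' nearest voxel centre inside \code{mask}, computed with a separable exact
#' squared-distance transform.
#'
#' @param mask logical array with the grid's shape.
#' @param grid a \code{grid_spec}.
#' @return Numeric array of distances in mm (\code{Inf} if \code{mask} is
#'   empty; 0 inside the mask).
#' @export
distance_map <- function(mask, grid) {
  assert_mask(mask, grid)
  d2 <- .edt_sq(as.vector(mask), grid$shape, grid$spacing)
  array(sqrt(d2), grid$shape)
}

#' Isotropic mask expansion (margin dilation)
#'
#' Expands a binary mask by a Euclidean margin: the result contains every
#' voxel whose centre lies within \code{margin_mm} of the centre of some
#' voxel of the input mask. \code{expand_mask(m, g, 0)} is the identity, and
#' the operation is monotone in both the mask and the margin.
#'
#' @param mask logical array.
#' @param grid a \code{grid_spec}.
#' @param margin_mm non-negative expansion margin in mm.
#' @return Logical array of the same shape.
#' @examples
#' g <- grid_spec(c(21, 21, 11), c(2, 2, 2))
#' m <- empty_mask(g); m[11, 11, 6] <- TRUE
#' sum(expand_mask(m, g, 4))  # voxels within 4 mm of the seed centre
#' @export
expand_mask <- function(mask, grid, margin_mm) {
  assert_mask(mask, grid)
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L ||
      !is.finite(margin_mm) || margin_mm < 0)
    stop("`margin_mm` must be a single non-negative number", call. = FALSE)
  if (margin_mm == 0 || !any(mask)) return(mask)
  d2 <- .edt_sq(as.vector(mask), grid$shape, grid$spacing)
  # small relative tolerance so exact-radius voxels are kept despite
  # floating-point roundoff in the squared-distance accumulation
  array(d2 <= margin_mm^2 * (1 + 1e-12) + 1e-9, grid$shape)
}
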