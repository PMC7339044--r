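#' Voxel grid specification
#'
#' Defines the regular 3D voxel lattice on which all masks and dose
#' distributions live. Coordinates are in millimetres; voxel centres are at
#' \code{origin + (i - 1) * spacing} along each axis (1-based indices).
#'
#' @param shape integer vector of length 3, voxels per axis (x, y, z).
#' @param spacing numeric vector of length 3, mm per voxel along each axis.
#' @param origin numeric vector of length 3, mm coordinate of the centre of
#'   voxel (1, 1, 1). Default places the grid centre at the coordinate origin.
#' @return An object of class \code{grid_spec}.
#' @examples
#' g <- grid_spec(c(64, 64, 16), c(2.5, 2.5, 4))
#' dim(voxel_coords(g, axis = 1))
#' @export
grid_spec <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  if (is.null(origin)) origin <- -(shape - 1L) * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @exportS3Method base::print
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", paste(x$shape, collapse = " x "),
      " voxels @ (", paste(format(x$spacing), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

#' Voxel centre coordinates
#'
#' @param grid a \code{grid_spec}.
#' @param axis 1, 2 or 3; if given, returns the 3D array of centre
#'   coordinates along that axis, otherwise an n-voxels x 3 matrix.
#' @return Array or matrix of mm coordinates.
#' @export
voxel_coords <- function(grid, axis = NULL) {
  ax <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
  if (!is.null(axis)) {
    a <- as.integer(axis)
    per <- switch(a,
      array(ax[[1]], grid$shape),
      aperm(array(ax[[2]], grid$shape[c(2, 1, 3)]), c(2, 1, 3)),
      aperm(array(ax[[3]], grid$shape[c(3, 1, 2)]), c(2, 3, 1)))
    return(per)
  }
  cbind(x = as.vector(voxel_coords(grid, 1)),
        y = as.vector(voxel_coords(grid, 2)),
        z = as.vector(voxel_coords(grid, 3)))
}

voxel_volume_mm3 <- function(grid) prod(grid$spacing)

assert_mask <- function(mask, grid, name = "mask") {
  if (!is.logical(mask) || !identical(dim(mask), as.integer(grid$shape)))
    stop(sprintf("`%s` must be a logical array with the grid's shape", name),
         call. = FALSE)
  invisible(TRUE)
}

empty_mask <- function(grid) array(FALSE, grid$shape)
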