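# Derivation of planning structures from the anatomical masks: PTVs with
# isotropic margins, the rectum planning-risk volume (PRV) with its
# overlap-dependent margin, conformality shells around PTV_Low, and the
# entrance-dose band.

#' Build the planning structure set from a phantom
#'
#' Applies the CTV-to-PTV margins, carves the rectum out of PTV_High,
#' builds the conformality shells at fixed distances from the PTV_Low edge
#' and the entrance-dose band just inside the external surface.
#'
#' @param phantom a \code{phantom}.
#' @param margin_high_mm isotropic CTV_High -> PTV_High margin, mm (5-6).
#' @param margin_low_mm isotropic CTV_Low -> PTV_Low margin, mm (8-10).
#' @param shell_distances_mm distances (mm) from the PTV_Low edge at which
#'   conformality shells start.
#' @param shell_band_mm radial thickness of each shell, mm.
#' @param entrance_depth_mm depth of the entrance-dose band inside the
#'   external surface, mm.
#' @param ptv_high_carve_mm margin by which PTV_High is expanded before
#'   subtracting it from PTV_Low for the intermediate-dose constraint
#'   structure (2.5 mm).
#' @return An object of class \code{structure_set}: \code{masks} (derived
#'   plus pass-through anatomy), \code{grid}, \code{margins_used}.
#' @export
build_planning_structures <- function(phantom, margin_high_mm = 5,
                                      margin_low_mm = 9,
                                      shell_distances_mm = c(5, 15, 25, 50),
                                      shell_band_mm = 5,
                                      entrance_depth_mm = 10,
                                      ptv_high_carve_mm = 2.5) {
  stopifnot(inherits(phantom, "phantom"))
  if (margin_high_mm < 5 || margin_high_mm > 6)
    stop("margin_high_mm must be in [5, 6] mm", call. = FALSE)
  if (margin_low_mm < 8 || margin_low_mm > 10)
    stop("margin_low_mm must be in [8, 10] mm", call. = FALSE)
  g <- phantom$grid
  mk <- phantom$masks
  ext <- mk$external

  ptv_high <- expand_mask(mk$CTV_High, g, margin_high_mm) & !mk$rectum & ext
  ptv_low <- expand_mask(mk$CTV_Low, g, margin_low_mm) & ext
  if (!any(ptv_high)) stop("resulting PTV_High is empty", call. = FALSE)
  if (!any(ptv_low)) stop("resulting PTV_Low is empty", call. = FALSE)
  ptv_low_carved <- ptv_low & !expand_mask(ptv_high, g, ptv_high_carve_mm)

  shells <- list()
  for (d in shell_distances_mm) {
    shells[[paste0("Shell", d)]] <-
      expand_mask(ptv_low, g, d + shell_band_mm) &
      !expand_mask(ptv_low, g, d) & ext
  }
  depth_in <- distance_map(!ext, g)
  entrance <- ext & depth_in <= entrance_depth_mm &
    !expand_mask(ptv_low, g, max(shell_distances_mm))

  masks <- c(list(PTV_High = ptv_high, PTV_Low = ptv_low,
                  PTV_Low_minus_expanded_PTV_High = ptv_low_carved,
                  EntranceDose = entrance),
             shells, mk)
  structure(list(masks = masks, grid = g,
                 margins_used = list(high = margin_high_mm,
                                     low = margin_low_mm,
                                     ptv_high_carve = ptv_high_carve_mm,
                                     shell_band = shell_band_mm,
                                     entrance_depth = entrance_depth_mm,
                                     shells = shell_distances_mm)),
            class = "structure_set")
}

#' @exportS3Method base::print
print.structure_set <- function(x, ...) {
  v <- vapply(x$masks, sum, numeric(1))
  cat("<structure_set>\n")
  cat(paste(sprintf("  %-34s %6d vox", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

#' Rectum-PTV_Low overlap
#'
#' Percentage of the rectum volume lying inside PTV_Low (rectum volume is
#' the denominator).
#'
#' @param structset a \code{structure_set}.
#' @return List with \code{overlap_voxels}, \code{overlap_pct} and
#'   \code{denominator_convention}.
#' @export
overlap_percentage <- function(structset) {
  rectum <- structset$masks$rectum
  ptv_low <- structset$masks$PTV_Low
  if (is.null(rectum) || !any(rectum))
    stop("rectum mask is empty", call. = FALSE)
  ov <- sum(rectum & ptv_low)
  list(overlap_voxels = ov, overlap_pct = 100 * ov / sum(rectum),
       denominator_convention = "rectum")
}

#' Overlap-dependent PRV margin selection
#'
#' Maps the rectum-PTV_Low overlap percentage to the PRV expansion margin:
#' 25, 20, 15 or 10 mm for overlaps of < 4, < 6, < 7 or >= 7 percent,
#' respectively. Patients with little overlap get a generous margin (more
#' of the overlap region released from the coverage objective); patients
#' with large overlap get a tight one.
#'
#' @param overlap_pct overlap percentage in [0, 100].
#' @return Margin in mm (25, 20, 15 or 10).
#' @examples
#' select_prv_margin(2) # 25
#' select_prv_margin(5) # 20
#' select_prv_margin(8) # 10
#' @export
select_prv_margin <- function(overlap_pct) {
  if (!is.numeric(overlap_pct) || length(overlap_pct) != 1L ||
      is.na(overlap_pct) || overlap_pct < 0 || overlap_pct > 100)
    stop("`overlap_pct` must be a single value in [0, 100]", call. = FALSE)
  if (overlap_pct < 4) 25
  else if (overlap_pct < 6) 20
  else if (overlap_pct < 7) 15
  else 10
}

#' Add the rectum PRV and the coverage-reduced target to a structure set
#'
#' RectumPRV is the rectum-PTV_Low overlap expanded by the selected
#' margin; PTV_Low minus RectumPRV is the target the reduced-coverage
#' plans must still cover fully.
#'
#' @param structset a \code{structure_set}.
#' @param margin_mm PRV margin in mm (from \code{\link{select_prv_margin}}).
#' @return The augmented \code{structure_set} (adds \code{RectumPRV},
#'   \code{PTV_Low_minus_RectumPRV}, \code{prv_margin_mm},
#'   \code{overlap}).
#' @export
build_rectum_prv <- function(structset, margin_mm) {
  stopifnot(inherits(structset, "structure_set"))
  g <- structset$grid
  ov_mask <- structset$masks$rectum & structset$masks$PTV_Low
  prv <- expand_mask(ov_mask, g, margin_mm)
  structset$masks$RectumPRV <- prv
  structset$masks$PTV_Low_minus_RectumPRV <- structset$masks$PTV_Low & !prv
  structset$prv_margin_mm <- margin_mm
  structset$overlap <- overlap_percentage(structset)
  structset
}
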