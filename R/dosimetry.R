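#' Prescription levels
#'
#' Total prescribed doses for the two dose levels of the simultaneously
#' integrated boost scheme, the number of fractions, and the coverage
#' convention (fraction of the prescription defining the coverage isodose,
#' and the clinically requested covered-volume percentage).
#'
#' @param pd_high total prescribed dose for PTV_High in Gy.
#' @param pd_low total prescribed dose for PTV_Low in Gy.
#' @param n_fractions number of fractions.
#' @param coverage_iso_fraction fraction of the prescription used as the
#'   coverage isodose (default 0.95, i.e. V95).
#' @param coverage_target_pct clinically requested coverage in percent.
#' @return An object of class \code{prescription}.
#' @export
prescription <- function(pd_high = 64.6, pd_low = 57.76, n_fractions = 19L,
                         coverage_iso_fraction = 0.95,
                         coverage_target_pct = 99) {
  if (!(pd_high > pd_low && pd_low > 0))
    stop("need pd_high > pd_low > 0", call. = FALSE)
  if (n_fractions < 1L) stop("n_fractions must be >= 1", call. = FALSE)
  if (!(coverage_iso_fraction > 0 && coverage_iso_fraction <= 1))
    stop("coverage_iso_fraction must be in (0, 1]", call. = FALSE)
  structure(list(pd_high = pd_high, pd_low = pd_low,
                 n_fractions = as.integer(n_fractions),
                 coverage_iso_fraction = coverage_iso_fraction,
                 coverage_target_pct = coverage_target_pct),
            class = "prescription")
}

#' Dose distribution from beamlet weights
#'
#' Applies the linear dose model: total dose = dose-influence matrix times
#' the non-negative beamlet weight vector.
#'
#' @param dij a \code{dose_influence} object.
#' @param w numeric vector of beamlet weights (>= 0), one per beamlet.
#' @return Numeric vector of dose (Gy) over the dose-influence rows (voxels
#'   inside the external contour, in \code{dij$voxel_index} order).
#' @export
dose_from_weights <- function(dij, w) {
  if (length(w) != ncol(dij$matrix))
    stop("weight vector length must equal the number of beamlets",
         call. = FALSE)
  if (any(!is.finite(w)) || any(w < 0))
    stop("beamlet weights must be finite and non-negative", call. = FALSE)
  as.numeric(dij$matrix %*% w)
}

#' Cumulative dose-volume histogram
#'
#' @param dose numeric vector of voxel doses (Gy) for the voxels of a
#'   structure.
#' @param bin_width_gy histogram bin width in Gy (default 0.1).
#' @return A data.frame with \code{dose_gy} (bin edges from 0 past the
#'   maximum dose) and \code{volume_pct} (percent of voxels with dose >=
#'   edge); starts at 100 and is non-increasing, reaching 0 beyond the
#'   maximum.
#' @export
dvh <- function(dose, bin_width_gy = 0.1) {
  if (length(dose) == 0L) stop("empty structure: no voxels", call. = FALSE)
  edges <- seq(0, max(dose) + bin_width_gy, by = bin_width_gy)
  vol <- vapply(edges, function(e) 100 * mean(dose >= e), numeric(1))
  data.frame(dose_gy = edges, volume_pct = vol)
}

#' Coverage of a structure at an isodose
#'
#' Percentage of structure voxels receiving at least
#' \code{iso_fraction * pd} Gy (V95 for the default 0.95).
#'
#' @param dose numeric vector of voxel doses over the structure.
#' @param pd prescription dose in Gy.
#' @param iso_fraction fraction of \code{pd} defining the isodose.
#' @return Coverage in percent.
#' @export
coverage <- function(dose, pd, iso_fraction = 0.95) {
  if (length(dose) == 0L) stop("empty structure: no voxels", call. = FALSE)
  if (!(iso_fraction > 0 && iso_fraction <= 1))
    stop("iso_fraction must be in (0, 1]", call. = FALSE)
  100 * mean(dose >= iso_fraction * pd)
}

#' Mean, maximum and minimum dose of a structure
#'
#' @param dose numeric vector of voxel doses over the structure.
#' @return Named numeric vector \code{c(mean, max, min)} in Gy.
#' @export
mean_max_dose <- function(dose) {
  if (length(dose) == 0L) stop("empty structure: no voxels", call. = FALSE)
  c(mean = mean(dose), max = max(dose), min = min(dose))
}

#' Logarithmic tumour control probability (LTCP)
#'
#' Convex coverage surrogate: the mean over target voxels of
#' \code{exp(-alpha * (d_j - pd))}. Equals 1 for a uniform dose at the
#' prescription, grows exponentially for cold spots, and tends to 0 for
#' overdosage.
#'
#' @param dose numeric vector of voxel doses over the target.
#' @param pd prescription dose in Gy.
#' @param alpha cell-sensitivity parameter (> 0), per Gy.
#' @return LTCP value (> 0).
#' @export
ltcp <- function(dose, pd, alpha) {
  if (length(dose) == 0L) stop("empty target: no voxels", call. = FALSE)
  if (!(alpha > 0)) stop("alpha must be > 0", call. = FALSE)
  mean(exp(-alpha * (dose - pd)))
}

#' Equivalent dose in 2 Gy fractions (EQD2)
#'
#' Linear-quadratic conversion of a total voxel dose delivered in
#' \code{n_fractions} equal fractions into the isoeffective total dose at
#' 2 Gy per fraction:
#' \code{EQD2 = D * (D / n + alpha_beta) / (2 + alpha_beta)}.
#' A voxel already at 2 Gy per fraction is a fixed point.
#'
#' @param dose numeric vector (or array) of total physical doses in Gy.
#' @param n_fractions number of fractions (>= 1).
#' @param alpha_beta tissue alpha/beta ratio in Gy (> 0; 3 Gy is the
#'   conventional late-complication value for rectum).
#' @return EQD2 doses, same shape as \code{dose}.
#' @export
eqd2 <- function(dose, n_fractions, alpha_beta = 3) {
  if (!(alpha_beta > 0)) stop("alpha_beta must be > 0", call. = FALSE)
  if (n_fractions < 1) stop("n_fractions must be >= 1", call. = FALSE)
  dose * (dose / n_fractions + alpha_beta) / (2 + alpha_beta)
}

#' Generalised equivalent uniform dose, gEUD(k)
#'
#' The k-power mean of the voxel doses,
#' \code{((1/m) * sum(d_j^k))^(1/k)}; k = 1 gives the mean dose, large k
#' approaches the maximum. Convex in dose for k >= 1.
#'
#' @param dose numeric vector of non-negative voxel doses over a structure.
#' @param k volume-effect parameter (>= 1); 7.7 for rectum here.
#' @return gEUD in Gy.
#' @export
geud <- function(dose, k) {
  if (length(dose) == 0L) stop("empty structure: no voxels", call. = FALSE)
  if (!(k >= 1)) stop("k must be >= 1", call. = FALSE)
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  mx <- max(dose)
  if (mx == 0) return(0)
  # factor out the maximum for numerical stability at large k
  mx * mean((dose / mx)^k)^(1 / k)
}

#' Rectum gEUD of the EQD2-converted dose
#'
#' The dosimetric predictor E of the GI toxicity model: voxel doses are
#' first converted to EQD2, then summarised with gEUD(k = 7.7).
#'
#' @param dose numeric vector of total physical rectum-voxel doses in Gy.
#' @param n_fractions number of fractions.
#' @param alpha_beta rectum alpha/beta in Gy (default 3).
#' @param k gEUD volume-effect parameter (default 7.7).
#' @return gEUD of the EQD2 dose, in Gy.
#' @export
rectum_geud_eqd2 <- function(dose, n_fractions, alpha_beta = 3, k = 7.7) {
  geud(eqd2(dose, n_fractions, alpha_beta), k)
}
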