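#' NTCP model coefficients for grade >= 2 late GI toxicity
#'
#' Frozen multivariate logistic-regression coefficients of the toxicity
#' model used throughout: linear predictor
#' \code{S = intercept + beta_b * B + beta_d * D + beta_t * T + beta_e * E}
#' with B = baseline GI toxicity (0/1), D = diabetes (0/1), T = high-risk
#' treatment group (0/1) and E = rectum gEUD of the EQD2 dose (Gy);
#' NTCP = 1 / (1 + exp(-S)). All coefficients are risk-increasing.
#'
#' @param intercept,beta_b,beta_d,beta_t,beta_e model coefficients;
#'   defaults are the published fit and should only be overridden with a
#'   documented provenance.
#' @return An object of class \code{ntcp_coefficients}.
#' @export
ntcp_coefficients <- function(intercept = -6.362, beta_b = 2.083,
                              beta_d = 0.608, beta_t = 0.406,
                              beta_e = 0.084) {
  structure(list(intercept = intercept, beta_b = beta_b, beta_d = beta_d,
                 beta_t = beta_t, beta_e = beta_e),
            class = "ntcp_coefficients")
}

#' Normal tissue complication probability (logistic model)
#'
#' @param e rectum gEUD of the EQD2 dose in Gy (>= 0); vectorised.
#' @param baseline_gi 0/1, pre-treatment GI symptoms.
#' @param diabetes 0/1, diabetes as co-morbidity.
#' @param high_risk 0/1, high-risk treatment group.
#' @param coefficients an \code{ntcp_coefficients} object.
#' @return Probability (0, 1) of grade >= 2 late GI toxicity.
#' @examples
#' ntcp(0)               # ~0.0017: all predictors at zero
#' ntcp(57, diabetes = 1) # diabetes shifts the logit by +0.608
#' @export
ntcp <- function(e, baseline_gi = 0, diabetes = 0, high_risk = 0,
                 coefficients = ntcp_coefficients()) {
  for (nm in c("baseline_gi", "diabetes", "high_risk")) {
    v <- get(nm)
    if (!all(v %in% c(0, 1)))
      stop(sprintf("`%s` must be 0 or 1", nm), call. = FALSE)
  }
  if (any(e < 0)) stop("`e` must be >= 0 Gy", call. = FALSE)
  s <- coefficients$intercept + coefficients$beta_b * baseline_gi +
    coefficients$beta_d * diabetes + coefficients$beta_t * high_risk +
    coefficients$beta_e * e
  stats::plogis(s)
}

#' NTCP with and without diabetes for one dose distribution
#'
#' Evaluates the toxicity model twice from the same rectum dose, toggling
#' only the diabetes flag, for the all-diabetic / none-diabetic cohort
#' analyses.
#'
#' @param rectum_dose numeric vector of total physical rectum-voxel doses
#'   (Gy).
#' @param n_fractions number of fractions.
#' @param baseline_gi,high_risk 0/1 non-dosimetric predictors held fixed.
#' @param alpha_beta rectum alpha/beta in Gy.
#' @param coefficients an \code{ntcp_coefficients} object.
#' @return List with \code{e_gy} (shared dosimetric predictor),
#'   \code{with_diabetes} and \code{without_diabetes} probabilities.
#' @export
ntcp_pair <- function(rectum_dose, n_fractions, baseline_gi = 0,
                      high_risk = 0, alpha_beta = 3,
                      coefficients = ntcp_coefficients()) {
  e <- rectum_geud_eqd2(rectum_dose, n_fractions, alpha_beta)
  list(e_gy = e,
       with_diabetes = ntcp(e, baseline_gi, 1, high_risk, coefficients),
       without_diabetes = ntcp(e, baseline_gi, 0, high_risk, coefficients))
}
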