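# Per-patient seven-plan workflow: one clinical plan with full (>= 99%)
# PTV_Low coverage plus six plans with progressively relaxed coverage
# demands, evaluated with the GI toxicity model, and the cohort-level
# analyses built on top (interpolated NTCP-vs-coverage curves, diabetes
# compensation, overlap regression).

#' Default priority-3 LTCP goal ladder for the six reduced-coverage plans
#'
#' Patient-independent X values used as the priority-3 goal of the six
#' reduced plans; each value allows the rectum-sparing objective to push
#' the PTV_Low LTCP up to X, trading coverage for rectum dose. The ladder
#' was calibrated once on the default synthetic cohort so realized PTV_Low
#' coverages span roughly 98 down to 90 percent, then frozen.
#'
#' @return Increasing numeric vector of length 6.
#' @export
default_x_schedule <- function() c(2, 10, 60, 400, 3e3, 3e4)

#' Run the seven-plan coverage-toxicity workflow for one patient
#'
#' Derives planning structures, measures the rectum-PTV_Low overlap,
#' selects the PRV margin, solves the clinical plan, then solves the six
#' reduced-coverage plans (bladder mean dose capped at the clinical value)
#' and evaluates coverage, rectum gEUD of the EQD2 dose, and NTCP with and
#' without diabetes for every plan.
#'
#' @param phantom a \code{phantom}.
#' @param dij optional precomputed \code{dose_influence} (computed with
#'   default \code{beam_config()} otherwise).
#' @param x_schedule increasing LTCP goal values for the reduced plans.
#' @param baseline_gi,high_risk 0/1 non-dosimetric predictors of the
#'   toxicity model (the diabetes flag is toggled internally).
#' @param rx a \code{\link{prescription}}.
#' @param alpha_beta rectum alpha/beta (Gy) for the EQD2 conversion.
#' @param opts \code{\link{solver_opts}}.
#' @param config \code{\link{beam_config}} used when \code{dij} is NULL.
#' @param coverage_levels integer coverage levels (percent) at which the
#'   NTCP curve is interpolated.
#' @return A \code{patient_tradeoff}: plans, per-plan \code{metrics}
#'   data.frame, \code{overlap_pct}, \code{prv_margin_mm}, and the
#'   interpolated \code{curve} (NTCP with/without diabetes per level; NA
#'   where the achieved coverage range does not reach the level).
#' @export
run_patient <- function(phantom, dij = NULL,
                        x_schedule = default_x_schedule(),
                        baseline_gi = 0, high_risk = 0,
                        rx = prescription(), alpha_beta = 3,
                        opts = solver_opts(), config = beam_config(),
                        coverage_levels = 99:90) {
  stopifnot(inherits(phantom, "phantom"))
  if (is.unsorted(x_schedule, strictly = TRUE))
    stop("x_schedule must be strictly increasing", call. = FALSE)
  if (is.null(dij)) dij <- compute_dose_influence(phantom, config)

  ss <- build_planning_structures(phantom)
  ov <- overlap_percentage(ss)
  prv_mm <- select_prv_margin(ov$overlap_pct)
  ss <- build_rectum_prv(ss, prv_mm)

  wl_clin <- build_clinical_wishlist(rx, slack_delta = opts$slack_delta)
  clinical <- lexicographic_solve(wl_clin, dij, ss, opts)
  if (!clinical$feasible)
    stop(structure(class = c("clinical_infeasible", "error", "condition"),
                   list(message = "clinical plan infeasible",
                        call = sys.call(),
                        report = clinical$infeasibility)))

  metric_row <- function(plan, label, x = NA_real_) {
    rows <- function(nm) structure_rows(dij, ss$masks[[nm]])
    rd <- plan$dose[rows("rectum")]
    np <- ntcp_pair(rd, rx$n_fractions, baseline_gi, high_risk, alpha_beta)
    data.frame(
      plan = label, x_value = x, feasible = plan$feasible,
      ptv_low_coverage = coverage(plan$dose[rows("PTV_Low")], rx$pd_low,
                                  rx$coverage_iso_fraction),
      ptv_high_coverage = coverage(plan$dose[rows("PTV_High")], rx$pd_high,
                                   rx$coverage_iso_fraction),
      ctv_low_coverage = coverage(plan$dose[rows("CTV_Low")], rx$pd_low,
                                  rx$coverage_iso_fraction),
      ctv_high_coverage = coverage(plan$dose[rows("CTV_High")], rx$pd_high,
                                   rx$coverage_iso_fraction),
      rectum_geud = geud(rd, 7.7),
      rectum_geud_eqd2 = np$e_gy,
      rectum_mean = mean(rd),
      bladder_mean = mean(plan$dose[rows("bladder")]),
      ntcp_with_diabetes = np$with_diabetes,
      ntcp_without_diabetes = np$without_diabetes,
      stringsAsFactors = FALSE)
  }

  metrics <- metric_row(clinical, "clinical")
  bladder_clin <- metrics$bladder_mean[1]

  plans <- list(clinical = clinical)
  for (i in seq_along(x_schedule)) {
    x <- x_schedule[i]
    # the bladder cap carries the solver slack so the clinical plan itself
    # remains strictly feasible as a warm start
    wl_red <- build_reduced_wishlist(rx, x_value = x,
                                     prv_margin_mm = prv_mm,
                                     bladder_dmean_clinical =
                                       bladder_clin * (1 + opts$slack_delta),
                                     slack_delta = opts$slack_delta)
    plan <- lexicographic_solve(wl_red, dij, ss, opts,
                                w_start = clinical$weights)
    lab <- sprintf("reduced_%d", i)
    plans[[lab]] <- plan
    metrics <- rbind(metrics, metric_row(plan, lab, x))
  }

  curve <- tradeoff_curve(metrics, coverage_levels)
  structure(list(id = phantom$seed, plans = plans, metrics = metrics,
                 overlap_pct = ov$overlap_pct, prv_margin_mm = prv_mm,
                 curve = curve, structures = ss, prescription = rx),
            class = "patient_tradeoff")
}

#' @exportS3Method base::print
print.patient_tradeoff <- function(x, ...) {
  cat("<patient_tradeoff> phantom seed", x$id, "- overlap",
      sprintf("%.2f%%", x$overlap_pct), "- PRV margin", x$prv_margin_mm,
      "mm\n")
  print(x$metrics[, c("plan", "ptv_low_coverage", "rectum_geud_eqd2",
                      "ntcp_with_diabetes", "ntcp_without_diabetes")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

# interpolate both NTCP curves at the integer coverage levels, using only
# feasible plans and enforcing the monotone-ladder policy
tradeoff_curve <- function(metrics, levels) {
  m <- metrics[metrics$feasible, , drop = FALSE]
  keep <- monotone_ladder_filter(m$ptv_low_coverage, m$ntcp_without_diabetes)
  m <- m[keep, , drop = FALSE]
  # a patient whose plans all coincide at full coverage (empty PRV: no
  # voxel is ever released) has no trade-off: the NTCP at any requested
  # level equals the clinical value, i.e. the curve is flat
  if (diff(range(m$ptv_low_coverage)) < 0.5 &&
      min(m$ptv_low_coverage) >= 99)
    return(data.frame(coverage = levels,
                      ntcp_with = m$ntcp_with_diabetes[1],
                      ntcp_without = m$ntcp_without_diabetes[1]))
  if (length(unique(m$ptv_low_coverage)) < 2L)
    return(data.frame(coverage = levels, ntcp_with = NA_real_,
                      ntcp_without = NA_real_))
  data.frame(
    coverage = levels,
    ntcp_with = interpolate_ntcp(m$ptv_low_coverage,
                                 m$ntcp_with_diabetes, levels),
    ntcp_without = interpolate_ntcp(m$ptv_low_coverage,
                                    m$ntcp_without_diabetes, levels))
}

# drop ladder rungs whose NTCP increases while coverage decreases (beyond
# a small tolerance); such rungs are solver noise, not trade-off points
monotone_ladder_filter <- function(cov, ntcp, tol = 1e-6) {
  ord <- order(cov, decreasing = TRUE)
  keep_ord <- rep(TRUE, length(ord))
  best <- Inf
  for (i in seq_along(ord)) {
    v <- ntcp[ord[i]]
    if (v <= best + tol) best <- min(best, v)
    else {
      keep_ord[i] <- FALSE
      warning("dropping non-monotone coverage-ladder rung", call. = FALSE)
    }
  }
  keep <- rep(TRUE, length(cov))
  keep[ord] <- keep_ord
  keep
}

#' Piecewise-linear interpolation of NTCP against coverage
#'
#' Node values are reproduced exactly; queries outside the achieved
#' coverage range return NA (no extrapolation).
#'
#' @param coverages achieved coverage values (percent); must contain at
#'   least 2 distinct values.
#' @param ntcps NTCP values at those coverages.
#' @param query_levels coverage levels to interpolate at.
#' @return Numeric vector of interpolated NTCPs (NA outside the range).
#' @export
interpolate_ntcp <- function(coverages, ntcps, query_levels) {
  stopifnot(length(coverages) == length(ntcps))
  dup <- duplicated(coverages)
  coverages <- coverages[!dup]; ntcps <- ntcps[!dup]
  if (length(coverages) < 2L)
    stop("need at least 2 distinct coverage points to interpolate",
         call. = FALSE)
  stats::approx(coverages, ntcps, xout = query_levels, method = "linear",
                rule = 1)$y
}

#' Coverage reduction compensating for diabetes
#'
#' Finds the largest coverage level at which the with-diabetes NTCP is at
#' or below the no-diabetes NTCP of the clinical (99 percent) coverage
#' level.
#'
#' @param patient a \code{patient_tradeoff}.
#' @return List with \code{compensating_coverage} (percent, or NA when no
#'   achieved level compensates) and \code{residual_gap} (with-diabetes
#'   NTCP minus the no-diabetes clinical NTCP at the lowest achieved
#'   level; <= 0 when compensation succeeds).
#' @export
diabetes_compensation <- function(patient) {
  cv <- patient$curve
  if (is.null(cv))
    stop("patient has no interpolated trade-off curve", call. = FALSE)
  # a computed curve with no achieved levels (e.g. zero overlap, where all
  # plans coincide) compensates nothing and has no measurable gap
  if (all(is.na(cv$ntcp_with)))
    return(list(compensating_coverage = NA_real_,
                residual_gap = NA_real_))
  ref <- cv$ntcp_without[cv$coverage == max(cv$coverage)]
  ok <- which(!is.na(cv$ntcp_with) & cv$ntcp_with <= ref)
  achieved <- which(!is.na(cv$ntcp_with))
  lowest <- achieved[length(achieved)]
  if (length(ok))
    list(compensating_coverage = cv$coverage[ok[1]],
         residual_gap = cv$ntcp_with[ok[1]] - ref)
  else
    list(compensating_coverage = NA_real_,
         residual_gap = cv$ntcp_with[lowest] - ref)
}

#' Cohort-level summary of the coverage-toxicity trade-off
#'
#' Per-level mean and sample SD of NTCP (with and without diabetes),
#' per-level NTCP-reduction ranges, and ordinary-least-squares regressions
#' of the NTCP reduction against the rectum-PTV_Low overlap percentage at
#' the 95 and 90 percent coverage levels.
#'
#' @param patients list of \code{patient_tradeoff} objects (>= 2).
#' @param regression_levels coverage levels at which the overlap
#'   regression is fitted.
#' @return A \code{cohort_summary}: \code{levels} data.frame (level, mean
#'   and SD per diabetes setting, reduction range), \code{regressions}
#'   data.frame (level, slope, intercept, r_squared, n), and
#'   \code{patients} data.frame with per-patient overlap and reductions.
#' @export
cohort_summary <- function(patients, regression_levels = c(95, 90)) {
  stopifnot(length(patients) >= 2L)
  for (p in patients) stopifnot(inherits(p, "patient_tradeoff"))
  levels <- patients[[1]]$curve$coverage
  ref_level <- max(levels)

  get_curve <- function(p, col) p$curve[[col]][match(levels, p$curve$coverage)]
  with_m <- vapply(patients, get_curve, numeric(length(levels)), "ntcp_with")
  wo_m <- vapply(patients, get_curve, numeric(length(levels)), "ntcp_without")
  red_with <- with_m[levels == ref_level, ] -
    t(with_m)  # per-patient reduction vs clinical level, columns = level
  red_wo <- wo_m[levels == ref_level, ] - t(wo_m)

  lv <- data.frame(
    coverage = levels,
    ntcp_with_mean = rowMeans(with_m, na.rm = TRUE),
    ntcp_with_sd = apply(with_m, 1, stats::sd, na.rm = TRUE),
    ntcp_without_mean = rowMeans(wo_m, na.rm = TRUE),
    ntcp_without_sd = apply(wo_m, 1, stats::sd, na.rm = TRUE),
    reduction_with_min = apply(red_with, 2, min, na.rm = TRUE),
    reduction_with_mean = colMeans(red_with, na.rm = TRUE),
    reduction_with_max = apply(red_with, 2, max, na.rm = TRUE),
    reduction_without_mean = colMeans(red_wo, na.rm = TRUE))

  overlap <- vapply(patients, `[[`, numeric(1), "overlap_pct")
  degenerate <- stats::sd(overlap) < 1e-9
  regs <- list()
  for (lev in regression_levels) {
    y <- red_with[, match(lev, levels)]
    ok <- !is.na(y)
    if (degenerate || sum(ok) < 2L ||
        length(unique(overlap[ok])) < 2L) {
      regs[[length(regs) + 1L]] <-
        data.frame(coverage = lev, slope = NA_real_, intercept = NA_real_,
                   r_squared = NA_real_, n = sum(ok), degenerate = TRUE)
      next
    }
    fit <- stats::lm(y[ok] ~ overlap[ok])
    regs[[length(regs) + 1L]] <-
      data.frame(coverage = lev, slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared, n = sum(ok),
                 degenerate = FALSE)
  }

  pts <- data.frame(
    id = vapply(patients, `[[`, numeric(1), "id"),
    overlap_pct = overlap,
    prv_margin_mm = vapply(patients, `[[`, numeric(1), "prv_margin_mm"),
    reduction_with_95 = red_with[, match(95, levels)],
    reduction_with_90 = red_with[, match(90, levels)],
    compensating_coverage = vapply(patients, function(p)
      tryCatch(diabetes_compensation(p)$compensating_coverage,
               error = function(e) NA_real_), numeric(1)))

  structure(list(levels = lv, regressions = do.call(rbind, regs),
                 patients = pts, reference_level = ref_level),
            class = "cohort_summary")
}

#' @exportS3Method base::print
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", nrow(x$patients), "patients\n")
  print(x$levels, digits = 3, row.names = FALSE)
  cat("reduction ~ overlap regressions:\n")
  print(x$regressions, digits = 3, row.names = FALSE)
  invisible(x)
}
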