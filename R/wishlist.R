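# Declarative wish-list: hard constraints plus prioritized goal-valued
# objectives, the protocol driving automated lexicographic plan
# generation. Dose limits and goals may be absolute Gy or percentages of a
# named prescription level, resolved before solving.

#' A dose value expressed as a percentage of a prescription level
#'
#' @param value percentage (e.g. 105 for 105 percent).
#' @param of \code{"PD_High"} or \code{"PD_Low"}.
#' @return A tagged list understood by \code{\link{resolve_limits}}.
#' @export
pct_of <- function(value, of) {
  of <- match.arg(of, c("PD_High", "PD_Low"))
  structure(list(value = value, of = of), class = "pct_of")
}

resolve_dose_value <- function(v, rx, what = "limit") {
  if (inherits(v, "pct_of") || (is.list(v) && !is.null(v$of))) {
    pd <- switch(v$of, PD_High = rx$pd_high, PD_Low = rx$pd_low,
                 stop(sprintf("unknown prescription reference '%s' in %s",
                              v$of, what), call. = FALSE))
    return(v$value / 100 * pd)
  }
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop(sprintf("%s must be a number or pct_of()", what), call. = FALSE)
  v
}

#' Hard planning constraint
#'
#' @param structure structure name the constraint applies to.
#' @param kind \code{"max_dose"}, \code{"min_dose"} or \code{"mean_dose"}.
#' @param limit dose limit: Gy, or \code{\link{pct_of}} a prescription
#'   level. \code{max_dose}/\code{mean_dose} are upper bounds,
#'   \code{min_dose} a lower bound.
#' @return A \code{wl_constraint}.
#' @export
hard_constraint <- function(structure, kind, limit) {
  kind <- match.arg(kind, c("max_dose", "min_dose", "mean_dose"))
  structure(list(structure = structure, kind = kind, limit = limit),
            class = "wl_constraint")
}

#' Prioritized planning objective
#'
#' @param priority positive integer; equal priorities are optimized
#'   jointly.
#' @param structure structure name.
#' @param kind \code{"ltcp"}, \code{"geud"}, \code{"mean_dose"},
#'   \code{"max_dose"} or \code{"min_dose"}.
#' @param goal goal value: unitless for LTCP, Gy (or \code{\link{pct_of}})
#'   for dose-type objectives. Minimization may stop once the goal is met.
#' @param sufficient sufficient value (defaults to the goal); the bound
#'   imposed after optimization is never tighter than this, leaving room
#'   for lower priorities.
#' @param pd,alpha LTCP parameters (prescription dose, cell sensitivity).
#' @param k gEUD volume-effect parameter.
#' @param enabled logical; disabled objectives are skipped but kept in the
#'   list.
#' @return A \code{wl_objective}.
#' @export
planning_objective <- function(priority, structure, kind, goal,
                               sufficient = goal, pd = NULL, alpha = NULL,
                               k = NULL, enabled = TRUE) {
  kind <- match.arg(kind, c("ltcp", "geud", "mean_dose", "max_dose",
                            "min_dose"))
  if (kind == "ltcp" && (is.null(pd) || is.null(alpha)))
    stop("ltcp objective needs `pd` and `alpha`", call. = FALSE)
  if (kind == "geud" && is.null(k))
    stop("geud objective needs `k`", call. = FALSE)
  if (priority < 1) stop("priority must be >= 1", call. = FALSE)
  structure(list(priority = as.integer(priority), structure = structure,
                 kind = kind, goal = goal, sufficient = sufficient,
                 pd = pd, alpha = alpha, k = k, enabled = isTRUE(enabled)),
            class = "wl_objective")
}

#' Assemble a wish-list
#'
#' @param prescription a \code{\link{prescription}}.
#' @param constraints list of \code{\link{hard_constraint}}s.
#' @param objectives list of \code{\link{planning_objective}}s; sorted by
#'   priority on assembly.
#' @param slack_delta relative slack applied when an optimized objective is
#'   converted into a constraint (default 1e-3); exact equality would make
#'   lower priorities numerically infeasible.
#' @param name label for traces and manifests.
#' @return An object of class \code{wishlist}.
#' @export
wishlist <- function(prescription, constraints, objectives,
                     slack_delta = 1e-3, name = "wishlist") {
  stopifnot(inherits(prescription, "prescription"))
  if (length(constraints) + length(objectives) == 0L)
    stop("a wish-list needs at least one constraint or objective",
         call. = FALSE)
  for (cc in constraints) stopifnot(inherits(cc, "wl_constraint"))
  for (oo in objectives) stopifnot(inherits(oo, "wl_objective"))
  if (slack_delta < 0) stop("slack_delta must be >= 0", call. = FALSE)
  ord <- order(vapply(objectives, `[[`, integer(1), "priority"))
  structure(list(prescription = prescription, constraints = constraints,
                 objectives = objectives[ord], slack_delta = slack_delta,
                 name = name, resolved = FALSE),
            class = "wishlist")
}

#' @exportS3Method base::print
print.wishlist <- function(x, ...) {
  cat("<wishlist>", x$name, "-", length(x$constraints), "constraints,",
      length(x$objectives), "objectives\n")
  invisible(x)
}

#' Resolve all percentage limits and goals to absolute Gy
#'
#' @param wl a \code{wishlist}.
#' @param prescription optional replacement \code{\link{prescription}};
#'   defaults to the wish-list's own.
#' @return The wish-list with \code{limit_gy}, \code{goal_val},
#'   \code{sufficient_val} and \code{pd_gy} fields filled in and
#'   \code{resolved = TRUE}.
#' @export
resolve_limits <- function(wl, prescription = NULL) {
  stopifnot(inherits(wl, "wishlist"))
  rx <- if (is.null(prescription)) wl$prescription else prescription
  wl$constraints <- lapply(wl$constraints, function(cc) {
    cc$limit_gy <- resolve_dose_value(cc$limit, rx,
                                      paste0("limit (", cc$structure, ")"))
    cc
  })
  wl$objectives <- lapply(wl$objectives, function(oo) {
    if (oo$kind %in% c("mean_dose", "max_dose", "min_dose")) {
      oo$goal_val <- resolve_dose_value(oo$goal, rx, "goal")
      oo$sufficient_val <- resolve_dose_value(oo$sufficient, rx,
                                              "sufficient")
    } else {
      oo$goal_val <- oo$goal
      oo$sufficient_val <- oo$sufficient
    }
    if (oo$kind == "ltcp")
      oo$pd_gy <- resolve_dose_value(oo$pd, rx, "ltcp pd")
    oo
  })
  wl$prescription <- rx
  wl$resolved <- TRUE
  wl
}

#' Evaluate one wish-list cost function on a dose distribution
#'
#' @param spec a \code{wl_constraint} or \code{wl_objective} (resolved).
#' @param dose numeric dose vector over the dose-influence rows.
#' @param structures a \code{structure_set}.
#' @param voxel_index row-to-grid-voxel mapping (from the
#'   \code{dose_influence}).
#' @return The cost-function value (Gy for dose functions, unitless for
#'   LTCP).
#' @export
evaluate_cost <- function(spec, dose, structures, voxel_index) {
  mask <- structures$masks[[spec$structure]]
  if (is.null(mask))
    stop(sprintf("unknown structure '%s'", spec$structure), call. = FALSE)
  sd <- dose[which(mask[voxel_index])]
  if (length(sd) == 0L)
    stop(sprintf("structure '%s' has no voxels", spec$structure),
         call. = FALSE)
  switch(spec$kind,
         max_dose = max(sd),
         min_dose = min(sd),
         mean_dose = mean(sd),
         ltcp = ltcp(sd, spec$pd_gy, spec$alpha),
         geud = geud(sd, spec$k),
         stop(sprintf("unknown cost-function kind '%s'", spec$kind),
              call. = FALSE))
}

table1_constraints <- function() {
  list(
    hard_constraint("PTV_High", "max_dose", pct_of(105, "PD_High")),
    hard_constraint("PTV_High", "mean_dose", pct_of(100.5, "PD_High")),
    hard_constraint("PTV_Low_minus_expanded_PTV_High", "max_dose",
                    pct_of(95, "PD_High")),
    hard_constraint("Shell50", "max_dose", pct_of(50, "PD_High")),
    hard_constraint("rectum", "max_dose", pct_of(102, "PD_High")),
    hard_constraint("anus", "max_dose", pct_of(102, "PD_High")),
    hard_constraint("external", "max_dose", pct_of(105, "PD_High")),
    hard_constraint("CTV_High", "min_dose", pct_of(95, "PD_High")),
    hard_constraint("CTV_Low", "min_dose", pct_of(95, "PD_Low")))
}

table1_objectives <- function(x_value, priority2_enabled,
                              include_bladder_objective = TRUE) {
  obj <- list(
    planning_objective(1, "PTV_High", "ltcp", goal = 0.8,
                       pd = pct_of(99.5, "PD_High"), alpha = 0.8),
    planning_objective(2, "PTV_Low_minus_RectumPRV", "ltcp", goal = 0.4,
                       pd = pct_of(100, "PD_Low"), alpha = 1.4,
                       enabled = priority2_enabled),
    planning_objective(3, "PTV_Low", "ltcp", goal = x_value,
                       pd = pct_of(100, "PD_Low"), alpha = 1.4),
    planning_objective(4, "rectum", "geud", goal = 0, k = 7.7),
    planning_objective(5, "EntranceDose", "max_dose",
                       goal = pct_of(20, "PD_Low")),
    planning_objective(5, "Shell5", "max_dose",
                       goal = pct_of(80, "PD_Low")),
    planning_objective(6, "rectum", "mean_dose", goal = 5),
    planning_objective(7, "anus", "mean_dose", goal = 5),
    planning_objective(8, "Shell15", "max_dose",
                       goal = pct_of(50, "PD_Low")),
    planning_objective(8, "Shell25", "max_dose",
                       goal = pct_of(30, "PD_Low")),
    planning_objective(10, "hip_left", "max_dose", goal = 40),
    planning_objective(10, "hip_right", "max_dose", goal = 40))
  if (include_bladder_objective)
    obj <- append(obj, list(planning_objective(9, "bladder", "mean_dose",
                                               goal = 5)), after = 10)
  obj
}

#' Build the clinical-plan wish-list
#'
#' The full-coverage configuration: the priority-2 objective (on PTV_Low
#' minus RectumPRV) is present but disabled, the priority-3 LTCP on the
#' entire PTV_Low (including the rectum overlap) uses goal X = 0.4 to
#' secure > 99 percent coverage, and the bladder mean-dose objective at
#' priority 9 is active.
#'
#' @param prescription a \code{\link{prescription}}.
#' @param slack_delta objective-to-constraint conversion slack.
#' @return A \code{wishlist}.
#' @export
build_clinical_wishlist <- function(prescription = prioplan::prescription(),
                                    slack_delta = 1e-3) {
  wishlist(prescription, table1_constraints(),
           table1_objectives(x_value = 0.4, priority2_enabled = FALSE,
                             include_bladder_objective = TRUE),
           slack_delta = slack_delta, name = "clinical")
}

#' Build a reduced-coverage wish-list
#'
#' The coverage-reduction configuration: priority 2 covers PTV_Low minus
#' RectumPRV with goal 0.4 (full coverage outside the PRV), priority 3
#' recovers coverage of the entire PTV_Low only up to the plan-specific
#' goal \code{x_value}, the bladder mean-dose objective is removed and
#' replaced by a hard bladder mean-dose constraint at the patient-specific
#' clinical-plan value, so rectum sparing cannot push dose into the
#' bladder.
#'
#' @param prescription a \code{\link{prescription}}.
#' @param x_value priority-3 LTCP goal; larger values demand less PTV_Low
#'   coverage recovery.
#' @param prv_margin_mm PRV margin used for this patient (metadata;
#'   the PRV geometry itself lives in the structure set).
#' @param bladder_dmean_clinical bladder mean dose of the solved clinical
#'   plan, Gy.
#' @param slack_delta objective-to-constraint conversion slack.
#' @return A \code{wishlist}.
#' @export
build_reduced_wishlist <- function(prescription = prioplan::prescription(),
                                   x_value, prv_margin_mm = NA,
                                   bladder_dmean_clinical,
                                   slack_delta = 1e-3) {
  if (missing(bladder_dmean_clinical) || !is.finite(bladder_dmean_clinical))
    stop("bladder_dmean_clinical (from a solved clinical plan) is required",
         call. = FALSE)
  cons <- c(table1_constraints(),
            list(hard_constraint("bladder", "mean_dose",
                                 bladder_dmean_clinical)))
  wl <- wishlist(prescription, cons,
                 table1_objectives(x_value = x_value,
                                   priority2_enabled = TRUE,
                                   include_bladder_objective = FALSE),
                 slack_delta = slack_delta,
                 name = sprintf("reduced_x%g", x_value))
  wl$prv_margin_mm <- prv_margin_mm
  wl
}
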