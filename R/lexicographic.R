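# Sequential priority-wise optimization of a wish-list: each enabled
# objective (group of equal-priority objectives) is minimized subject to
# all hard constraints and all bounds accumulated from higher priorities;
# its attained value is then frozen as a new constraint (with a small
# relative slack, floored at the sufficient value) before moving on.

VIOL_TOL <- 1e-6  # normalized residual above which a constraint counts as violated

new_vox_term <- function(dij, rows_full, type, b, label, opts,
                         act_rows = NULL) {
  lazy <- length(rows_full) > opts$lazy_cap
  rows <- if (lazy && !is.null(act_rows)) act_rows else rows_full
  list(type = type, A = dij$matrix[rows, , drop = FALSE], b = b,
       scale = max(1, abs(b)), label = label, lazy = lazy,
       rows_full = rows_full, rows_act = rows)
}

activate_rows <- function(dij, rows_full, type, b, w, opts) {
  d <- as.numeric(dij$matrix[rows_full, , drop = FALSE] %*% w)
  sel <- if (type == "vox_upper") d >= opts$activation_frac * b
         else d <= b / opts$activation_frac
  if (sum(sel) < 50) {
    o <- if (type == "vox_upper") order(d, decreasing = TRUE) else order(d)
    sel[o[seq_len(min(50, length(d)))]] <- TRUE
  }
  rows_full[sel]
}

refresh_lazy_term <- function(term, dij, w, opts) {
  if (!term$lazy) return(term)
  act <- activate_rows(dij, term$rows_full, term$type, term$b, w, opts)
  act <- sort(unique(c(act, term$rows_act)))
  term$rows_act <- act
  term$A <- dij$matrix[act, , drop = FALSE]
  term
}

lazy_violations <- function(term, dij, w) {
  if (!term$lazy) return(integer(0))
  rest <- setdiff(term$rows_full, term$rows_act)
  if (length(rest) == 0L) return(integer(0))
  d <- as.numeric(dij$matrix[rest, , drop = FALSE] %*% w)
  g <- if (term$type == "vox_upper") (d - term$b) / term$scale
       else (term$b - d) / term$scale
  bad <- which(g > -VIOL_TOL)
  if (length(bad) > 2000L) bad <- bad[order(g[bad], decreasing = TRUE)[1:2000]]
  rest[bad]
}

hard_constraint_terms <- function(wl, dij, structures, w_ref, opts) {
  terms <- list()
  notes <- character(0)
  for (cc in wl$constraints) {
    mask <- structures$masks[[cc$structure]]
    if (is.null(mask))
      stop(sprintf("constraint references unknown structure '%s'",
                   cc$structure), call. = FALSE)
    rows <- structure_rows(dij, mask)
    label <- sprintf("%s %s < %.4g Gy", cc$structure, cc$kind, cc$limit_gy)
    if (length(rows) == 0L) {
      notes <- c(notes, sprintf("constraint on empty structure '%s' skipped",
                                cc$structure))
      next
    }
    if (cc$kind == "mean_dose") {
      terms[[length(terms) + 1L]] <-
        list(type = "mean_upper",
             a = Matrix::colMeans(dij$matrix[rows, , drop = FALSE]),
             A = NULL, b = cc$limit_gy, scale = max(1, abs(cc$limit_gy)),
             label = label, lazy = FALSE)
    } else {
      type <- if (cc$kind == "max_dose") "vox_upper" else "vox_lower"
      act <- NULL
      if (length(rows) > opts$lazy_cap)
        act <- activate_rows(dij, rows, type, cc$limit_gy, w_ref, opts)
      terms[[length(terms) + 1L]] <-
        new_vox_term(dij, rows, type, cc$limit_gy, label, opts, act)
    }
  }
  list(terms = terms, notes = notes)
}

objective_component <- function(oo, dij, structures) {
  rows <- structure_rows(dij, structures$masks[[oo$structure]])
  if (length(rows) == 0L) return(NULL)
  A <- dij$matrix[rows, , drop = FALSE]
  base <- list(structure = oo$structure, kind = oo$kind, rows = rows,
               priority = oo$priority, goal = oo$goal_val,
               sufficient = oo$sufficient_val, weight = 1)
  switch(oo$kind,
    ltcp = c(base, list(type = "ltcp", A = A, pd = oo$pd_gy,
                        alpha = oo$alpha)),
    geud = c(base, list(type = "geud", A = A, k = oo$k, s0 = 50)),
    mean_dose = c(base, list(type = "lin", a = Matrix::colMeans(A))),
    max_dose = c(base, list(type = "max", A = A)),
    min_dose = c(base, list(type = "min", A = A)))
}

component_value <- function(cm, dij, w) {
  d <- if (!is.null(cm$A)) as.numeric(cm$A %*% w)
       else as.numeric(dij$matrix[cm$rows, , drop = FALSE] %*% w)
  switch(cm$type,
    ltcp = mean(clip_exp(-cm$alpha * (d - cm$pd))),
    geud = geud_val(d, cm$k, cm$s0),
    lin = mean(d),
    max = max(d),
    min = min(d))
}

#' Solve a wish-list by sequential lexicographic optimization
#'
#' Runs phase-1 feasibility for the hard constraints, then minimizes each
#' enabled objective in priority order (equal priorities jointly, as an
#' equally weighted sum), converting every optimized objective into a
#' constraint at \code{max(attained, sufficient) * (1 + slack_delta)}
#' before the next priority is addressed.
#'
#' @param wl a \code{wishlist} (resolved or not).
#' @param dij a \code{dose_influence}.
#' @param structures a \code{structure_set} containing every structure the
#'   wish-list references.
#' @param opts a \code{\link{solver_opts}}.
#' @param w_start optional starting beamlet weights (e.g. a previously
#'   solved plan for the same patient); phase 1 begins there.
#' @return An object of class \code{rt_plan}: beamlet \code{weights}, the
#'   \code{dose} vector over the dose-influence rows, a per-objective
#'   \code{trace} data.frame (attained value, imposed bound, status),
#'   \code{feasible}, and on infeasibility an \code{infeasibility} report
#'   naming the blocking constraints.
#' @export
lexicographic_solve <- function(wl, dij, structures, opts = solver_opts(),
                                w_start = NULL) {
  stopifnot(inherits(wl, "wishlist"), inherits(dij, "dose_influence") ||
              is.list(dij))
  if (!isTRUE(wl$resolved)) wl <- resolve_limits(wl)
  nb <- ncol(dij$matrix)

  # start point: caller-supplied warm start, else uniform weights scaled
  # to the high prescription in PTV_High (or overall mean dose if absent)
  w_ref <- if (!is.null(w_start)) {
    stopifnot(length(w_start) == nb)
    pmax(w_start, 1e-8)
  } else {
    d1 <- as.numeric(dij$matrix %*% rep(1, nb))
    ph <- structures$masks$PTV_High
    tgt <- if (!is.null(ph) && any(ph[dij$voxel_index]))
      mean(d1[structure_rows(dij, ph)]) else mean(d1[d1 > 0])
    rep(wl$prescription$pd_high / max(tgt, 1e-9), nb)
  }

  hc <- hard_constraint_terms(wl, dij, structures, w_ref, opts)
  cons <- hc$terms
  notes <- hc$notes

  ph1 <- phase1_solve(cons, nb, w_ref, opts)
  if (!ph1$feasible) {
    rep_ <- infeasibility_report(cons, nb, ph1, opts)
    return(structure(list(weights = ph1$w,
                          dose = as.numeric(dij$matrix %*% ph1$w),
                          voxel_index = dij$voxel_index,
                          trace = empty_trace(), feasible = FALSE,
                          infeasibility = rep_, wishlist = wl,
                          notes = notes),
                     class = "rt_plan"))
  }
  w <- ph1$w

  obj_enabled <- Filter(function(o) isTRUE(o$enabled), wl$objectives)
  # coverage warm-up: drive every enabled LTCP objective to (or below) its
  # sufficient value under the hard constraints, as a soft-minimax
  # feasibility problem. This starts the priority sequence from a
  # well-covered plan instead of recovering coverage by slow descents
  # later; the lexicographic result does not depend on the starting point.
  ltcp_objs <- Filter(function(o) o$kind == "ltcp", obj_enabled)
  if (length(ltcp_objs)) {
    comps <- Filter(Negate(is.null),
                    lapply(ltcp_objs, objective_component, dij = dij,
                           structures = structures))
    if (length(comps)) {
      pseudo <- lapply(comps, function(cm)
        list(type = "ltcp_upper", A = cm$A, pd = cm$pd, alpha = cm$alpha,
             b = cm$sufficient, scale = max(1, cm$sufficient),
             label = paste0("warm-up ", cm$structure), lazy = FALSE))
      wu_opts <- opts
      wu_opts$max_newton <- max(60L, opts$max_newton)
      wu <- phase1_solve(c(cons, pseudo), nb, w, wu_opts)
      w <- wu$w
    }
  }
  comps_all <- lapply(obj_enabled, objective_component, dij = dij,
                      structures = structures)
  skipped <- vapply(comps_all, is.null, logical(1))
  for (o in obj_enabled[skipped])
    notes <- c(notes, sprintf("objective on empty structure '%s' skipped",
                              o$structure))
  comps_all <- comps_all[!skipped]
  prios <- sort(unique(vapply(comps_all, `[[`, integer(1), "priority")))

  trace <- list()
  delta <- wl$slack_delta
  feasible <- TRUE

  for (p in prios) {
    group <- Filter(function(cm) cm$priority == p, comps_all)
    if (!is.null(dmp <- getOption("prioplan.dump_dir")))
      saveRDS(list(p = p, group = group, cons = cons, w = w, nb = nb),
              file.path(dmp, sprintf("state_p%d.rds", p)))
    epi_rows <- vector("list", length(group))
    # objectives already at their sufficient values need no optimization;
    # the bound below is floored at the sufficient value either way
    if (isTRUE(opts$stop_at_sufficient) &&
        all(vapply(group, function(cm)
          cm$type != "min" && is.finite(cm$sufficient) &&
            component_value(cm, dij, w) <= cm$sufficient, logical(1)))) {
      sol <- list(status = "sufficient")
      for (cm in group) {
        att <- component_value(cm, dij, w)
        trace[[length(trace) + 1L]] <-
          data.frame(priority = p, structure = cm$structure, kind = cm$kind,
                     attained = att,
                     bound = max(att, cm$sufficient) * (1 + delta) + 1e-9,
                     goal = cm$goal, sufficient = cm$sufficient,
                     status = "sufficient", stringsAsFactors = FALSE)
        lab <- sprintf("p%d %s %s", p, cm$structure, cm$kind)
        cons[[length(cons) + 1L]] <-
          convert_component(cm, max(att, cm$sufficient) * (1 + delta) + 1e-9,
                            lab, dij, w, opts)
        if (opts$verbose)
          message(sprintf("  p%-2d %-30s %-9s attained %.5g (goal %.5g) [pre-sufficient]",
                          p, cm$structure, cm$kind, att, cm$goal))
      }
      next
    }
    for (round in seq_len(opts$max_lazy_rounds + 2L)) {
      sol <- tryCatch(solve_priority(group, cons, dij, nb, w, opts, epi_rows),
                      error = function(e) NULL)
      if (is.null(sol)) {
        # numerical drift can leave the warm start marginally infeasible;
        # re-establish strict feasibility and retry once
        ph <- phase1_solve(cons, nb, w, opts)
        if (ph$feasible) w <- ph$w
        sol <- tryCatch(solve_priority(group, cons, dij, nb, w, opts,
                                       epi_rows),
                        error = function(e) NULL)
        if (is.null(sol)) {
          # leave this priority unoptimized rather than aborting the plan;
          # its current values are still frozen as bounds below
          notes <- c(notes, sprintf(
            "priority %d: solve could not start (residual %.3g); skipped",
            p, ph$max_violation))
          sol <- list(w = w, status = "skipped", epi_rows = epi_rows)
        }
      }
      w_new <- sol$w
      epi_rows <- sol$epi_rows
      aug <- FALSE
      # epigraph objectives: if the true structure maximum sits on rows
      # that were not in the active subset, activate them and re-solve
      for (gi in seq_along(group)) {
        cm <- group[[gi]]
        if (!cm$type %in% c("max", "min") || is.null(epi_rows[[gi]])) next
        if (length(epi_rows[[gi]]) == length(cm$rows)) next
        d_full <- as.numeric(cm$A %*% w_new)
        act <- epi_rows[[gi]]
        if (cm$type == "max") {
          att_full <- max(d_full)
          att_act <- max(d_full[match(act, cm$rows)])
          if (att_full > att_act * (1 + 1e-4)) {
            add <- cm$rows[d_full >= opts$activation_frac * att_full]
            epi_rows[[gi]] <- sort(unique(c(act, add)))
            aug <- TRUE
          }
        } else {
          att_full <- min(d_full)
          att_act <- min(d_full[match(act, cm$rows)])
          if (att_full < att_act * (1 - 1e-4)) {
            add <- cm$rows[d_full <= att_full / opts$activation_frac]
            epi_rows[[gi]] <- sort(unique(c(act, add)))
            aug <- TRUE
          }
        }
      }
      # full-row verification of all lazy voxelwise constraints
      for (i in seq_along(cons)) {
        bad <- lazy_violations(cons[[i]], dij, w_new)
        if (length(bad)) {
          cons[[i]]$rows_act <- sort(unique(c(cons[[i]]$rows_act, bad)))
          cons[[i]]$A <- dij$matrix[cons[[i]]$rows_act, , drop = FALSE]
          aug <- TRUE
        }
      }
      if (!aug) { w <- w_new; break }
      if (round == opts$max_lazy_rounds + 2L) {
        w <- w_new
        notes <- c(notes,
                   sprintf("priority %d: lazy rows still active after %d rounds",
                           p, round))
      } else {
        ph <- phase1_solve(cons, nb, w_new, opts)
        w <- if (ph$feasible) ph$w else w_new
      }
    }
    # convert each component to a constraint at its attained value
    for (cm in group) {
      att <- component_value(cm, dij, w)
      bound <- if (cm$type == "min")
        max(att, cm$sufficient) * (1 - delta) - 1e-9
      else max(att, cm$sufficient) * (1 + delta) + 1e-9
      lab <- sprintf("p%d %s %s", p, cm$structure, cm$kind)
      cons[[length(cons) + 1L]] <- convert_component(cm, bound, lab, dij,
                                                     w, opts)
      trace[[length(trace) + 1L]] <-
        data.frame(priority = p, structure = cm$structure, kind = cm$kind,
                   attained = att, bound = bound, goal = cm$goal,
                   sufficient = cm$sufficient, status = sol$status,
                   stringsAsFactors = FALSE)
      if (opts$verbose)
        message(sprintf("  p%-2d %-30s %-9s attained %.5g (goal %.5g) [%s]",
                        p, cm$structure, cm$kind, att, cm$goal, sol$status))
    }
  }

  # optional polish: re-minimize each priority in order under the full set
  # of accumulated bounds (its own bound included, so values only improve)
  if (isTRUE(opts$polish)) {
    for (p in prios) {
      group <- Filter(function(cm) cm$priority == p, comps_all)
      sol <- solve_priority(group, cons, dij, nb, w, opts)
      w <- sol$w
    }
  }

  dose <- as.numeric(dij$matrix %*% w)
  viol <- check_constraint_residuals(cons, w)
  feasible <- all(viol <= VIOL_TOL)
  tr <- if (length(trace)) do.call(rbind, trace) else empty_trace()
  structure(list(weights = w, dose = dose, voxel_index = dij$voxel_index,
                 trace = tr, feasible = feasible, wishlist = wl,
                 notes = notes),
            class = "rt_plan")
}

# freeze an optimized objective component as a constraint term at `bound`
convert_component <- function(cm, bound, lab, dij, w, opts) {
  switch(cm$type,
    ltcp = list(type = "ltcp_upper", A = cm$A, pd = cm$pd,
                alpha = cm$alpha, b = bound, scale = max(bound, 1),
                label = lab, lazy = FALSE),
    geud = list(type = "geud_upper", A = cm$A, k = cm$k, s0 = cm$s0,
                b = bound, scale = max(1, bound), label = lab,
                lazy = FALSE),
    lin = list(type = "mean_upper", a = cm$a, b = bound,
               scale = max(1, bound), label = lab, lazy = FALSE),
    max = new_vox_term(dij, cm$rows, "vox_upper", bound, lab, opts,
                       if (length(cm$rows) > opts$lazy_cap)
                         activate_rows(dij, cm$rows, "vox_upper",
                                       bound, w, opts) else NULL),
    min = new_vox_term(dij, cm$rows, "vox_lower", bound, lab, opts, NULL))
}

empty_trace <- function() {
  data.frame(priority = integer(0), structure = character(0),
             kind = character(0), attained = numeric(0),
             bound = numeric(0), goal = numeric(0),
             sufficient = numeric(0), status = character(0),
             stringsAsFactors = FALSE)
}

check_constraint_residuals <- function(cons, w) {
  vapply(cons, function(tm) max(term_g(tm, w)), numeric(1))
}

# Solve one priority group: equally weighted sum of its components, with
# epigraph variables for max/min components. epi_rows carries the active
# voxel-row subsets of the epigraph components across re-solve rounds.
# gEUD objectives (the rectum-sparing drive, whose attained value feeds
# the toxicity model) always get the full stage-retry budget, even when
# the caller trades precision for speed elsewhere.
solve_priority <- function(group, cons, dij, nb, w, opts,
                           epi_rows = vector("list", length(group))) {
  if (any(vapply(group, function(cm) cm$type == "geud", logical(1))))
    opts$max_retries <- max(opts$max_retries, 4L)
  naux <- 0L
  comps <- list(); aux_cost <- numeric(0); epi_terms <- list()
  t_init <- numeric(0)
  for (gi in seq_along(group)) {
    cm <- group[[gi]]
    if (cm$type %in% c("max", "min")) {
      naux <- naux + 1L
      d <- as.numeric(cm$A %*% w)
      rows <- cm$rows
      if (length(rows) > opts$lazy_cap && is.null(epi_rows[[gi]])) {
        thr <- if (cm$type == "max") opts$activation_frac * max(d)
               else min(d) / opts$activation_frac
        sel <- if (cm$type == "max") d >= thr else d <= thr
        if (sum(sel) < 50)
          sel[order(d, decreasing = cm$type == "max")[1:min(50, length(d))]] <- TRUE
        rows <- cm$rows[sel]
      } else if (!is.null(epi_rows[[gi]])) {
        rows <- epi_rows[[gi]]
      }
      epi_rows[[gi]] <- rows
      dr <- d[match(rows, cm$rows)]
      scl <- max(1, abs(if (cm$type == "max") max(d) else min(d)))
      epi_terms[[length(epi_terms) + 1L]] <-
        list(type = if (cm$type == "max") "epi_upper" else "epi_lower",
             A = dij$matrix[rows, , drop = FALSE], aux = naux, scale = scl,
             rows_full = cm$rows, comp = cm)
      aux_cost[naux] <- if (cm$type == "max") cm$weight else -cm$weight
      t_init[naux] <- if (cm$type == "max") max(dr) * 1.001 + 1e-3
                      else min(dr) * 0.999 - 1e-3
    } else {
      comps[[length(comps) + 1L]] <- cm
    }
  }
  if (naux > 0L) {
    # smooth warm start: replace each max/min component by a soft-max
    # (log-sum-exp style) exponential surrogate so the solver crosses the
    # long barrier valley quickly; the exact epigraph solve then polishes
    tau <- 1.5
    sur <- comps
    for (gi in seq_along(group)) {
      cm <- group[[gi]]
      if (!cm$type %in% c("max", "min")) next
      d <- as.numeric(dij$matrix[epi_rows[[gi]], , drop = FALSE] %*% w)
      ref <- if (cm$type == "max") max(d) else min(d)
      sur[[length(sur) + 1L]] <-
        list(type = "ltcp", A = dij$matrix[epi_rows[[gi]], , drop = FALSE],
             pd = ref, alpha = if (cm$type == "max") -1 / tau else 1 / tau,
             weight = cm$weight * tau)
    }
    wu <- opts
    wu$gap_tol <- 1e-2; wu$max_newton <- 30; wu$stop_at_sufficient <- FALSE
    probw <- list(nb = nb, naux = 0L,
                  obj = list(comps = sur, aux_cost = numeric(0)),
                  cons = cons)
    w <- barrier_solve(probw, w, wu)$x[seq_len(nb)]
    for (gi in seq_along(group)) {
      cm <- group[[gi]]
      if (!cm$type %in% c("max", "min")) next
      j <- match(gi, which(vapply(group, function(g)
        g$type %in% c("max", "min"), logical(1))))
      d <- as.numeric(dij$matrix[epi_rows[[gi]], , drop = FALSE] %*% w)
      t_init[j] <- if (cm$type == "max") max(d) * 1.001 + 1e-3
                   else min(d) * 0.999 - 1e-3
    }
  }
  prob <- list(nb = nb, naux = naux,
               obj = list(comps = comps, aux_cost = aux_cost),
               cons = c(cons, epi_terms))
  x0 <- c(w, t_init)

  stop_check <- NULL
  if (isTRUE(opts$stop_at_sufficient) &&
      !any(vapply(group, function(cm) cm$type == "min", logical(1))) &&
      all(vapply(group, function(cm) is.finite(cm$sufficient), logical(1))) &&
      any(vapply(group, function(cm) cm$sufficient > 0, logical(1)))) {
    stop_check <- function(x) {
      wv <- x[seq_len(nb)]
      all(vapply(group, function(cm)
        component_value(cm, dij, wv) <= cm$sufficient, logical(1)))
    }
  }
  res <- barrier_solve(prob, x0, opts, stop_check)
  # for lazy epigraph objectives the aux value may undershoot the true
  # maximum; attained values are always recomputed on the full rows
  list(w = res$x[seq_len(nb)], status = res$status, epi_rows = epi_rows)
}

infeasibility_report <- function(cons, nb, ph1, opts) {
  g_at <- lapply(cons, term_g, w = ph1$w)
  gmax <- vapply(g_at, max, numeric(1))
  top <- max(gmax)
  blocking <- vapply(cons, `[[`, character(1), "label")[
    gmax >= min(-opts$feas_margin, top - max(0.05 * abs(top), 1e-6))]
  # greedy relaxation probe: drop the worst constraint until feasible
  relaxed <- character(0)
  remaining <- cons
  w <- ph1$w
  for (k in seq_len(length(cons) - 1L)) {
    gm <- vapply(remaining, function(tm) max(term_g(tm, w)), numeric(1))
    if (max(gm) <= -opts$feas_margin) break
    drop_i <- which.max(gm)
    relaxed <- c(relaxed, remaining[[drop_i]]$label)
    remaining <- remaining[-drop_i]
    if (length(remaining) == 0L) break
    ph <- phase1_solve(remaining, nb, w, opts)
    w <- ph$w
    if (ph$feasible) break
  }
  structure(list(blocking = unique(blocking), relaxed = relaxed,
                 max_violation = ph1$max_violation),
            class = "infeasibility_report")
}

#' @exportS3Method base::print
print.rt_plan <- function(x, ...) {
  cat("<rt_plan>", if (x$feasible) "feasible" else "INFEASIBLE",
      "-", length(x$weights), "beamlets\n")
  if (nrow(x$trace)) print(x$trace, digits = 4)
  if (!is.null(x$infeasibility))
    cat("blocking constraints:",
        paste(x$infeasibility$blocking, collapse = "; "), "\n")
  invisible(x)
}

#' Verify a plan against a wish-list
#'
#' Re-evaluates every hard constraint and every enabled objective of the
#' wish-list on the plan's dose distribution.
#'
#' @param plan an \code{rt_plan}.
#' @param wl the \code{wishlist} (resolved or not).
#' @param structures the \code{structure_set}.
#' @return A data.frame with one row per constraint/objective: value,
#'   limit or goal, satisfied flag and margin.
#' @export
check_plan <- function(plan, wl, structures) {
  if (!isTRUE(wl$resolved)) wl <- resolve_limits(wl)
  rows <- list()
  for (cc in wl$constraints) {
    mask <- structures$masks[[cc$structure]]
    if (is.null(mask) || !any(mask)) next
    v <- evaluate_cost(cc, plan$dose, structures, plan$voxel_index)
    lower <- cc$kind == "min_dose"
    margin <- if (lower) v - cc$limit_gy else cc$limit_gy - v
    rows[[length(rows) + 1L]] <-
      data.frame(role = "constraint", structure = cc$structure,
                 kind = cc$kind, value = v, reference = cc$limit_gy,
                 satisfied = margin >= -VIOL_TOL * max(1, abs(cc$limit_gy)),
                 margin = margin, priority = NA_integer_,
                 stringsAsFactors = FALSE)
  }
  for (oo in wl$objectives) {
    if (!isTRUE(oo$enabled)) next
    mask <- structures$masks[[oo$structure]]
    if (is.null(mask) || !any(mask)) next
    v <- evaluate_cost(oo, plan$dose, structures, plan$voxel_index)
    rows[[length(rows) + 1L]] <-
      data.frame(role = "objective", structure = oo$structure,
                 kind = oo$kind, value = v, reference = oo$goal_val,
                 satisfied = NA, margin = oo$goal_val - v,
                 priority = oo$priority, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
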