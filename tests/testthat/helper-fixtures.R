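# Shared fixtures: micro linear-algebra problems with a brute-force
# lexicographic oracle, small phantom scales sized for test runtime, and
# a cached seven-plan workflow shared by several test files.

library(Matrix)

micro_grid <- function(n) grid_spec(c(n, 1L, 1L), c(1, 1, 1))

# wrap a plain influence matrix as a dose_influence-like object
micro_dij <- function(A) {
  structure(list(matrix = as(A, "CsparseMatrix"),
                 voxel_index = seq_len(nrow(A)),
                 grid = micro_grid(nrow(A)),
                 beam_of_beamlet = seq_len(ncol(A)),
                 config = beam_config(n_beams = 2)),
            class = "dose_influence")
}

micro_structs <- function(nvox, masks) {
  g <- micro_grid(nvox)
  ms <- lapply(masks, function(idx) {
    m <- array(FALSE, g$shape); m[idx] <- TRUE; m
  })
  structure(list(masks = ms, grid = g), class = "structure_set")
}

# Brute-force lexicographic oracle: refining grid search over the weight
# box, applying the same objective-to-constraint conversion contract as
# the solver (bound = max(attained, sufficient) * (1 + delta) + 1e-9).
# objs: list(fun = function(dose) value, sufficient = number)
# cons: list of function(dose) -> residual <= 0 when satisfied
oracle_lexicographic <- function(A, cons, objs, wmax, delta = 1e-3,
                                 npts = 25, rounds = 8) {
  A <- as.matrix(A)
  nb <- ncol(A)
  attained <- numeric(0)
  bounds <- list()
  best_w <- NULL
  feasible_fun <- function(d, upto) {
    for (cc in cons) if (any(cc(d) > 1e-12)) return(FALSE)
    for (bi in seq_len(upto))
      if (objs[[bi]]$fun(d) > bounds[[bi]]) return(FALSE)
    TRUE
  }
  for (oi in seq_along(objs)) {
    # search around the incumbent (feasible for all accumulated bounds by
    # construction), falling back to the global box on the first objective
    if (is.null(best_w)) {
      lo_i <- rep(0, nb); hi_i <- rep(wmax, nb)
    } else {
      lo_i <- pmax(0, best_w - wmax / 2); hi_i <- best_w + wmax / 2
    }
    w_best <- best_w
    f_best <- if (is.null(best_w)) Inf
              else objs[[oi]]$fun(as.numeric(A %*% best_w))
    for (r in seq_len(rounds)) {
      grids <- lapply(seq_len(nb), function(j)
        seq(lo_i[j], hi_i[j], length.out = npts))
      W <- as.matrix(expand.grid(grids))
      if (!is.null(w_best)) W <- rbind(W, w_best)
      D <- W %*% t(A)
      ok <- apply(D, 1, feasible_fun, upto = length(bounds))
      if (any(ok)) {
        fv <- apply(D[ok, , drop = FALSE], 1, function(d) objs[[oi]]$fun(d))
        k <- which.min(fv)
        if (fv[k] < f_best) {
          f_best <- fv[k]
          w_best <- W[ok, , drop = FALSE][k, ]
        }
      }
      span <- (hi_i - lo_i) / (npts - 1)
      ctr <- if (is.null(w_best)) (lo_i + hi_i) / 2 else w_best
      lo_i <- pmax(0, ctr - 1.5 * span)
      hi_i <- ctr + 1.5 * span
    }
    attained[oi] <- f_best
    bounds[[oi]] <- max(f_best, objs[[oi]]$sufficient) * (1 + delta) + 1e-9
    best_w <- w_best
  }
  list(attained = attained, w = best_w, bounds = unlist(bounds))
}

# tight solver options for oracle-equivalence checks on micro problems
oracle_opts <- function() {
  solver_opts(stop_at_sufficient = FALSE, gap_tol = 1e-8,
              max_newton = 80, mu_init_mult = 1)
}

# small-phantom scale used by the geometry/dosimetry tests: coarse enough
# to be fast, fine enough that the anatomy is resolved
test_phantom_params <- function() {
  phantom_params(grid = grid_spec(c(44, 44, 12), c(3.6, 3.6, 5.5)))
}

test_beam_config <- function() beam_config(n_beams = 9L, beamlet_width_mm = 8)

test_x_schedule <- function() default_x_schedule()

# workflow scale: coarser still, with 12 beams of 8 mm beamlets so the
# coverage ladder can reach the low-90s floors within test runtime
echo_phantom_params <- function() {
  phantom_params(grid = grid_spec(c(36, 36, 10), c(4.4, 4.4, 6.6)))
}

echo_beam_config <- function() beam_config(n_beams = 12L,
                                           beamlet_width_mm = 8)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# one seeded test phantom with structures and dose influence (no solving)
test_patient_inputs <- function() {
  cached("inputs", {
    ph <- generate_phantom(7, test_phantom_params())
    ss <- build_planning_structures(ph)
    ss <- build_rectum_prv(ss, select_prv_margin(
      overlap_percentage(ss)$overlap_pct))
    dij <- compute_dose_influence(ph, test_beam_config())
    list(phantom = ph, structures = ss, dij = dij)
  })
}

# five-patient mini-cohort at the workflow scale, shared by the workflow
# and cohort-level tests: patient 1 runs the full six-rung ladder, the
# other overlapping patients a three-rung ladder spanning the same
# coverage range, the zero-overlap patients a single deep rung (their
# plans coincide anyway). The cohort holds two zero-overlap patients and
# overlaps spanning the 25/10 mm PRV-margin classes.
cached_echo_cohort <- function() {
  cached("echo", {
    pp <- echo_phantom_params()
    cfg <- echo_beam_config()
    opts <- solver_opts(max_retries = 2L)
    cohort <- generate_cohort(5, 1, pp)
    lapply(seq_along(cohort), function(i) {
      ov <- overlap_percentage(build_planning_structures(
        cohort[[i]]))$overlap_pct
      xs <- if (i == 1) test_x_schedule()
            else if (ov == 0) 3e4
            else c(10, 3e4)
      run_patient(cohort[[i]],
                  dij = compute_dose_influence(cohort[[i]], cfg),
                  x_schedule = xs, opts = opts)
    })
  })
}

# the cached full seven-plan workflow run shared across test files
cached_workflow <- function() cached_echo_cohort()[[1]]
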