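# Convex solver backing the lexicographic engine: a log-barrier
# interior-point method with damped Newton inner iterations. All cost
# functions used by the wish-list are smooth convex (LTCP, gEUD for k >= 1,
# linear dose functions), maximum/minimum-dose objectives are handled
# exactly through epigraph variables, and voxelwise dose limits are linear
# rows. Problems are expressed as lists of typed "terms":
#
#   vox_upper   A w <= b (per row)         vox_lower   A w >= b
#   mean_upper  a' w <= b                  ltcp_upper  LTCP(A w) <= b
#   geud_upper  gEUD_k(A w) <= b
#   epi_upper   (A w)_i <= t_j             epi_lower   (A w)_i >= t_j
#
# Objective components: ltcp, geud, lin (a' w), plus linear costs on
# epigraph variables. The variable vector is x = (w, t_aux); w is kept
# positive by its own barrier term.
#
# For speed, all dose-dependent terms of a priority are evaluated through
# one stacked sparse matrix: a single mat-vec gives every voxel dose, one
# row-weighted crossprod assembles the whole A' D A part of the Hessian,
# and one multi-column crossprod collects every rank-one / epigraph cross
# vector.

EXP_CLIP <- 250

#' Solver options
#'
#' @param slack_delta relative slack used when converting an optimized
#'   objective into a constraint for lower priorities.
#' @param mu_factor geometric reduction factor of the barrier parameter.
#' @param gap_tol relative duality-gap target terminating the barrier
#'   sequence (suboptimality <= n_constraints * mu).
#' @param newton_tol Newton-decrement stopping tolerance (relative).
#' @param max_newton maximum Newton iterations per barrier stage.
#' @param feas_margin strict-feasibility margin demanded by phase 1
#'   (normalized units).
#' @param lazy_cap voxelwise constraints on structures with more rows than
#'   this use lazy row activation.
#' @param activation_frac fraction of the bound (or of the running
#'   maximum) above which voxel rows are activated.
#' @param max_lazy_rounds re-solve rounds allowed for lazy row violations.
#' @param stop_at_sufficient stop minimizing an objective once its
#'   sufficient value is reached (the imposed bound is unaffected).
#' @param polish run a final re-minimization pass over all priorities
#'   under the accumulated bounds.
#' @param mu_init_mult multiplier on the initial barrier parameter; values
#'   above 1 re-centre warm-started iterates away from the constraint
#'   boundaries of higher priorities before the descent.
#' @param max_retries how often an uncentred (iteration-capped) barrier
#'   stage is retried at the same barrier parameter before the stage is
#'   declared stalled.
#' @param verbose print per-priority progress lines.
#' @return List of class \code{solver_opts}.
#' @export
solver_opts <- function(slack_delta = 1e-3, mu_factor = 20, gap_tol = 1e-4,
                        newton_tol = 1e-8, max_newton = 30,
                        feas_margin = 1e-5, lazy_cap = 1200,
                        activation_frac = 0.8, max_lazy_rounds = 3,
                        stop_at_sufficient = TRUE, polish = FALSE,
                        mu_init_mult = 30, max_retries = 4L,
                        verbose = FALSE) {
  structure(as.list(environment()), class = "solver_opts")
}

clip_exp <- function(z) exp(pmin(z, EXP_CLIP))

geud_val <- function(d, k, s0) {
  r <- d / s0
  s0 * mean(r^k)^(1 / k)
}

# gradient and Hessian pieces of gEUD wrt the dose vector: H_d =
# diag(dd) + qcoef * q q'
geud_parts <- function(d, k, s0) {
  m <- length(d)
  r <- d / s0
  S <- sum(r^k)
  if (S < 1e-290)
    return(list(val = 0, gd = numeric(m), dd = numeric(m), q = numeric(m),
                qcoef = 0))
  cc <- s0 * m^(-1 / k)
  list(val = cc * S^(1 / k),
       gd = (cc / s0) * S^(1 / k - 1) * r^(k - 1),
       dd = (cc * (k - 1) / s0^2) * S^(1 / k - 1) * r^(k - 2),
       q = r^(k - 1) / s0,
       qcoef = -(cc * (k - 1)) * S^(1 / k - 2))
}

at_v <- function(A, v) as.numeric(Matrix::crossprod(A, v))

# A' diag(v) A for a dgCMatrix without dispatch overhead: scale the
# nonzeros row-wise by sqrt(v) and take one crossprod
atda <- function(A, v) {
  A@x <- A@x * sqrt(v)[A@i + 1L]
  Matrix::crossprod(A)
}

# normalized residual(s) g <= 0 of one constraint term
term_g <- function(term, w) {
  if (term$type == "mean_upper")
    return((sum(term$a * w) - term$b) / term$scale)
  d <- as.numeric(term$A %*% w)
  switch(term$type,
    vox_upper = (d - term$b) / term$scale,
    vox_lower = (term$b - d) / term$scale,
    ltcp_upper = (mean(clip_exp(-term$alpha * (d - term$pd))) - term$b) /
      term$scale,
    geud_upper = (geud_val(d, term$k, term$s0) - term$b) / term$scale,
    stop("bad term type ", term$type))
}

# ---- stacked problem ------------------------------------------------------

# Collect the A blocks of every dose-dependent objective component and
# constraint term into one sparse matrix, remembering slice offsets.
build_stack <- function(prob) {
  blocks <- list()
  off <- 0L
  add <- function(role, idx, A) {
    n <- nrow(A)
    blocks[[length(blocks) + 1L]] <<- list(role = role, idx = idx,
                                           off = off, n = n)
    off <<- off + n
    A
  }
  As <- list()
  for (i in seq_along(prob$obj$comps)) {
    cm <- prob$obj$comps[[i]]
    if (cm$type %in% c("ltcp", "geud"))
      As[[length(As) + 1L]] <- add("obj", i, cm$A)
  }
  for (i in seq_along(prob$cons)) {
    tm <- prob$cons[[i]]
    if (tm$type != "mean_upper")
      As[[length(As) + 1L]] <- add("con", i, tm$A)
  }
  prob$stack <- list(
    A = if (length(As)) do.call(rbind, As) else
      Matrix::Matrix(0, 0, prob$nb, sparse = TRUE),
    blocks = blocks)
  prob
}

# Evaluate objective + barrier at x; with want_deriv also gradient and
# dense Hessian. Returns phi = Inf outside the strictly feasible domain.
eval_barrier <- function(prob, x, mu, want_deriv = FALSE) {
  nb <- prob$nb
  naux <- prob$naux
  nvar <- nb + naux
  w <- x[seq_len(nb)]
  taux <- if (naux) x[nb + seq_len(naux)] else numeric(0)
  if (any(w <= 0)) return(list(phi = Inf))

  st <- prob$stack
  dstk <- as.numeric(st$A %*% w)

  f <- 0
  phi_extra <- -mu * sum(log(w))
  vvec <- numeric(length(dstk))   # gradient row-coefficients
  cvec <- numeric(length(dstk))   # Hessian row-weights (A' diag(cvec) A)
  rank1 <- list()                 # list(coef, rvec, off, n) -> A_blk' rvec
  cross <- list()                 # list(j (aux), rvec, off, n)
  grad_t <- numeric(naux)
  htt <- numeric(naux)
  grad_w_dense <- numeric(nb)     # pieces not through the stack
  rank1_dense <- list()           # list(coef, v (length nvar))

  for (bl in st$blocks) {
    sl <- bl$off + seq_len(bl$n)
    d <- dstk[sl]
    if (bl$role == "obj") {
      cm <- prob$obj$comps[[bl$idx]]
      wgt <- cm$weight
      if (cm$type == "ltcp") {
        e <- clip_exp(-cm$alpha * (d - cm$pd))
        m <- bl$n
        f <- f + wgt * mean(e)
        if (want_deriv) {
          vvec[sl] <- vvec[sl] - wgt * (cm$alpha / m) * e
          cvec[sl] <- cvec[sl] + wgt * (cm$alpha^2 / m) * e
        }
      } else {                    # geud
        gp <- geud_parts(d, cm$k, cm$s0)
        f <- f + wgt * gp$val
        if (want_deriv) {
          vvec[sl] <- vvec[sl] + wgt * gp$gd
          cvec[sl] <- cvec[sl] + wgt * gp$dd
          rank1[[length(rank1) + 1L]] <-
            list(coef = wgt * gp$qcoef, rvec = gp$q, off = bl$off, n = bl$n)
        }
      }
    } else {
      tm <- prob$cons[[bl$idx]]
      tt <- tm$type
      if (tt %in% c("vox_upper", "vox_lower", "epi_upper", "epi_lower")) {
        s <- switch(tt,
          vox_upper = tm$b - d,
          vox_lower = d - tm$b,
          epi_upper = taux[tm$aux] - d,
          epi_lower = d - taux[tm$aux])
        if (any(s <= 0)) return(list(phi = Inf))
        phi_extra <- phi_extra - mu * sum(log(s))
        if (want_deriv) {
          sgn <- if (tt %in% c("vox_upper", "epi_upper")) 1 else -1
          vvec[sl] <- vvec[sl] + sgn * mu / s
          cvec[sl] <- cvec[sl] + mu / s^2
          if (tt %in% c("epi_upper", "epi_lower")) {
            j <- tm$aux
            grad_t[j] <- grad_t[j] - sgn * sum(mu / s)
            htt[j] <- htt[j] + sum(mu / s^2)
            cross[[length(cross) + 1L]] <-
              list(j = j, rvec = -mu / s^2, off = bl$off, n = bl$n)
          }
        }
      } else if (tt == "ltcp_upper") {
        e <- clip_exp(-tm$alpha * (d - tm$pd))
        m <- bl$n
        V <- mean(e)
        s <- tm$b - V
        if (s <= 0) return(list(phi = Inf))
        phi_extra <- phi_extra - mu * log(s)
        if (want_deriv) {
          vvec[sl] <- vvec[sl] - (mu / s) * (tm$alpha / m) * e
          cvec[sl] <- cvec[sl] + (mu / s) * (tm$alpha^2 / m) * e
          rank1[[length(rank1) + 1L]] <-
            list(coef = mu / s^2, rvec = -(tm$alpha / m) * e,
                 off = bl$off, n = bl$n)
        }
      } else if (tt == "geud_upper") {
        gp <- geud_parts(d, tm$k, tm$s0)
        s <- tm$b - gp$val
        if (s <= 0) return(list(phi = Inf))
        phi_extra <- phi_extra - mu * log(s)
        if (want_deriv) {
          vvec[sl] <- vvec[sl] + (mu / s) * gp$gd
          cvec[sl] <- cvec[sl] + (mu / s) * gp$dd
          rank1[[length(rank1) + 1L]] <-
            list(coef = (mu / s) * gp$qcoef, rvec = gp$q,
                 off = bl$off, n = bl$n)
          rank1[[length(rank1) + 1L]] <-
            list(coef = mu / s^2, rvec = gp$gd, off = bl$off, n = bl$n)
        }
      }
    }
  }

  # non-stacked pieces: linear objective components, mean constraints
  for (cm in prob$obj$comps) {
    if (cm$type == "lin") {
      f <- f + cm$weight * sum(cm$a * w)
      if (want_deriv) grad_w_dense <- grad_w_dense + cm$weight * cm$a
    }
  }
  for (tm in prob$cons) {
    if (tm$type == "mean_upper") {
      s <- tm$b - sum(tm$a * w)
      if (s <= 0) return(list(phi = Inf))
      phi_extra <- phi_extra - mu * log(s)
      if (want_deriv) {
        grad_w_dense <- grad_w_dense + (mu / s) * tm$a
        rank1_dense[[length(rank1_dense) + 1L]] <-
          list(coef = mu / s^2, v = c(tm$a, numeric(naux)))
      }
    }
  }
  if (naux) f <- f + sum(prob$obj$aux_cost * taux)

  out <- list(phi = f + phi_extra, f = f)
  if (!want_deriv) return(out)

  grad <- numeric(nvar)
  grad[seq_len(nb)] <- at_v(st$A, vvec) + grad_w_dense - mu / w
  if (naux) grad[nb + seq_len(naux)] <- grad_t + prob$obj$aux_cost

  Hw <- as.matrix(atda(st$A, cvec))
  H <- matrix(0, nvar, nvar)
  H[seq_len(nb), seq_len(nb)] <- Hw
  diag(H)[seq_len(nb)] <- diag(H)[seq_len(nb)] + mu / w^2
  if (naux) diag(H)[nb + seq_len(naux)] <- htt

  nR <- length(rank1) + length(cross)
  if (nR) {
    R <- matrix(0, length(dstk), nR)
    k <- 0L
    for (r1 in rank1) { k <- k + 1L; R[r1$off + seq_len(r1$n), k] <- r1$rvec }
    for (cr in cross) { k <- k + 1L; R[cr$off + seq_len(cr$n), k] <- cr$rvec }
    AtR <- as.matrix(Matrix::crossprod(st$A, R))
    k <- 0L
    for (r1 in rank1) {
      k <- k + 1L
      H[seq_len(nb), seq_len(nb)] <- H[seq_len(nb), seq_len(nb)] +
        r1$coef * tcrossprod(AtR[, k])
    }
    for (cr in cross) {
      k <- k + 1L
      j <- nb + cr$j
      H[seq_len(nb), j] <- H[seq_len(nb), j] + AtR[, k]
      H[j, seq_len(nb)] <- H[j, seq_len(nb)] + AtR[, k]
    }
  }
  for (r1 in rank1_dense) H <- H + r1$coef * tcrossprod(r1$v)

  out$grad <- grad
  out$H <- H
  out
}

# Solve H p = -g with Jacobi equilibration (for the huge dynamic range of
# barrier curvatures) and one step of iterative refinement.
chol_solve <- function(H, g) {
  dg <- diag(H)
  s <- 1 / sqrt(pmax(dg, 1e-300))
  Hs <- H * tcrossprod(s)
  for (j in 0:10) {
    R <- tryCatch(chol(Hs + diag(10^(j - 14), nrow(H))),
                  error = function(e) NULL)
    if (!is.null(R)) {
      solve_sys <- function(rhs)
        s * backsolve(R, backsolve(R, s * rhs, transpose = TRUE))
      p <- solve_sys(-g)
      r <- as.numeric(H %*% p) + g
      p <- p - solve_sys(r)
      return(p)
    }
  }
  -g / (mean(abs(dg)) + 1e-12)
}

# Largest step along p keeping every barrier slack positive (exact for the
# linear rows and w-positivity, first-order for the scalar convex terms).
step_to_boundary <- function(prob, x, p) {
  nb <- prob$nb
  naux <- prob$naux
  w <- x[seq_len(nb)]
  pw <- p[seq_len(nb)]
  taux <- if (naux) x[nb + seq_len(naux)] else numeric(0)
  pt <- if (naux) p[nb + seq_len(naux)] else numeric(0)
  amax <- Inf
  neg <- pw < 0
  if (any(neg)) amax <- min(amax, min(w[neg] / -pw[neg]))
  st <- prob$stack
  dstk <- as.numeric(st$A %*% w)
  delta <- as.numeric(st$A %*% pw)
  for (bl in st$blocks) {
    if (bl$role != "con") next
    tm <- prob$cons[[bl$idx]]
    sl <- bl$off + seq_len(bl$n)
    d <- dstk[sl]; dd <- delta[sl]
    sr <- switch(tm$type,
      vox_upper = cbind(tm$b - d, dd),
      vox_lower = cbind(d - tm$b, -dd),
      epi_upper = cbind(taux[tm$aux] - d, dd - pt[tm$aux]),
      epi_lower = cbind(d - taux[tm$aux], pt[tm$aux] - dd),
      ltcp_upper = {
        e <- clip_exp(-tm$alpha * (d - tm$pd))
        cbind(tm$b - mean(e), -sum((tm$alpha / bl$n) * e * dd))
      },
      geud_upper = {
        gp <- geud_parts(d, tm$k, tm$s0)
        cbind(tm$b - gp$val, sum(gp$gd * dd))
      })
    pos <- sr[, 2] > 0
    if (any(pos)) amax <- min(amax, min(sr[pos, 1] / sr[pos, 2]))
  }
  for (tm in prob$cons) {
    if (tm$type != "mean_upper") next
    rate <- sum(tm$a * pw)
    if (rate > 0) amax <- min(amax, (tm$b - sum(tm$a * w)) / rate)
  }
  amax
}

newton_minimize <- function(prob, x, mu, opts, stop_check = NULL) {
  status <- "maxit"
  nls <- 0L
  it <- 0L
  for (it in seq_len(opts$max_newton)) {
    e <- eval_barrier(prob, x, mu, want_deriv = TRUE)
    if (!is.finite(e$phi)) stop("barrier left the feasible domain")
    p <- chol_solve(e$H, e$grad)
    lam2 <- -sum(e$grad * p)
    if (!is.finite(lam2) || lam2 < 0) { p <- -e$grad; lam2 <- sum(e$grad^2) }
    if (lam2 / 2 <= opts$newton_tol * (1 + abs(e$phi))) {
      status <- "converged"; break
    }
    amax <- step_to_boundary(prob, x, p)
    tstep <- min(1, 0.99 * amax)
    ok <- FALSE
    for (ls in 1:60) {
      nls <- nls + 1L
      xt <- x + tstep * p
      et <- eval_barrier(prob, xt, mu, want_deriv = FALSE)
      if (is.finite(et$phi) && et$phi <= e$phi - 0.01 * tstep * lam2) {
        x <- xt; ok <- TRUE; break
      }
      tstep <- tstep / 2
    }
    if (identical(getOption("prioplan.solver_debug"), 2L))
      message(sprintf("      it %d phi %.8g f %.6g lam2 %.3g amax %.3g t %.3g",
                      it, e$phi, e$f, lam2, amax, tstep))
    if (!ok) { status <- "stalled"; break }
    if (!is.null(stop_check) && stop_check(x)) {
      status <- "sufficient"; break
    }
  }
  if (isTRUE(getOption("prioplan.solver_debug")))
    message(sprintf("    mu %.3g: %d newton, %d ls evals [%s]",
                    mu, it, nls, status))
  list(x = x, status = status)
}

count_cons <- function(prob) {
  prob$nb + sum(vapply(prob$cons, function(tm)
    if (tm$type %in% c("vox_upper", "vox_lower", "epi_upper", "epi_lower"))
      nrow(tm$A) else 1L, numeric(1)))
}

# Minimize the problem objective from a strictly feasible x0.
barrier_solve <- function(prob, x0, opts, stop_check = NULL) {
  if (is.null(prob$stack)) prob <- build_stack(prob)
  e0 <- eval_barrier(prob, x0, mu = 1e-8, want_deriv = FALSE)
  if (!is.finite(e0$phi))
    stop("barrier_solve requires a strictly feasible starting point")
  m_con <- count_cons(prob)
  mu <- (if (is.null(opts$mu_init_mult)) 1 else opts$mu_init_mult) *
    max(abs(e0$f), 1e-2) / m_con
  x <- x0
  status <- "optimal"
  f_prev <- Inf
  retries <- 0L
  fac <- opts$mu_factor
  for (stage in seq_len(200L)) {
    res <- newton_minimize(prob, x, mu, opts, stop_check)
    x <- res$x
    if (res$status == "sufficient") { status <- "sufficient"; break }
    f <- eval_barrier(prob, x, mu, want_deriv = FALSE)$f
    if (res$status == "converged") {
      # the duality-gap bound (m * mu) is only valid at centred points
      if (mu * m_con <= opts$gap_tol * (abs(f) + 1e-3)) break
      retries <- 0L
      # when the objective collapsed by orders of magnitude within one
      # stage (huge LTCP descents), let mu track it down rather than
      # walking the whole geometric ladder
      mu <- if (abs(f) < 0.1 * abs(f_prev))
        min(mu / fac, max(abs(f), 1e-3) / m_con) else mu / fac
    } else {
      # not yet centred at this mu: keep working at the same mu, giving
      # long crawls the iterations they need; give up only when repeated
      # attempts stop improving the objective
      retries <- retries + 1L
      if (retries >= 3L &&
          abs(f_prev - f) <= 1e-7 * (abs(f) + 1e-3)) {
        status <- "stalled"; break
      }
      if (retries >= opts$max_retries) { status <- "stalled"; break }
    }
    f_prev <- f
  }
  f <- eval_barrier(prob, x, mu, want_deriv = FALSE)$f
  list(x = x, f = f, status = status)
}

# ---- phase 1: strict feasibility ------------------------------------------

# Smooth-minimax feasibility search: minimize the soft maximum of the
# normalized constraint residuals, annealing the smoothing width; stops as
# soon as every residual is below -feas_margin. Only w-space constraint
# terms occur here (epigraph variables are introduced with feasible
# initial values later).
phase1_solve <- function(cons, nb, w0, opts) {
  if (length(cons) == 0L)
    return(list(w = pmax(w0, 1e-6), feasible = TRUE, max_violation = -Inf))
  w_pos_mu <- 1e-7
  ps <- build_phase1_stack(cons, nb)
  w <- pmax(w0, 1e-6)
  eps_seq <- 0.5 * 0.25^(0:7)
  g_fin <- eval_phase1(ps, w, 1, w_pos_mu, FALSE)$g_all
  for (eps in eps_seq) {
    if (max(g_fin) <= -opts$feas_margin) break
    for (it in seq_len(opts$max_newton)) {
      ev <- eval_phase1(ps, w, eps, w_pos_mu, TRUE)
      g_fin <- ev$g_all
      if (max(g_fin) <= -opts$feas_margin) break
      p <- chol_solve(ev$H, ev$grad)
      lam2 <- -sum(ev$grad * p)
      if (!is.finite(lam2) || lam2 < 0) { p <- -ev$grad; lam2 <- sum(ev$grad^2) }
      if (lam2 / 2 <= 1e-10 * (1 + abs(ev$phi))) break
      tstep <- 1
      moved <- FALSE
      for (ls in 1:60) {
        wt <- w + tstep * p
        if (all(wt > 0)) {
          evt <- eval_phase1(ps, wt, eps, w_pos_mu, FALSE)
          if (is.finite(evt$phi) &&
              evt$phi <= ev$phi - 0.01 * tstep * lam2) {
            moved <- TRUE; break
          }
        }
        tstep <- tstep / 2
      }
      if (!moved) break
      w <- wt
      g_fin <- evt$g_all
    }
  }
  list(w = w, feasible = max(g_fin) <= -opts$feas_margin / 10,
       max_violation = max(g_fin))
}

build_phase1_stack <- function(cons, nb) {
  blocks <- list()
  As <- list()
  off <- 0L
  for (i in seq_along(cons)) {
    tm <- cons[[i]]
    if (tm$type == "mean_upper") {
      blocks[[length(blocks) + 1L]] <- list(idx = i, type = tm$type,
                                            off = NA, n = 1L)
    } else {
      blocks[[length(blocks) + 1L]] <- list(idx = i, type = tm$type,
                                            off = off, n = nrow(tm$A))
      As[[length(As) + 1L]] <- tm$A
      off <- off + nrow(tm$A)
    }
  }
  list(A = if (length(As)) do.call(rbind, As) else
         Matrix::Matrix(0, 0, nb, sparse = TRUE),
       blocks = blocks, cons = cons, nb = nb)
}

eval_phase1 <- function(ps, w, eps, w_pos_mu, want_deriv) {
  nb <- ps$nb
  dstk <- as.numeric(ps$A %*% w)
  nscal <- sum(vapply(ps$blocks, function(b)
    b$type %in% c("mean_upper", "ltcp_upper", "geud_upper"), logical(1)))
  nvox <- length(dstk) -
    sum(vapply(ps$blocks, function(b)
      if (b$type %in% c("ltcp_upper", "geud_upper")) b$n else 0L, numeric(1)))
  g_all <- numeric(0)
  cache <- vector("list", length(ps$blocks))
  gi <- 0L
  g_all <- numeric(nvox + nscal)
  for (bi in seq_along(ps$blocks)) {
    bl <- ps$blocks[[bi]]
    tm <- ps$cons[[bl$idx]]
    if (bl$type == "vox_upper" || bl$type == "vox_lower") {
      d <- dstk[bl$off + seq_len(bl$n)]
      g <- if (bl$type == "vox_upper") (d - tm$b) / tm$scale
           else (tm$b - d) / tm$scale
      cache[[bi]] <- list(gpos = gi, n = bl$n)
      g_all[gi + seq_len(bl$n)] <- g
      gi <- gi + bl$n
    } else if (bl$type == "mean_upper") {
      g_all[gi + 1L] <- (sum(tm$a * w) - tm$b) / tm$scale
      cache[[bi]] <- list(gpos = gi, n = 1L)
      gi <- gi + 1L
    } else if (bl$type == "ltcp_upper") {
      d <- dstk[bl$off + seq_len(bl$n)]
      e <- clip_exp(-tm$alpha * (d - tm$pd))
      g_all[gi + 1L] <- (mean(e) - tm$b) / tm$scale
      cache[[bi]] <- list(gpos = gi, n = 1L, e = e)
      gi <- gi + 1L
    } else if (bl$type == "geud_upper") {
      d <- dstk[bl$off + seq_len(bl$n)]
      gp <- geud_parts(d, tm$k, tm$s0)
      g_all[gi + 1L] <- (gp$val - tm$b) / tm$scale
      cache[[bi]] <- list(gpos = gi, n = 1L, gp = gp)
      gi <- gi + 1L
    }
  }
  M <- max(g_all)
  wts <- exp((g_all - M) / eps)
  Z <- sum(wts)
  phi <- M + eps * log(Z) - w_pos_mu * sum(log(w))
  if (!want_deriv) return(list(phi = phi, g_all = g_all))
  p_all <- wts / Z

  vvec <- numeric(length(dstk))
  cvec <- numeric(length(dstk))
  rank1 <- list()        # stacked rank-1: coef, rvec over slice
  rank1_dense <- list()  # coef, v (length nb)
  for (bi in seq_along(ps$blocks)) {
    bl <- ps$blocks[[bi]]
    tm <- ps$cons[[bl$idx]]
    ch <- cache[[bi]]
    if (bl$type %in% c("vox_upper", "vox_lower")) {
      sl <- bl$off + seq_len(bl$n)
      p <- p_all[ch$gpos + seq_len(bl$n)]
      sgn <- if (bl$type == "vox_upper") 1 else -1
      vvec[sl] <- vvec[sl] + sgn * p / tm$scale
      cvec[sl] <- cvec[sl] + (p / tm$scale^2) / eps
    } else if (bl$type == "mean_upper") {
      p <- p_all[ch$gpos + 1L]
      rank1_dense[[length(rank1_dense) + 1L]] <-
        list(coef = p / eps, v = tm$a / tm$scale, gcoef = p)
    } else if (bl$type == "ltcp_upper") {
      sl <- bl$off + seq_len(bl$n)
      p <- p_all[ch$gpos + 1L]
      m <- bl$n
      gd <- -(tm$alpha / m) * ch$e / tm$scale
      vvec[sl] <- vvec[sl] + p * gd
      cvec[sl] <- cvec[sl] + p * (tm$alpha^2 / m) * ch$e / tm$scale
      rank1[[length(rank1) + 1L]] <-
        list(coef = p / eps, rvec = gd, off = bl$off, n = bl$n)
    } else if (bl$type == "geud_upper") {
      sl <- bl$off + seq_len(bl$n)
      p <- p_all[ch$gpos + 1L]
      gp <- ch$gp
      vvec[sl] <- vvec[sl] + p * gp$gd / tm$scale
      cvec[sl] <- cvec[sl] + p * gp$dd / tm$scale
      rank1[[length(rank1) + 1L]] <-
        list(coef = p * gp$qcoef / tm$scale, rvec = gp$q,
             off = bl$off, n = bl$n)
      rank1[[length(rank1) + 1L]] <-
        list(coef = p / eps, rvec = gp$gd / tm$scale,
             off = bl$off, n = bl$n)
    }
  }

  u <- at_v(ps$A, vvec)
  grad <- u - w_pos_mu / w
  for (r1 in rank1_dense) grad <- grad + r1$gcoef * r1$v
  H <- as.matrix(atda(ps$A, cvec))
  diag(H) <- diag(H) + w_pos_mu / w^2
  if (length(rank1)) {
    R <- matrix(0, length(dstk), length(rank1))
    for (k in seq_along(rank1))
      R[rank1[[k]]$off + seq_len(rank1[[k]]$n), k] <- rank1[[k]]$rvec
    AtR <- as.matrix(Matrix::crossprod(ps$A, R))
    for (k in seq_along(rank1))
      H <- H + rank1[[k]]$coef * tcrossprod(AtR[, k])
  }
  u_full <- u
  for (r1 in rank1_dense) {
    H <- H + r1$coef * tcrossprod(r1$v)
    u_full <- u_full + r1$gcoef * r1$v
  }
  H <- H - tcrossprod(u_full) / eps
  H <- H + diag(1e-9 * (mean(abs(diag(H))) + 1), nb)
  list(phi = phi, grad = grad, H = H, g_all = g_all)
}
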