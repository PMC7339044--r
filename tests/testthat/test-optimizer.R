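# Lexicographic solver correctness on micro instances where a refining
# grid-search oracle is tractable (<= 4 beamlets, <= 20 voxels).

test_that("a single linear objective with a dose floor matches the oracle", {
  A <- Matrix(c(1, 0.5,
                0.2, 1,
                0.6, 0.6), 3, 2, byrow = TRUE, sparse = TRUE)
  dij <- micro_dij(A)
  ss <- micro_structs(3, list(all = 1:3, v1 = 1))
  wl <- wishlist(prescription(),
                 list(hard_constraint("v1", "min_dose", 10)),
                 list(planning_objective(1, "all", "mean_dose", goal = 0)),
                 name = "micro-lp")
  pl <- lexicographic_solve(wl, dij, ss, oracle_opts())
  # analytic optimum: all weight on beamlet 1, w = (10, 0), mean dose 6
  expect_true(pl$feasible)
  expect_equal(pl$trace$attained, 6, tolerance = 1e-4)
  orc <- oracle_lexicographic(
    A, cons = list(function(d) 10 - d[1]),
    objs = list(list(fun = mean, sufficient = 0)), wmax = 25)
  expect_equal(pl$trace$attained, orc$attained, tolerance = 1e-4)
})

test_that("two-priority solves match the oracle on every attained value", {
  set.seed(5)
  A <- Matrix(matrix(runif(12, 0.1, 1), 6, 2), sparse = TRUE)
  dij <- micro_dij(A)
  ss <- micro_structs(6, list(tgt = 1:3, oar = 4:6, hot = 2))
  wl <- wishlist(
    prescription(),
    list(hard_constraint("tgt", "min_dose", 8),
         hard_constraint("hot", "max_dose", 30)),
    list(planning_objective(1, "oar", "mean_dose", goal = 0),
         planning_objective(2, "tgt", "mean_dose", goal = 0)),
    name = "micro-2p")
  pl <- lexicographic_solve(wl, dij, ss, oracle_opts())
  expect_true(pl$feasible)
  orc <- oracle_lexicographic(
    A,
    cons = list(function(d) 8 - min(d[1:3]), function(d) d[2] - 30),
    objs = list(list(fun = function(d) mean(d[4:6]), sufficient = 0),
                list(fun = function(d) mean(d[1:3]), sufficient = 0)),
    wmax = 40)
  expect_equal(pl$trace$attained, orc$attained, tolerance = 1e-4)
})

test_that("LTCP and gEUD objectives match the oracle", {
  set.seed(9)
  A <- Matrix(matrix(runif(16, 0.1, 1), 8, 2), sparse = TRUE)
  dij <- micro_dij(A)
  ss <- micro_structs(8, list(tgt = 1:4, oar = 5:8))
  pd <- 20
  wl <- wishlist(
    prescription(),
    list(hard_constraint("oar", "max_dose", 18)),
    list(planning_objective(1, "tgt", "ltcp", goal = 0.5, pd = pd,
                            alpha = 0.5),
         planning_objective(2, "oar", "geud", goal = 0, k = 7.7)),
    name = "micro-nl")
  pl <- lexicographic_solve(wl, dij, ss, oracle_opts())
  expect_true(pl$feasible)
  orc <- oracle_lexicographic(
    A,
    cons = list(function(d) max(d[5:8]) - 18),
    objs = list(list(fun = function(d) mean(exp(-0.5 * (d[1:4] - pd))),
                     sufficient = 0.5),
                list(fun = function(d) geud(d[5:8], 7.7), sufficient = 0)),
    wmax = 60)
  expect_lt(max(abs(pl$trace$attained - orc$attained) /
                  pmax(1, abs(orc$attained))), 1e-3)
})

test_that("later priorities never degrade earlier attained values", {
  set.seed(13)
  A <- Matrix(matrix(runif(20, 0.05, 1), 10, 2), sparse = TRUE)
  dij <- micro_dij(A)
  ss <- micro_structs(10, list(a = 1:4, b = 5:7, c = 8:10))
  wl <- wishlist(
    prescription(),
    list(hard_constraint("a", "min_dose", 5)),
    list(planning_objective(1, "b", "mean_dose", goal = 0),
         planning_objective(2, "c", "mean_dose", goal = 0),
         planning_objective(3, "a", "mean_dose", goal = 0)),
    name = "micro-3p")
  pl <- lexicographic_solve(wl, dij, ss, oracle_opts())
  expect_true(pl$feasible)
  # re-evaluate each converted objective at the final dose: it must hold
  # its bound (the lexicographic contract)
  for (i in seq_len(nrow(pl$trace))) {
    val <- switch(pl$trace$structure[i], a = mean(pl$dose[1:4]),
                  b = mean(pl$dose[5:7]), c = mean(pl$dose[8:10]))
    expect_lte(val, pl$trace$bound[i] + 1e-8)
  }
})

test_that("equal priorities are solved jointly and order-independently", {
  set.seed(17)
  A <- Matrix(matrix(runif(12, 0.1, 1), 6, 2), sparse = TRUE)
  dij <- micro_dij(A)
  ss <- micro_structs(6, list(tgt = 1:2, o1 = 3:4, o2 = 5:6))
  mk <- function(swap) {
    objs <- list(planning_objective(1, "tgt", "min_dose", goal = 12),
                 planning_objective(2, "o1", "mean_dose", goal = 0),
                 planning_objective(2, "o2", "mean_dose", goal = 0))
    if (swap) objs <- objs[c(1, 3, 2)]
    wishlist(prescription(), list(hard_constraint("tgt", "min_dose", 6)),
             objs, name = "micro-tie")
  }
  p1 <- lexicographic_solve(mk(FALSE), dij, ss, oracle_opts())
  p2 <- lexicographic_solve(mk(TRUE), dij, ss, oracle_opts())
  expect_true(p1$feasible && p2$feasible)
  # the priority-1 attained value is unaffected by the tie order
  expect_equal(p1$trace$attained[1], p2$trace$attained[1],
               tolerance = 1e-5)
  # and the joint tie solution itself is order-independent
  expect_equal(sort(p1$trace$attained[-1]), sort(p2$trace$attained[-1]),
               tolerance = 1e-4)
})

test_that("solves are deterministic", {
  set.seed(21)
  A <- Matrix(matrix(runif(12, 0.1, 1), 6, 2), sparse = TRUE)
  dij <- micro_dij(A)
  ss <- micro_structs(6, list(tgt = 1:3, oar = 4:6))
  wl <- wishlist(prescription(),
                 list(hard_constraint("tgt", "min_dose", 7)),
                 list(planning_objective(1, "oar", "mean_dose", goal = 0)),
                 name = "micro-det")
  p1 <- lexicographic_solve(wl, dij, ss, oracle_opts())
  p2 <- lexicographic_solve(wl, dij, ss, oracle_opts())
  expect_identical(p1$weights, p2$weights)
  expect_identical(p1$trace, p2$trace)
})

test_that("contradictory constraints produce a structured report", {
  A <- Matrix(diag(2), sparse = TRUE)
  dij <- micro_dij(A)
  ss <- micro_structs(2, list(v = 1:2))
  wl <- wishlist(prescription(),
                 list(hard_constraint("v", "min_dose", 20),
                      hard_constraint("v", "max_dose", 10)),
                 list(planning_objective(1, "v", "mean_dose", goal = 0)),
                 name = "micro-inf")
  pl <- lexicographic_solve(wl, dij, ss, oracle_opts())
  expect_false(pl$feasible)
  expect_s3_class(pl$infeasibility, "infeasibility_report")
  blocking <- paste(pl$infeasibility$blocking, collapse = " ")
  expect_match(blocking, "min_dose")
  expect_match(blocking, "max_dose")
  expect_true(length(pl$infeasibility$relaxed) >= 1)
})

test_that("check_plan flags exactly the violated constraint", {
  set.seed(2)
  A <- Matrix(matrix(runif(12, 0.1, 1), 6, 2), sparse = TRUE)
  dij <- micro_dij(A)
  ss <- micro_structs(6, list(tgt = 1:3, oar = 4:6))
  wl <- wishlist(prescription(),
                 list(hard_constraint("tgt", "min_dose", 7),
                      hard_constraint("oar", "max_dose", 25)),
                 list(planning_objective(1, "oar", "mean_dose", goal = 0)),
                 name = "micro-chk")
  pl <- lexicographic_solve(wl, dij, ss, oracle_opts())
  rep1 <- check_plan(pl, wl, ss)
  expect_true(all(rep1$satisfied[rep1$role == "constraint"]))
  # report values agree with direct evaluation
  expect_equal(rep1$value[rep1$role == "objective"], mean(pl$dose[4:6]),
               tolerance = 1e-10)

  # break the dose floor by scaling the weights down
  bad <- pl
  bad$weights <- pl$weights * 0.5
  bad$dose <- pl$dose * 0.5
  rep2 <- check_plan(bad, wl, ss)
  cons_rows <- rep2$role == "constraint"
  viol <- cons_rows & !rep2$satisfied
  expect_equal(rep2$kind[viol], "min_dose")
})
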