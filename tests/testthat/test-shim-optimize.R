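## shared random brain-geometry problem: 60 voxels on a realistic scale
mkProblem8 <- function(lambda = 0.03, sd = 0, lb = -1000, ub = 1000,
                       seed = 5) {
  set.seed(seed)
  coords <- cbind(runif(60, -50, 50), runif(60, -40, 60),
                  runif(60, -40, 40))
  A <- evaluateBasis(coords)
  sTrue <- c(35, -25, 15, 50, -30, 20, 45, -35)
  b <- drop(A %*% sTrue) + rnorm(60, 0, sd)
  list(problem = shimProblemMatrices(A, b, lambda = lambda, lb = lb,
                                     ub = ub, terms = colnames(A)),
       sTrue = sTrue)
}

test_that("an exactly representable field is recovered with zero residual", {
  p <- mkProblem8(lambda = 0, sd = 0)
  sol <- solveLocalized(p$problem)
  expect_equal(unname(shimCoefficients(sol)), p$sTrue, tolerance = 1e-9)
  resid <- p$problem@A %*% shimCoefficients(sol) - p$problem@b
  expect_lt(sd(resid), 1e-9)
})

test_that("the bounds-inactive ridge solution equals the normal equations", {
  p <- mkProblem8(lambda = 0.03, sd = 3)
  sol <- solveLocalized(p$problem)
  A <- p$problem@A
  d <- sqrt(colMeans(A^2))
  closed <- solve(crossprod(A) + 0.03 * diag(d^2),
                  crossprod(A, p$problem@b))
  expect_equal(unname(shimCoefficients(sol)), unname(drop(closed)),
               tolerance = 1e-8)
  expect_equal(length(sol@activeBounds), 0L)
})

test_that("a one-term problem clips at the bound found by grid search", {
  A <- matrix(seq(0.5, 1.5, length.out = 12), ncol = 1)
  b <- drop(A * 30)  # unconstrained optimum 30, above ub = 20
  pr <- shimProblemMatrices(A, b, lambda = 0, lb = -20, ub = 20)
  sol <- solveLocalized(pr)
  expect_equal(unname(shimCoefficients(sol)), 20, tolerance = 1e-9)
  expect_equal(sol@activeBounds, "c1")
  ## 1-D grid oracle agrees
  orc <- qpOracle(pr, gridPoints = 4001L)
  expect_equal(unname(orc$s), 20, tolerance = 0.02)
})

test_that("the constrained solver matches the zoomed QP oracle on toys", {
  pr <- toyProblem2()
  sol <- solveConstrained(pr)
  orc <- qpOracle(pr, gridPoints = 401L, refine = 5L)
  expect_true(orc$feasible)
  expect_equal(unname(shimCoefficients(sol)), unname(orc$s),
               tolerance = 1e-4)
  ## convexity: the oracle can never beat the QP
  expect_gt(orc$objective, sol@objective - 1e-6)
  expect_lte(sol@objective, orc$objective + 1e-6)
})

test_that("inactive fat constraints reproduce the localized solution", {
  p <- mkProblem8(lambda = 0.03, sd = 2)
  sL <- solveLocalized(p$problem)
  ## constraints built far outside the residual range
  C <- p$problem@A[1:10, ]
  bFat <- drop(C %*% p$sTrue)
  pr <- shimProblemMatrices(p$problem@A, p$problem@b, lambda = 0.03,
                            C = C, bFat = bFat, d1 = -500, d2 = 500,
                            terms = p$problem@terms)
  sC <- solveConstrained(pr)
  expect_equal(shimCoefficients(sC), shimCoefficients(sL),
               tolerance = 1e-8)
  expect_true(sC@feasible)
})

test_that("regularization shrinks monotonically and constraints cost objective", {
  p1 <- mkProblem8(lambda = 0.01, sd = 5)
  p2 <- mkProblem8(lambda = 1, sd = 5)
  d <- sqrt(colMeans(p1$problem@A^2))
  n1 <- sum((d * shimCoefficients(solveLocalized(p1$problem)))^2)
  n2 <- sum((d * shimCoefficients(solveLocalized(p2$problem)))^2)
  expect_gte(n1, n2)
  ## binding constraints can only raise the objective
  pr <- toyProblem2()
  solL <- solveLocalized(pr)
  solC <- solveConstrained(pr)
  expect_gte(solC@objective, solL@objective - 1e-9)
})

test_that("returned constrained solutions certify feasibility", {
  pr <- toyProblem2()
  sol <- solveConstrained(pr)
  r <- pr@bFat - drop(pr@Cfat %*% shimCoefficients(sol))
  expect_true(all(r >= pr@d1 - 1e-6 & r <= pr@d2 + 1e-6))
  expect_true(sol@feasible)
})

test_that("infeasible bands follow the chosen policy", {
  ## two fat voxels demanding incompatible responses: same row, bands
  ## forced apart further than the row span allows
  A <- matrix(c(1, 0.5), ncol = 1)
  C <- matrix(c(1, 1), ncol = 1)
  pr <- shimProblemMatrices(A, c(0, 0), lambda = 0, lb = -400, ub = 400,
                            C = C, bFat = c(0, 300), d1 = -20, d2 = 20)
  expect_error(solveConstrained(pr, infeasiblePolicy = "strict"),
               "infeasible")
  sol <- suppressWarnings(solveConstrained(pr, infeasiblePolicy = "relax"))
  expect_false(sol@feasible)
  expect_match(sol@solverReport, "widened")
  ## minimal symmetric widening: 300 apart, band 40 wide -> eps = 130
  eps <- as.numeric(sub(".*widened by ([0-9.]+) Hz.*", "\\1",
                        sol@solverReport))
  expect_equal(eps, 130, tolerance = 0.01)
  ## the oracle reports the empty feasible set
  orc <- qpOracle(pr, gridPoints = 501L)
  expect_false(orc$feasible)
})

test_that("the oracle refuses high-dimensional problems and rank issues warn", {
  p <- mkProblem8()
  expect_error(qpOracle(p$problem), "refuses")
  Adef <- cbind(1:6, (1:6) * 2)  # rank 1
  prd <- shimProblemMatrices(Adef, rnorm(6), lambda = 0.03)
  expect_warning(solveLocalized(prd), "rank-deficient")
})

test_that("recovery error decays with the injected field noise", {
  rmse <- vapply(c(0, 1, 5), function(sdn) {
    p <- mkProblem8(lambda = 0, sd = sdn, seed = 17)
    sqrt(mean((shimCoefficients(solveLocalized(p$problem)) - p$sTrue)^2))
  }, 0)
  expect_lt(rmse[1], 1e-9)
  expect_true(all(diff(rmse) > 0))
  ## roughly linear in sigma
  expect_equal(rmse[3] / rmse[2], 5, tolerance = 0.2)
})
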