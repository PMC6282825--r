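## Localized (L-IB) and fat-constrained (FC-IB) shim solvers.
##
## Both minimize ||A s - b||^2 + lambda ||D s||^2 subject to lb <= s <= ub,
## where D scales each coefficient by the RMS of its design column over the
## brain ROI so that lambda is dimensionless and meaningful regardless of
## coefficient units. The fat-constrained variant adds the per-voxel band
## d1 <= bFat - C s <= d2 that keeps the residual frequency at every fat
## voxel inside the effective range of the fat-saturation pulse. The sign
## convention is A s ~ field, residual = field - A s; hardware must apply
## the negated coefficients.

#' Assemble a shim problem from field map and masks
#'
#' Collects the brain design matrix and field values (restricted to valid
#' voxels), the optional fat constraint matrix, the Tikhonov weight and
#' the hardware bounds into a \linkS4class{ShimProblem}.
#'
#' @param fm unwrapped \linkS4class{FieldMap}
#' @param brainMask \linkS4class{RegionMask} of the fetal brain ROI
#' @param basis \linkS4class{ShimBasis}
#' @param lambda Tikhonov weight; default 0.03
#' @param limits \linkS4class{ShimLimits}; defaults are wide placeholders
#' @param fatMask optional \linkS4class{RegionMask} of the fat region
#' @param d1,d2 fat residual band (Hz); defaults -350 and 100, the
#'   95-percent saturation band of the optimized SPIR pulse expressed as
#'   fat-frequency deviation (see \code{\link{spirFatConstraints}})
#' @param fatStride keep every k-th fat voxel; default 1
#' @return a \linkS4class{ShimProblem}
#' @export
shimProblem <- function(fm, brainMask, basis = shimBasis(), lambda = 0.03,
                        limits = shimLimits(), fatMask = NULL,
                        d1 = -350, d2 = 100, fatStride = 1L) {
  stopifnot(is(fm, "FieldMap"), is(brainMask, "RegionMask"))
  .stopGeometry(fm, brainMask, what = "field map and brain mask")
  useMask <- regionMask(brainMask@mask & fm@valid, brainMask@label,
                        brainMask@spacing, brainMask@origin)
  if (!any(useMask@mask))
    stop("brain ROI contains no valid field-map voxels", call. = FALSE)
  A <- buildDesignMatrix(useMask, basis)
  b <- fm@freq[A@voxelIndex]
  if (length(b) < length(basis@terms))
    warning("fewer brain voxels than shim terms: fit may be ill-conditioned",
            call. = FALSE)
  Cm <- matrix(0, 0, length(basis@terms))
  bFat <- numeric(0)
  if (!is.null(fatMask)) {
    .stopGeometry(fm, fatMask, what = "field map and fat mask")
    fUse <- regionMask(fatMask@mask & fm@valid, fatMask@label,
                       fatMask@spacing, fatMask@origin)
    Cd <- buildDesignMatrix(fUse, basis, stride = fatStride,
                            onEmpty = "vacuous")
    Cm <- Cd@values
    bFat <- fm@freq[Cd@voxelIndex]
  }
  new("ShimProblem", A = A@values, b = b, lambda = as.numeric(lambda),
      lb = limits@lb, ub = limits@ub, Cfat = Cm, bFat = bFat,
      d1 = as.numeric(d1), d2 = as.numeric(d2), terms = basis@terms)
}

#' Assemble a shim problem from raw matrices
#'
#' Low-level constructor used for toy problems and tests; the high-level
#' interface is \code{\link{shimProblem}}.
#'
#' @param A brain design matrix
#' @param b brain field values (Hz)
#' @param lambda Tikhonov weight
#' @param lb,ub coefficient bounds (recycled)
#' @param C fat constraint matrix (may have 0 rows)
#' @param bFat fat field values (Hz)
#' @param d1,d2 fat residual band (Hz)
#' @param terms optional column labels
#' @return a \linkS4class{ShimProblem}
#' @export
shimProblemMatrices <- function(A, b, lambda = 0.03, lb = -1000, ub = 1000,
                                C = NULL, bFat = numeric(0),
                                d1 = -350, d2 = 100, terms = NULL) {
  A <- as.matrix(A)
  p <- ncol(A)
  if (is.null(C)) C <- matrix(0, 0, p)
  if (is.null(terms))
    terms <- if (p == 8L) SHIM_TERMS else paste0("c", seq_len(p))
  new("ShimProblem", A = A, b = as.numeric(b), lambda = as.numeric(lambda),
      lb = rep_len(as.numeric(lb), p), ub = rep_len(as.numeric(ub), p),
      Cfat = as.matrix(C), bFat = as.numeric(bFat),
      d1 = as.numeric(d1), d2 = as.numeric(d2), terms = terms)
}

## column-RMS normalization weights for the Tikhonov term
.tikhonovWeights <- function(A) {
  d <- sqrt(colMeans(A^2))
  d[d == 0 | !is.finite(d)] <- 1
  d
}

.shimObjective <- function(problem, s) {
  d <- .tikhonovWeights(problem@A)
  sum((problem@A %*% s - problem@b)^2) + problem@lambda * sum((d * s)^2)
}

## constraint rows in quadprog's form t(Amat) %*% s >= bvec
.constraintRows <- function(problem, withFat, d1 = problem@d1,
                            d2 = problem@d2) {
  p <- ncol(problem@A)
  Amat <- matrix(0, p, 0); bvec <- numeric(0)
  finLo <- is.finite(problem@lb); finHi <- is.finite(problem@ub)
  if (any(finLo)) {
    Amat <- cbind(Amat, diag(p)[, finLo, drop = FALSE])
    bvec <- c(bvec, problem@lb[finLo])
  }
  if (any(finHi)) {
    Amat <- cbind(Amat, -diag(p)[, finHi, drop = FALSE])
    bvec <- c(bvec, -problem@ub[finHi])
  }
  if (withFat && nrow(problem@Cfat) > 0L) {
    ## d1 <= bFat - C s  <=>  -C s >= d1 - bFat
    ## bFat - C s <= d2  <=>   C s >= bFat - d2
    Amat <- cbind(Amat, -t(problem@Cfat), t(problem@Cfat))
    bvec <- c(bvec, d1 - problem@bFat, problem@bFat - d2)
  }
  list(Amat = Amat, bvec = bvec)
}

.solveQP <- function(problem, withFat, d1 = problem@d1, d2 = problem@d2) {
  d <- .tikhonovWeights(problem@A)
  H <- crossprod(problem@A) + problem@lambda * diag(d^2, ncol(problem@A))
  rank <- qr(problem@A)$rank
  if (rank < ncol(problem@A)) {
    warning("rank-deficient design matrix; Tikhonov term ensures a unique ",
            "solution", call. = FALSE)
    if (problem@lambda == 0)
      H <- H + diag(1e-10 * max(diag(H)), ncol(H))
  }
  g <- drop(crossprod(problem@A, problem@b))
  cons <- .constraintRows(problem, withFat, d1, d2)
  if (ncol(cons$Amat) == 0L)
    return(list(s = solve(H, g), status = "unconstrained"))
  sol <- quadprog::solve.QP(Dmat = 2 * H, dvec = 2 * g,
                            Amat = cons$Amat, bvec = cons$bvec)
  list(s = sol$solution, status = "qp",
       nActive = length(sol$iact[sol$iact > 0]))
}

.makeSolution <- function(problem, s, report, tol = 1e-6) {
  s <- pmin(pmax(s, problem@lb), problem@ub)  # clip float dust at bounds
  names(s) <- problem@terms
  atLo <- abs(s - problem@lb) < tol & is.finite(problem@lb)
  atHi <- abs(s - problem@ub) < tol & is.finite(problem@ub)
  feasible <- TRUE
  nActiveFat <- 0L
  if (nrow(problem@Cfat) > 0L) {
    r <- problem@bFat - drop(problem@Cfat %*% s)
    feasible <- all(r >= problem@d1 - tol & r <= problem@d2 + tol)
    nActiveFat <- sum(abs(r - problem@d1) < tol | abs(r - problem@d2) < tol)
  }
  new("ShimSolution", s = s, objective = .shimObjective(problem, s),
      feasible = feasible,
      activeBounds = problem@terms[atLo | atHi],
      activeFatVoxels = as.integer(nActiveFat), solverReport = report)
}

#' Solve the localized (L-IB) shim problem
#'
#' Minimizes the regularized brain-ROI misfit subject only to the hardware
#' coefficient bounds. When no bound is active this equals the closed-form
#' ridge solution of the normal equations.
#'
#' @param problem a \linkS4class{ShimProblem} (fat constraints, if present,
#'   are ignored here)
#' @return a \linkS4class{ShimSolution}
#' @export
solveLocalized <- function(problem) {
  stopifnot(is(problem, "ShimProblem"))
  if (nrow(problem@A) == 0L) stop("empty brain ROI", call. = FALSE)
  res <- .solveQP(problem, withFat = FALSE)
  .makeSolution(problem, res$s, paste0("localized (", res$status, ")"))
}

#' Solve the fat-constrained (FC-IB) shim problem
#'
#' Same objective as \code{\link{solveLocalized}} plus the per-fat-voxel
#' band constraints d1 <= bFat - C s <= d2. If the band is infeasible
#' within the hardware bounds, behavior follows \code{infeasiblePolicy}:
#' \code{"relax"} (default) widens the band symmetrically by the minimal
#' epsilon (found by bisection) and reports it; \code{"strict"} raises an
#' error listing the most-violated voxels.
#'
#' @param problem a \linkS4class{ShimProblem} with a fat constraint matrix;
#'   with an empty fat region the localized solution is returned with a
#'   note
#' @param infeasiblePolicy \code{"relax"} or \code{"strict"}
#' @return a \linkS4class{ShimSolution}
#' @export
solveConstrained <- function(problem,
                             infeasiblePolicy = c("relax", "strict")) {
  stopifnot(is(problem, "ShimProblem"))
  infeasiblePolicy <- match.arg(infeasiblePolicy)
  if (nrow(problem@A) == 0L) stop("empty brain ROI", call. = FALSE)
  if (nrow(problem@Cfat) == 0L) {
    sol <- solveLocalized(problem)
    sol@solverReport <- "constrained: empty fat region, localized fallback"
    return(sol)
  }
  res <- tryCatch(.solveQP(problem, withFat = TRUE), error = identity)
  if (!inherits(res, "error"))
    return(.makeSolution(problem, res$s, "constrained (qp)"))
  if (!grepl("constraints are inconsistent", conditionMessage(res)))
    stop(res)
  ## infeasible band
  sL <- solveLocalized(problem)@s
  rL <- problem@bFat - drop(problem@Cfat %*% sL)
  viol <- pmax(problem@d1 - rL, rL - problem@d2, 0)
  if (infeasiblePolicy == "strict") {
    worst <- order(viol, decreasing = TRUE)[seq_len(min(5L, sum(viol > 0)))]
    stop("fat constraints infeasible; most-violated voxels (Hz): ",
         paste(sprintf("#%d: %.1f", worst, viol[worst]), collapse = ", "),
         call. = FALSE)
  }
  ## minimal symmetric widening by bisection on epsilon
  lo <- 0; hi <- max(viol) + 1e-6
  feasAt <- function(eps)
    !inherits(tryCatch(.solveQP(problem, TRUE, problem@d1 - eps,
                                problem@d2 + eps),
                       error = identity), "error")
  if (!feasAt(hi)) hi <- 2 * hi + 100  # pathological bounds; widen further
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    if (feasAt(mid)) hi <- mid else lo <- mid
  }
  eps <- hi * (1 + 1e-9) + 1e-9
  res <- .solveQP(problem, TRUE, problem@d1 - eps, problem@d2 + eps)
  sol <- .makeSolution(problem, res$s,
                       sprintf("constrained (qp, band widened by %.3f Hz)",
                               eps))
  sol@feasible <- FALSE  # relative to the original band
  sol
}

#' Exhaustive grid-search oracle for small shim problems
#'
#' Global minimizer of the shim objective over a dense grid of the feasible
#' box, for problems with at most 3 coefficients. Test-only reference: it
#' is independent of the QP path and refuses larger problems.
#'
#' @param problem a \linkS4class{ShimProblem} with <= 3 coefficients and
#'   finite bounds
#' @param gridPoints grid resolution per axis; default 201 (capped at 101
#'   for 3 coefficients)
#' @param refine number of zoom rounds: after each pass the box shrinks to
#'   a few grid steps around the incumbent, so accuracy improves
#'   geometrically while each pass stays dense. Default 1 (single pass
#'   over the full feasible box).
#' @return list with \code{s} (best feasible grid point, NA if the
#'   feasible set is empty), \code{objective}, and \code{feasible}
#' @export
qpOracle <- function(problem, gridPoints = 201L, refine = 1L) {
  stopifnot(is(problem, "ShimProblem"))
  p <- ncol(problem@A)
  if (p > 3L)
    stop("qpOracle refuses problems with more than 3 free coefficients",
         call. = FALSE)
  stopifnot(all(is.finite(problem@lb)), all(is.finite(problem@ub)))
  if (p == 3L) gridPoints <- min(gridPoints, 101L)
  d <- .tikhonovWeights(problem@A)
  onePass <- function(lo, hi) {
    axes <- lapply(seq_len(p), function(j)
      seq(lo[j], hi[j], length.out = gridPoints))
    grid <- as.matrix(expand.grid(axes))
    obj <- colSums((tcrossprod(problem@A, grid) - problem@b)^2) +
      problem@lambda * colSums((d * t(grid))^2)
    ok <- rep(TRUE, nrow(grid))
    if (nrow(problem@Cfat) > 0L) {
      r <- matrix(problem@bFat, nrow(problem@Cfat), nrow(grid)) -
        tcrossprod(problem@Cfat, grid)
      ok <- colSums(r < problem@d1 | r > problem@d2) == 0L
    }
    if (!any(ok)) return(NULL)
    obj[!ok] <- Inf
    best <- which.min(obj)
    list(s = grid[best, ], objective = obj[best])
  }
  lo <- problem@lb; hi <- problem@ub
  best <- NULL
  for (round in seq_len(max(1L, refine))) {
    res <- onePass(lo, hi)
    if (is.null(res)) break
    if (is.null(best) || res$objective <= best$objective) best <- res
    step <- (hi - lo) / (gridPoints - 1)
    lo <- pmax(problem@lb, best$s - 3 * step)
    hi <- pmin(problem@ub, best$s + 3 * step)
  }
  if (is.null(best))
    return(list(s = rep(NA_real_, p), objective = NA_real_,
                feasible = FALSE))
  list(s = stats::setNames(best$s, problem@terms),
       objective = best$objective, feasible = TRUE)
}
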