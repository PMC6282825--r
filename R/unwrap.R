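## Goldstein branch-cut phase unwrapping, slice by slice.
##
## A residue is a 2x2 loop of wrapped phase differences that fails to close
## (loop integral +-2*pi). Unwrapping by integration is path-independent only
## if no path encircles a net residue charge, so residues of opposite sign
## are paired (or tied to the grid border) by branch cuts that integration
## paths may not cross.

.wrapToPi <- function(x) x - 2 * pi * round(x / (2 * pi))

## residue charges at the corners of a phase matrix; corners touching
## invalid pixels are ignored (invalid pixels already block integration)
.residueCharges <- function(p, valid) {
  n1 <- nrow(p); n2 <- ncol(p)
  if (n1 < 2L || n2 < 2L)
    return(matrix(0L, max(n1 - 1L, 0L), max(n2 - 1L, 0L)))
  a <- p[-n1, -n2]; b <- p[-1, -n2]; c <- p[-1, -1]; d <- p[-n1, -1]
  s <- .wrapToPi(b - a) + .wrapToPi(c - b) + .wrapToPi(d - c) + .wrapToPi(a - d)
  q <- matrix(as.integer(round(s / (2 * pi))), n1 - 1L, n2 - 1L)
  ok <- valid[-n1, -n2] & valid[-1, -n2] & valid[-1, -1] & valid[-n1, -1]
  q[!ok] <- 0L
  q
}

## walk the dual lattice from corner (ai,aj) towards (bi,bj) (L-shaped path,
## i first), blocking each primal edge crossed; a path may run off the grid
## border (bi/bj outside 1..n-1) to discharge a residue at the boundary
## cuts$I[i, j] blocks the pixel edge (i,j)-(i+1,j); cuts$J[i, j] blocks
## (i,j)-(i,j+1). A dual step along i crosses a J-type edge and vice versa:
## (i,j)->(i+1,j) crosses the edge between pixels (i+1,j) and (i+1,j+1).
.placeCut <- function(cuts, ai, aj, bi, bj) {
  i <- ai; j <- aj
  while (i != bi) {
    if (bi > i) { cuts$J[i + 1L, j] <- TRUE; i <- i + 1L }
    else        { cuts$J[i,      j] <- TRUE; i <- i - 1L }
  }
  while (j != bj) {
    if (bj > j) { cuts$I[i, j + 1L] <- TRUE; j <- j + 1L }
    else        { cuts$I[i, j     ] <- TRUE; j <- j - 1L }
  }
  cuts
}

.makeCuts <- function(q, n1, n2) {
  cuts <- list(I = matrix(FALSE, max(n1 - 1L, 1L), n2),
               J = matrix(FALSE, n1, max(n2 - 1L, 1L)))
  idx <- which(q != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(cuts)
  charge <- q[idx]
  open <- rep(TRUE, nrow(idx))
  for (k in seq_len(nrow(idx))) {
    if (!open[k]) next
    ai <- idx[k, 1]; aj <- idx[k, 2]
    ## distance to nearest grid border of the dual lattice
    dBorder <- min(ai, aj, (n1 - 1L) - ai + 1L, (n2 - 1L) - aj + 1L)
    opp <- which(open & charge == -charge[k] & seq_along(open) != k)
    if (length(opp)) {
      dOpp <- abs(idx[opp, 1] - ai) + abs(idx[opp, 2] - aj)
      m <- which.min(dOpp)
      if (dOpp[m] <= dBorder) {
        bi <- idx[opp[m], 1]; bj <- idx[opp[m], 2]
        cuts <- .placeCut(cuts, ai, aj, bi, bj)
        open[k] <- open[opp[m]] <- FALSE
        next
      }
    }
    ## tie to the nearest border
    dists <- c(ai, aj, (n1 - 1L) - ai + 1L, (n2 - 1L) - aj + 1L)
    side <- which.min(dists)
    bi <- ai; bj <- aj
    if (side == 1L) bi <- 0L
    else if (side == 2L) bj <- 0L
    else if (side == 3L) bi <- n1
    else bj <- n2
    cuts <- .placeCut(cuts, ai, aj, bi, bj)
    open[k] <- FALSE
  }
  cuts
}

## flood-fill integration of wrapped phase differences, not crossing cuts
## or invalid pixels; each connected component keeps its own 2*pi constant
.integrateSlice <- function(p, valid, cuts) {
  n1 <- nrow(p); n2 <- ncol(p)
  u <- matrix(NA_real_, n1, n2)
  reached <- matrix(FALSE, n1, n2)
  queue <- integer(n1 * n2)
  for (seed in which(valid & !reached)) {
    if (reached[seed]) next
    u[seed] <- p[seed]
    reached[seed] <- TRUE
    queue[1L] <- seed
    head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      i <- (cur - 1L) %% n1 + 1L
      j <- (cur - 1L) %/% n1 + 1L
      ## neighbors: (i-1,j), (i+1,j), (i,j-1), (i,j+1)
      if (i > 1L && !cuts$I[i - 1L, j]) {
        nb <- cur - 1L
        if (valid[nb] && !reached[nb]) {
          u[nb] <- u[cur] + .wrapToPi(p[nb] - p[cur])
          reached[nb] <- TRUE; tail <- tail + 1L; queue[tail] <- nb
        }
      }
      if (i < n1 && !cuts$I[i, j]) {
        nb <- cur + 1L
        if (valid[nb] && !reached[nb]) {
          u[nb] <- u[cur] + .wrapToPi(p[nb] - p[cur])
          reached[nb] <- TRUE; tail <- tail + 1L; queue[tail] <- nb
        }
      }
      if (j > 1L && !cuts$J[i, j - 1L]) {
        nb <- cur - n1
        if (valid[nb] && !reached[nb]) {
          u[nb] <- u[cur] + .wrapToPi(p[nb] - p[cur])
          reached[nb] <- TRUE; tail <- tail + 1L; queue[tail] <- nb
        }
      }
      if (j < n2 && !cuts$J[i, j]) {
        nb <- cur + n1
        if (valid[nb] && !reached[nb]) {
          u[nb] <- u[cur] + .wrapToPi(p[nb] - p[cur])
          reached[nb] <- TRUE; tail <- tail + 1L; queue[tail] <- nb
        }
      }
    }
  }
  list(u = u, reached = reached)
}

#' Goldstein branch-cut 2-D phase unwrapping
#'
#' Unwraps a wrapped phase array slice by slice. Per slice: residues (2x2
#' loop-integral failures) are detected, paired with opposite-sign partners
#' or tied to the grid border by branch cuts, and the phase is integrated
#' by flood fill without crossing a cut or an invalid voxel. On a
#' residue-free slice the result equals the true phase up to one additive
#' multiple of 2*pi per connected component. For 3-D input the per-slice
#' 2*pi ambiguity is then aligned by minimizing the median difference
#' between adjacent slices over commonly valid voxels.
#'
#' @param phase wrapped phase, values in \code{(-pi, pi]}; a matrix (one
#'   slice) or a 3-D array (slices along the third axis)
#' @param valid logical array of the same shape; invalid voxels are left
#'   untouched and flagged unreached. Default: all valid.
#' @return a list with \code{phase} (unwrapped where reached, input phase
#'   elsewhere), \code{reached} (logical), and \code{residues} (integer,
#'   residue count per slice). An all-invalid slice yields
#'   \code{reached = FALSE} throughout that slice, not an error.
#' @export
goldsteinUnwrap <- function(phase, valid = NULL) {
  was2d <- length(dim(phase)) == 2L || is.null(dim(phase))
  if (is.null(dim(phase))) phase <- as.matrix(phase)
  if (was2d) dim(phase) <- c(dim(phase), 1L)
  if (is.null(valid)) valid <- array(TRUE, dim(phase))
  if (was2d && length(dim(valid)) == 2L) dim(valid) <- dim(phase)
  stopifnot(identical(dim(valid), dim(phase)))
  nz <- dim(phase)[3]
  out <- array(NA_real_, dim(phase))
  reached <- array(FALSE, dim(phase))
  residues <- integer(nz)
  for (k in seq_len(nz)) {
    p <- phase[, , k]; v <- valid[, , k]
    if (!any(v)) next
    q <- .residueCharges(p, v)
    residues[k] <- sum(abs(q))
    cuts <- .makeCuts(q, nrow(p), ncol(p))
    res <- .integrateSlice(p, v, cuts)
    out[, , k] <- res$u
    reached[, , k] <- res$reached
  }
  ## inter-slice 2*pi alignment
  if (nz > 1L) {
    for (k in 2:nz) {
      common <- reached[, , k] & reached[, , k - 1L]
      if (!any(common)) next
      d <- stats::median(out[, , k][common] - out[, , k - 1L][common])
      out[, , k] <- out[, , k] - 2 * pi * round(d / (2 * pi))
    }
  }
  out[!reached] <- phase[!reached]
  if (was2d) {
    dim(out) <- dim(out)[1:2]
    dim(reached) <- dim(reached)[1:2]
  }
  list(phase = out, reached = reached, residues = residues)
}
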