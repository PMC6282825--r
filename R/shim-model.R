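## First/second-order real solid-harmonic shim fields. Raw (unnormalized)
## forms: X=x, Y=y, Z=z, Z2=2z^2-x^2-y^2, ZX=zx, ZY=zy, X2-Y2=x^2-y^2,
## XY=xy. Each is divided by its maximum magnitude on the reference sphere
## so a unit coefficient yields `scale` Hz at the reference radius on the
## term's principal axis: r0 for the linear terms; 2 r0^2 (poles) for Z2;
## r0^2/2 (45-degree diagonals) for ZX, ZY and XY; r0^2 (axes) for X2-Y2.

#' Evaluate the shim basis fields at physical points
#'
#' @param coords numeric matrix of points (n x 3, mm) or a vector of
#'   length 3
#' @param basis a \linkS4class{ShimBasis}
#' @return n x 8 matrix (Hz per unit coefficient), columns labeled by term
#' @examples
#' evaluateBasis(c(200, 0, 0), shimBasis())  # X term = 1, rest 0
#' @export
evaluateBasis <- function(coords, basis = shimBasis()) {
  stopifnot(is(basis, "ShimBasis"))
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  r0 <- basis@referenceRadius
  out <- cbind(
    X        = x / r0,
    Y        = y / r0,
    Z        = z / r0,
    Z2       = (2 * z^2 - x^2 - y^2) / (2 * r0^2),
    ZX       = z * x / (r0^2 / 2),
    ZY       = z * y / (r0^2 / 2),
    `X2-Y2`  = (x^2 - y^2) / r0^2,
    XY       = x * y / (r0^2 / 2)
  ) * basis@scale
  out
}

#' Build the shim design matrix over a region
#'
#' Rows are \code{\link{evaluateBasis}} at the physical centers of the
#' masked voxels in deterministic x-fastest order: the matrix A over the
#' brain ROI, or the constraint matrix C over the fat region.
#'
#' @param mask a \linkS4class{RegionMask}
#' @param basis a \linkS4class{ShimBasis}
#' @param stride keep every stride-th masked voxel (fat subsampling for
#'   speed); default 1 (all)
#' @param onEmpty \code{"error"} (brain) or \code{"vacuous"} (fat: return a
#'   0-row matrix so constraints are vacuously satisfied)
#' @return a \linkS4class{ShimDesign}
#' @export
buildDesignMatrix <- function(mask, basis = shimBasis(), stride = 1L,
                              onEmpty = c("error", "vacuous")) {
  stopifnot(is(mask, "RegionMask"))
  onEmpty <- match.arg(onEmpty)
  idx <- which(mask@mask)
  if (stride > 1L) idx <- idx[seq(1L, length(idx), by = as.integer(stride))]
  if (!length(idx)) {
    if (onEmpty == "error")
      stop("empty region mask: cannot build a design matrix", call. = FALSE)
    return(new("ShimDesign",
               values = matrix(0, 0, length(basis@terms)),
               voxelIndex = integer(0), region = mask@label,
               terms = basis@terms))
  }
  coords <- .voxelCoordinates(dim(mask@mask), mask@spacing, mask@origin, idx)
  new("ShimDesign", values = evaluateBasis(coords, basis),
      voxelIndex = as.integer(idx), region = mask@label,
      terms = basis@terms)
}

#' Project shim coefficients onto a field map
#'
#' Simulates applying a shim setting by subtracting the basis combination
#' from the field on the whole grid: residual = field - sum_j s_j basis_j.
#' The valid mask is unchanged.
#'
#' @param fm a \linkS4class{FieldMap}
#' @param basis a \linkS4class{ShimBasis}
#' @param s coefficient vector (8 entries)
#' @param limits optional \linkS4class{ShimLimits}; out-of-bounds
#'   coefficients trigger a warning (simulation is still allowed)
#' @return the residual \linkS4class{FieldMap}
#' @export
projectShim <- function(fm, basis, s, limits = NULL) {
  stopifnot(is(fm, "FieldMap"), length(s) == length(basis@terms))
  if (!is.null(limits) && (any(s < limits@lb - 1e-9) ||
                           any(s > limits@ub + 1e-9)))
    warning("shim coefficients outside hardware bounds (simulation only)",
            call. = FALSE)
  dm <- dim(fm@freq)
  coords <- .voxelCoordinates(dm, fm@spacing, fm@origin, seq_len(prod(dm)))
  shimField <- array(drop(evaluateBasis(coords, basis) %*% s), dm)
  fieldMap(fm@freq - shimField, spacing = fm@spacing, origin = fm@origin,
           valid = fm@valid)
}
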