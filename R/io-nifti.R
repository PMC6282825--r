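## NIfTI-1 input/output via RNifti. The affine stores spacing on the
## diagonal and the world position of voxel (1,1,1) in the translation;
## units are recorded in the header where the format allows.

.writeVolume <- function(arr, spacing, origin, path, description = "") {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  if (nzchar(description))
    img <- RNifti::asNifti(img, descrip = description)
  RNifti::writeNifti(img, path)
  invisible(path)
}

.readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  x <- RNifti::xform(img)
  list(data = array(as.vector(img), dim(img)),
       spacing = abs(diag(x)[1:3]),
       origin = as.numeric(x[1:3, 4]))
}

#' Write a field map to NIfTI
#'
#' The frequency volume (Hz) goes to \code{path}; the validity mask is
#' written alongside with suffix \code{_valid}.
#'
#' @param fm a \linkS4class{FieldMap}
#' @param path output .nii/.nii.gz path
#' @return the path, invisibly
#' @export
writeFieldMapNifti <- function(fm, path) {
  stopifnot(is(fm, "FieldMap"))
  .writeVolume(fm@freq, fm@spacing, fm@origin, path, "off-resonance [Hz]")
  .writeVolume(fm@valid + 0, fm@spacing, fm@origin,
               .validPath(path), "valid mask")
  invisible(path)
}

.validPath <- function(path)
  sub("(\\.nii(\\.gz)?)$", "_valid\\1", path)

#' Read a field map from NIfTI
#'
#' @param path frequency volume (Hz) written by
#'   \code{\link{writeFieldMapNifti}}; the \code{_valid} companion is
#'   loaded when present
#' @return a \linkS4class{FieldMap}
#' @export
readFieldMapNifti <- function(path) {
  v <- .readVolume(path)
  vp <- .validPath(path)
  valid <- if (file.exists(vp)) array(.readVolume(vp)$data > 0.5,
                                      dim(v$data)) else NULL
  fieldMap(v$data, spacing = v$spacing, origin = v$origin, valid = valid)
}

#' Write a region mask to NIfTI
#'
#' @param mask a \linkS4class{RegionMask}
#' @param path output path
#' @return the path, invisibly
#' @export
writeMaskNifti <- function(mask, path) {
  stopifnot(is(mask, "RegionMask"))
  .writeVolume(mask@mask + 0, mask@spacing, mask@origin, path,
               paste("region mask:", mask@label))
}

#' Read a region mask from NIfTI
#'
#' @param path mask volume (nonzero = inside)
#' @param label region label to assign
#' @return a \linkS4class{RegionMask}
#' @export
readMaskNifti <- function(path, label = "other") {
  v <- .readVolume(path)
  regionMask(array(v$data > 0.5, dim(v$data)), label = label,
             spacing = v$spacing, origin = v$origin)
}

#' Read an echo image from magnitude and phase NIfTI volumes
#'
#' @param magnitudePath,phasePath NIfTI volumes; phase in radians
#' @param te echo time (ms)
#' @return an \linkS4class{EchoImage}
#' @export
readEchoImageNifti <- function(magnitudePath, phasePath, te) {
  m <- .readVolume(magnitudePath)
  p <- .readVolume(phasePath)
  stopifnot(identical(dim(m$data), dim(p$data)))
  echoImage(array(complex(modulus = m$data, argument = p$data),
                  dim(m$data)),
            te = te, spacing = m$spacing, origin = m$origin)
}

#' Write shim solution coefficients to JSON
#'
#' @param solution a \linkS4class{ShimSolution}
#' @param path output file
#' @param basis the \linkS4class{ShimBasis} giving units context
#' @return the path, invisibly
#' @export
writeShimSolution <- function(solution, path, basis = shimBasis()) {
  jsonlite::write_json(
    list(coefficients = as.list(solution@s),
         units = sprintf("Hz at %g mm reference radius per unit",
                         basis@referenceRadius),
         objective = solution@objective, feasible = solution@feasible,
         activeBounds = solution@activeBounds,
         activeFatVoxels = solution@activeFatVoxels,
         solverReport = solution@solverReport),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
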