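#' @include AllClasses.R
NULL

#' Voxel spacing of a gridded object
#'
#' @param x an object with a voxel grid (\linkS4class{EchoImage},
#'   \linkS4class{FieldMap}, \linkS4class{RegionMask})
#' @return numeric vector of length 3, spacing in mm per axis
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Grid origin of a gridded object
#'
#' Position of voxel (1,1,1) in scanner coordinates (mm, isocenter at 0).
#'
#' @param x a gridded object
#' @return numeric vector of length 3 (mm)
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' Off-resonance frequency values
#'
#' @param x a \linkS4class{FieldMap}
#' @return numeric array in Hz
#' @export
setGeneric("freq", function(x) standardGeneric("freq"))

#' Reliable-voxel mask
#'
#' @param x a \linkS4class{FieldMap}
#' @return logical array
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Boolean mask array of a region
#'
#' @param x a \linkS4class{RegionMask}
#' @return logical array
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Region label
#'
#' @param x a \linkS4class{RegionMask}
#' @return character, one of \code{"brain"}, \code{"fat"}, \code{"other"}
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))

#' Shim coefficients of a solution
#'
#' @param object a \linkS4class{ShimSolution}
#' @param ... ignored
#' @return named numeric vector of coefficients, one per basis term
#' @export
setGeneric("shimCoefficients",
           function(object, ...) standardGeneric("shimCoefficients"))
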