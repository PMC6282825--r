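#' Standard deviation of a field over an ROI
#'
#' Population SD (divisor N) of the frequencies over the masked valid
#' voxels, the homogeneity metric reported for the fetal brain ROI.
#'
#' @param fm a \linkS4class{FieldMap}
#' @param mask a \linkS4class{RegionMask}
#' @return SD in Hz
#' @export
roiSD <- function(fm, mask) {
  stopifnot(is(fm, "FieldMap"), is(mask, "RegionMask"))
  .stopGeometry(fm, mask, what = "field map and mask")
  v <- fm@freq[mask@mask & fm@valid]
  if (!length(v)) stop("empty ROI", call. = FALSE)
  sqrt(mean((v - mean(v))^2))
}

#' Percentage of fat voxels outside the saturation band
#'
#' Fraction (in percent) of masked valid voxels whose residual frequency
#' falls outside the closed band [d1, d2]; a voxel exactly at a band edge
#' counts as inside (band endpoints are feasibility at equality in the
#' constrained fit).
#'
#' @param fm residual \linkS4class{FieldMap}
#' @param fatMask \linkS4class{RegionMask} of the fat region
#' @param d1,d2 band limits (Hz)
#' @return percentage in [0, 100]
#' @export
fatOutOfBand <- function(fm, fatMask, d1 = -350, d2 = 100) {
  stopifnot(is(fm, "FieldMap"), is(fatMask, "RegionMask"), d1 < d2)
  .stopGeometry(fm, fatMask, what = "field map and fat mask")
  v <- fm@freq[fatMask@mask & fm@valid]
  if (!length(v)) stop("empty fat mask", call. = FALSE)
  100 * mean(v < d1 | v > d2)
}

#' Water-fat shift in acquired pixels
#'
#' Displacement of the fat signal along the EPI phase-encode direction:
#' |chemical shift| times the echo-train duration,
#' \code{|shift| * etl * echoSpacing / 1000} pixels. The echo spacing can
#' be derived from the readout gradient switching frequency as
#' \code{1/(2 fSwitch)}.
#'
#' @param chemicalShift water-fat shift (Hz)
#' @param echoSpacing EPI echo spacing (ms); derived from \code{fSwitch}
#'   when missing
#' @param etl echo-train length (number of phase-encode echoes)
#' @param fSwitch readout switching frequency (Hz), used when
#'   \code{echoSpacing} is missing
#' @return shift in pixels (unrounded)
#' @examples
#' wfsPixels(434, etl = 73, fSwitch = 490)  # ~32.3 pixels
#' @export
wfsPixels <- function(chemicalShift, echoSpacing = NULL, etl,
                      fSwitch = NULL) {
  if (is.null(echoSpacing)) {
    stopifnot(!is.null(fSwitch), fSwitch > 0)
    echoSpacing <- 1000 / (2 * fSwitch)
  }
  stopifnot(echoSpacing > 0, etl > 0)
  abs(chemicalShift) * etl * echoSpacing / 1000
}

#' Per-voxel EPI displacement map from a residual field
#'
#' The pixel shift each voxel suffers along the phase-encode axis,
#' \code{freq * etl * echoSpacing / 1000}: the geometric distortion the
#' shim minimizes.
#'
#' @param fm residual \linkS4class{FieldMap}
#' @param echoSpacing EPI echo spacing (ms)
#' @param etl echo-train length
#' @param phaseAxis phase-encode axis index (1-3); recorded as an attribute
#' @return numeric array of pixel shifts
#' @export
displacementMap <- function(fm, echoSpacing, etl, phaseAxis = 2L) {
  stopifnot(is(fm, "FieldMap"), echoSpacing > 0, etl > 0,
            phaseAxis %in% 1:3)
  out <- fm@freq * etl * echoSpacing / 1000
  attr(out, "phaseAxis") <- as.integer(phaseAxis)
  out
}

#' Build a shim evaluation report
#'
#' @param residual residual \linkS4class{FieldMap} after projecting the
#'   solution
#' @param brainMask,fatMask \linkS4class{RegionMask}s; \code{fatMask} may
#'   be NULL (fat fraction reported as NA)
#' @param d1,d2 band limits (Hz)
#' @param mode \code{"localized"} or \code{"constrained"}
#' @param provenance list of inputs/config/seed to record
#' @return a \linkS4class{ShimReport}
#' @export
shimReport <- function(residual, brainMask, fatMask = NULL,
                       d1 = -350, d2 = 100, mode, provenance = list()) {
  v <- residual@freq[brainMask@mask & residual@valid]
  new("ShimReport",
      roiSdHz = roiSD(residual, brainMask),
      fatOutFraction = if (is.null(fatMask) || !any(fatMask@mask))
        NA_real_ else fatOutOfBand(residual, fatMask, d1, d2),
      meanOffsetHz = mean(v), mode = mode, provenance = provenance)
}

#' Write a shim report to JSON
#'
#' @param report a \linkS4class{ShimReport}
#' @param path output file
#' @return the path, invisibly
#' @export
writeShimReport <- function(report, path) {
  jsonlite::write_json(
    list(roiSdHz = report@roiSdHz, fatOutFraction = report@fatOutFraction,
         meanOffsetHz = report@meanOffsetHz, mode = report@mode,
         provenance = report@provenance),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a shim report from JSON
#'
#' @param path file written by \code{\link{writeShimReport}}
#' @return a \linkS4class{ShimReport}
#' @export
readShimReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ShimReport", roiSdHz = as.numeric(x$roiSdHz %||% NA),
      fatOutFraction = as.numeric(x$fatOutFraction %||% NA),
      meanOffsetHz = as.numeric(x$meanOffsetHz %||% NA),
      mode = x$mode, provenance = as.list(x$provenance))
}
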