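## Grid geometry helpers. Arrays are indexed (x, y, z), x fastest; the
## physical center of voxel (i,j,k) is origin + (c(i,j,k)-1)*spacing.

## axis coordinate vectors for a grid
.gridAxes <- function(dm, spacing, origin) {
  list(x = origin[1] + (seq_len(dm[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(dm[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(dm[3]) - 1) * spacing[3])
}

## physical coordinates (n x 3, mm) of linear voxel indices
.voxelCoordinates <- function(dm, spacing, origin, index) {
  index <- as.integer(index) - 1L
  i <- index %% dm[1]
  j <- (index %/% dm[1]) %% dm[2]
  k <- index %/% (dm[1] * dm[2])
  cbind(x = origin[1] + i * spacing[1],
        y = origin[2] + j * spacing[2],
        z = origin[3] + k * spacing[3])
}

## origin that centers a grid on the isocenter
.centeredOrigin <- function(dm, spacing) -(dm - 1) / 2 * spacing

.sameGeometry <- function(a, b) {
  identical(dim(.gridData(a)), dim(.gridData(b))) &&
    isTRUE(all(a@spacing == b@spacing)) &&
    isTRUE(all(a@origin == b@origin))
}

.gridData <- function(x) {
  if (is(x, "EchoImage")) x@data
  else if (is(x, "FieldMap")) x@freq
  else if (is(x, "RegionMask")) x@mask
  else stop("not a gridded object")
}

.stopGeometry <- function(..., what = "inputs") {
  objs <- list(...)
  for (i in seq_along(objs)[-1])
    if (!.sameGeometry(objs[[1]], objs[[i]]))
      stop(what, " must share grid shape, spacing and origin exactly",
           call. = FALSE)
  invisible(TRUE)
}

#' @rdname voxelSpacing
setMethod("voxelSpacing", "EchoImage", function(x) x@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "FieldMap", function(x) x@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "RegionMask", function(x) x@spacing)

#' @rdname gridOrigin
setMethod("gridOrigin", "EchoImage", function(x) x@origin)
#' @rdname gridOrigin
setMethod("gridOrigin", "FieldMap", function(x) x@origin)
#' @rdname gridOrigin
setMethod("gridOrigin", "RegionMask", function(x) x@origin)

#' @rdname freq
setMethod("freq", "FieldMap", function(x) x@freq)
#' @rdname validMask
setMethod("validMask", "FieldMap", function(x) x@valid)
#' @rdname maskArray
setMethod("maskArray", "RegionMask", function(x) x@mask)
#' @rdname maskLabel
setMethod("maskLabel", "RegionMask", function(x) x@label)

#' @rdname shimCoefficients
setMethod("shimCoefficients", "ShimSolution", function(object, ...) object@s)

setMethod("show", "FieldMap", function(object) {
  v <- object@freq[object@valid]
  cat("FieldMap:", paste(dim(object@freq), collapse = " x "),
      "voxels at", paste(object@spacing, collapse = " x "), "mm\n")
  cat(sprintf("  valid voxels: %d (%.1f%%)\n", sum(object@valid),
              100 * mean(object@valid)))
  if (length(v))
    cat(sprintf("  freq range (valid): [%.2f, %.2f] Hz, SD %.2f Hz\n",
                min(v), max(v), stats::sd(v)))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask '%s': %d of %d voxels\n", object@label,
              sum(object@mask), length(object@mask)))
})

setMethod("show", "ShimSolution", function(object) {
  cat("ShimSolution (", object@solverReport, ")\n", sep = "")
  print(round(object@s, 4))
  cat(sprintf("  objective %.6g; feasible: %s\n",
              object@objective, object@feasible))
  if (length(object@activeBounds))
    cat("  bounds active:", paste(object@activeBounds, collapse = ", "), "\n")
  if (object@activeFatVoxels > 0L)
    cat("  fat voxels at a band edge:", object@activeFatVoxels, "\n")
})

setMethod("show", "SaturationBand", function(object) {
  cat(sprintf("SaturationBand (%.0f%% of peak): [%.1f, %.1f] Hz absolute\n",
              100 * object@level, object@low, object@high))
  cat(sprintf("  as fat deviation (shift %.0f Hz): d1 = %.1f, d2 = %.1f Hz\n",
              object@fatShift, object@fatLow, object@fatHigh))
})

setMethod("show", "ShimReport", function(object) {
  cat(sprintf("ShimReport [%s]: brain SD %.2f Hz, fat out-of-band %.1f%%, f0 offset %.2f Hz\n",
              object@mode, object@roiSdHz, object@fatOutFraction,
              object@meanOffsetHz))
})
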