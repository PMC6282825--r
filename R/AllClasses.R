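## S4 classes for the shimming pipeline. All gridded objects share the same
## geometry convention: arrays indexed (x, y, z) with x varying fastest
## (native R order); physical coordinates in mm, isocenter at 0; the position
## of voxel (1,1,1) is `origin`, voxel centers at origin + (index-1)*spacing.

.checkGeometrySlots <- function(object, dims) {
  msg <- character(0)
  if (length(dims) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  msg
}

#' Complex gradient-echo image at one echo time
#'
#' A single echo of a (multi-slice 2-D) spoiled gradient-echo acquisition,
#' stored as a complex 3-D array with its voxel geometry. Echoes combined in
#' one computation must share grid shape, spacing and origin exactly.
#'
#' @slot data complex 3-D array (arbitrary units)
#' @slot te echo time in ms, > 0
#' @slot spacing voxel size per axis (mm)
#' @slot origin scanner coordinates of voxel (1,1,1) (mm)
#' @export
setClass("EchoImage",
  representation(data = "array", te = "numeric",
                 spacing = "numeric", origin = "numeric"))

setValidity("EchoImage", function(object) {
  msg <- .checkGeometrySlots(object, dim(object@data))
  if (!is.complex(object@data))
    msg <- c(msg, "data must be complex")
  if (length(object@te) != 1L || !is.finite(object@te) || object@te <= 0)
    msg <- c(msg, "te must be a single positive number (ms)")
  if (length(msg)) msg else TRUE
})

#' Construct an EchoImage
#'
#' @param data complex (or numeric, promoted) 3-D array
#' @param te echo time (ms)
#' @param spacing voxel size (mm), length 3
#' @param origin position of voxel (1,1,1) (mm), length 3
#' @return an \linkS4class{EchoImage}
#' @export
echoImage <- function(data, te, spacing, origin = c(0, 0, 0)) {
  storage.mode(data) <- "complex"
  new("EchoImage", data = data, te = as.numeric(te),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Off-resonance field map
#'
#' Scalar B0 deviation from the water center frequency, in Hz, on a voxel
#' grid, together with a mask of reliable voxels (sufficient magnitude).
#'
#' @slot freq numeric 3-D array (Hz)
#' @slot valid logical 3-D array, same shape
#' @slot spacing,origin grid geometry (mm)
#' @export
setClass("FieldMap",
  representation(freq = "array", valid = "array",
                 spacing = "numeric", origin = "numeric"))

setValidity("FieldMap", function(object) {
  msg <- .checkGeometrySlots(object, dim(object@freq))
  if (!is.logical(object@valid))
    msg <- c(msg, "valid must be logical")
  if (!identical(dim(object@freq), dim(object@valid)))
    msg <- c(msg, "freq and valid must have identical dimensions")
  v <- object@valid & !is.na(object@valid)
  if (any(!is.finite(object@freq[v])))
    msg <- c(msg, "freq must be finite on valid voxels")
  if (length(msg)) msg else TRUE
})

#' Construct a FieldMap
#'
#' @param freq numeric 3-D array (Hz)
#' @param spacing,origin grid geometry (mm)
#' @param valid logical array of reliable voxels; default all TRUE
#' @return a \linkS4class{FieldMap}
#' @export
fieldMap <- function(freq, spacing, origin = c(0, 0, 0), valid = NULL) {
  if (is.null(valid)) valid <- array(TRUE, dim(freq))
  new("FieldMap", freq = freq, valid = valid,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Boolean region-of-interest mask
#'
#' Selects the fetal-brain target region or the maternal-fat constraint
#' region on the same grid as the field map it indexes.
#'
#' @slot mask logical 3-D array
#' @slot label one of \code{"brain"}, \code{"fat"}, \code{"other"}
#' @slot spacing,origin grid geometry (mm)
#' @export
setClass("RegionMask",
  representation(mask = "array", label = "character",
                 spacing = "numeric", origin = "numeric"))

setValidity("RegionMask", function(object) {
  msg <- .checkGeometrySlots(object, dim(object@mask))
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (length(object@label) != 1L ||
      !object@label %in% c("brain", "fat", "other"))
    msg <- c(msg, "label must be one of 'brain', 'fat', 'other'")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionMask
#'
#' @param mask logical 3-D array
#' @param label region label: \code{"brain"}, \code{"fat"} or \code{"other"}
#' @param spacing,origin grid geometry (mm)
#' @return a \linkS4class{RegionMask}
#' @export
regionMask <- function(mask, label = "other", spacing, origin = c(0, 0, 0)) {
  new("RegionMask", mask = mask, label = label,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Ellipsoidal fetal-brain ROI
#'
#' Axis-aligned ellipsoid of adjustable position and size, set once and
#' propagated over a slice range, used to circumscribe the fetal brain.
#'
#' @slot center scanner coordinates of the ellipsoid center (mm)
#' @slot semiaxes three semi-axis lengths (mm), > 0
#' @slot sliceRange integer slice indices the ROI propagates over;
#'   \code{integer(0)} means all slices
#' @export
setClass("EllipsoidROI",
  representation(center = "numeric", semiaxes = "numeric",
                 sliceRange = "integer"))

setValidity("EllipsoidROI", function(object) {
  msg <- character(0)
  if (length(object@center) != 3L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be 3 finite values (mm)")
  if (length(object@semiaxes) != 3L || any(!is.finite(object@semiaxes)) ||
      any(object@semiaxes <= 0))
    msg <- c(msg, "semiaxes must be 3 strictly positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct an EllipsoidROI
#'
#' @param center ellipsoid center (mm), length 3
#' @param semiaxes semi-axis lengths (mm), length 3
#' @param sliceRange slice indices to restrict to; \code{NULL} for all
#' @return an \linkS4class{EllipsoidROI}
#' @export
ellipsoidROI <- function(center, semiaxes, sliceRange = NULL) {
  new("EllipsoidROI", center = as.numeric(center),
      semiaxes = as.numeric(semiaxes),
      sliceRange = as.integer(sliceRange %||% integer(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' First- and second-order spherical-harmonic shim basis
#'
#' The eight real solid-harmonic field shapes generated by first- and
#' second-order shim coils: X, Y, Z, Z2, ZX, ZY, X2-Y2, XY. Each term is
#' scaled so a unit coefficient produces \code{scale} Hz at
#' \code{referenceRadius} on the term's principal axis.
#'
#' @slot terms the eight term labels, fixed order
#' @slot referenceRadius reference radius in mm
#' @slot scale Hz produced at the reference radius per unit coefficient
#' @export
setClass("ShimBasis",
  representation(terms = "character", referenceRadius = "numeric",
                 scale = "numeric"))

SHIM_TERMS <- c("X", "Y", "Z", "Z2", "ZX", "ZY", "X2-Y2", "XY")

setValidity("ShimBasis", function(object) {
  msg <- character(0)
  if (!identical(object@terms, SHIM_TERMS))
    msg <- c(msg, "terms must be the 8 first/second-order labels in order")
  if (length(object@referenceRadius) != 1L || object@referenceRadius <= 0)
    msg <- c(msg, "referenceRadius must be a single positive value (mm)")
  if (length(object@scale) != 1L || object@scale <= 0)
    msg <- c(msg, "scale must be a single positive value (Hz)")
  if (length(msg)) msg else TRUE
})

#' Construct the shim basis
#'
#' @param referenceRadius reference radius (mm); default 200 mm
#' @param scale Hz at the reference radius per unit coefficient; default 1,
#'   so coefficients read directly as "Hz at the reference radius"
#' @return a \linkS4class{ShimBasis}
#' @export
shimBasis <- function(referenceRadius = 200, scale = 1) {
  new("ShimBasis", terms = SHIM_TERMS,
      referenceRadius = as.numeric(referenceRadius),
      scale = as.numeric(scale))
}

#' Shim design matrix over a region
#'
#' Rows are the basis fields evaluated at the physical centers of the masked
#' voxels, in deterministic x-fastest voxel order. For the brain ROI this is
#' the matrix A of the shim fit; for the fat region the constraint matrix C.
#'
#' @slot values N_voxels x N_terms matrix (Hz per unit coefficient)
#' @slot voxelIndex linear grid index of each row
#' @slot region label of the generating mask
#' @slot terms column labels
#' @export
setClass("ShimDesign",
  representation(values = "matrix", voxelIndex = "integer",
                 region = "character", terms = "character"))

setValidity("ShimDesign", function(object) {
  msg <- character(0)
  if (nrow(object@values) != length(object@voxelIndex))
    msg <- c(msg, "row count must equal voxelIndex length")
  if (ncol(object@values) != length(object@terms))
    msg <- c(msg, "column count must equal number of terms")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "design values must be finite")
  if (length(msg)) msg else TRUE
})

#' Hardware coefficient bounds
#'
#' @slot lb,ub per-term lower/upper bounds in coefficient units;
#'   \code{lb <= ub} elementwise
#' @export
setClass("ShimLimits", representation(lb = "numeric", ub = "numeric"))

setValidity("ShimLimits", function(object) {
  msg <- character(0)
  if (length(object@lb) != length(object@ub))
    msg <- c(msg, "lb and ub must have equal length")
  if (any(object@lb > object@ub))
    msg <- c(msg, "lb must be <= ub elementwise")
  if (length(msg)) msg else TRUE
})

#' Construct shim hardware limits
#'
#' The defaults are wide placeholders; real systems must supply their own
#' calibrated bounds.
#'
#' @param lb,ub per-term bounds (coefficient units, recycled to 8)
#' @return a \linkS4class{ShimLimits}
#' @export
shimLimits <- function(lb = rep(-1000, 8), ub = rep(1000, 8)) {
  n <- max(length(lb), length(ub))
  new("ShimLimits", lb = rep_len(as.numeric(lb), n),
      ub = rep_len(as.numeric(ub), n))
}

#' Shim optimization problem
#'
#' Data of the regularized bounded least-squares shim fit: brain design
#' matrix A and field values b, Tikhonov weight lambda, coefficient bounds,
#' and (optionally) the fat constraint matrix C with field values b_fat and
#' the residual band limits d1 < d2 inside which the fat residual frequency
#' must stay for the saturation pulse to remain effective.
#'
#' @slot A brain design matrix (N_b x N_terms)
#' @slot b field values over the brain ROI (Hz)
#' @slot lambda Tikhonov weight acting on column-RMS-normalized coefficients
#' @slot lb,ub coefficient bounds
#' @slot Cfat fat design matrix (0 rows when unconstrained)
#' @slot bFat field values over the fat region (Hz)
#' @slot d1,d2 fat residual band limits (Hz), d1 < d2
#' @slot terms coefficient labels
#' @export
setClass("ShimProblem",
  representation(A = "matrix", b = "numeric", lambda = "numeric",
                 lb = "numeric", ub = "numeric",
                 Cfat = "matrix", bFat = "numeric",
                 d1 = "numeric", d2 = "numeric", terms = "character"))

setValidity("ShimProblem", function(object) {
  msg <- character(0)
  p <- ncol(object@A)
  if (nrow(object@A) != length(object@b))
    msg <- c(msg, "nrow(A) must equal length(b)")
  if (length(object@lb) != p || length(object@ub) != p)
    msg <- c(msg, "bounds must have one entry per term")
  if (any(object@lb > object@ub))
    msg <- c(msg, "lb must be <= ub elementwise")
  if (length(object@lambda) != 1L || object@lambda < 0)
    msg <- c(msg, "lambda must be a single value >= 0")
  if (nrow(object@Cfat) > 0L) {
    if (ncol(object@Cfat) != p)
      msg <- c(msg, "C must have the same number of columns as A")
    if (nrow(object@Cfat) != length(object@bFat))
      msg <- c(msg, "nrow(C) must equal length(bFat)")
    if (object@d1 >= object@d2)
      msg <- c(msg, "d1 must be < d2")
  }
  if (length(object@terms) != p)
    msg <- c(msg, "terms must label every column of A")
  if (length(msg)) msg else TRUE
})

#' Solved shim setting
#'
#' @slot s named coefficient vector, always within bounds
#' @slot objective final cost value
#' @slot feasible TRUE when every fat constraint holds within tolerance
#' @slot activeBounds term labels at a bound
#' @slot activeFatVoxels number of fat voxels at a band edge
#' @slot solverReport free-text solver status
#' @export
setClass("ShimSolution",
  representation(s = "numeric", objective = "numeric", feasible = "logical",
                 activeBounds = "character", activeFatVoxels = "integer",
                 solverReport = "character"))

#' Sampled frequency-selective saturation pulse
#'
#' @slot envelope complex B1 samples in Hz (rotation rate), including the
#'   frequency-offset phase ramp
#' @slot duration pulse duration (ms)
#' @slot nominalFlip on-resonance flip angle (degrees)
#' @slot tbp time-bandwidth product
#' @slot offset saturation-band center as a positive magnitude on the fat
#'   side of water (Hz); internally the band sits at \code{-offset}
#' @export
setClass("RFPulse",
  representation(envelope = "complex", duration = "numeric",
                 nominalFlip = "numeric", tbp = "numeric",
                 offset = "numeric"))

setValidity("RFPulse", function(object) {
  msg <- character(0)
  if (length(object@envelope) < 256L)
    msg <- c(msg, "envelope must have at least 256 samples")
  if (object@duration <= 0)
    msg <- c(msg, "duration must be positive (ms)")
  if (length(msg)) msg else TRUE
})

#' Bloch-simulated spectral saturation profile
#'
#' @slot offsets off-resonance axis (Hz, relative to water)
#' @slot mz longitudinal magnetization at pulse end, fraction of equilibrium
#' @export
setClass("SaturationProfile",
  representation(offsets = "numeric", mz = "numeric"))

setValidity("SaturationProfile", function(object) {
  msg <- character(0)
  if (length(object@offsets) != length(object@mz))
    msg <- c(msg, "offsets and mz must have equal length")
  if (any(object@mz < -1 - 1e-9 | object@mz > 1 + 1e-9))
    msg <- c(msg, "mz must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Effective saturation band of a pulse
#'
#' Contiguous off-resonance range where saturation reaches at least
#' \code{level} of its peak, in absolute Hz and re-expressed as deviation
#' from the fat resonance. The fat-deviation edges are the residual-band
#' limits d1 and d2 of the constrained shim fit.
#'
#' @slot low,high absolute band edges (Hz)
#' @slot fatLow,fatHigh edges as fat-frequency deviation (Hz)
#' @slot level the peak fraction defining the band
#' @slot fatShift fat chemical shift used for re-expression (Hz)
#' @export
setClass("SaturationBand",
  representation(low = "numeric", high = "numeric",
                 fatLow = "numeric", fatHigh = "numeric",
                 level = "numeric", fatShift = "numeric"))

setValidity("SaturationBand", function(object) {
  if (object@low >= object@high) "low must be < high" else TRUE
})

#' Spectral model for signal-vs-offset simulation
#'
#' Normalized fat and water frequency histograms with longitudinal
#' relaxation times and the delay from pulse end to excitation.
#'
#' @slot fatFreq,fatWeight fat histogram (Hz; weights sum to 1)
#' @slot waterFreq,waterWeight water histogram (Hz; weights sum to 1)
#' @slot t1Fat,t1Water T1 times (ms)
#' @slot spirDelay delay from saturation-pulse end to excitation (ms)
#' @export
setClass("SpectralModel",
  representation(fatFreq = "numeric", fatWeight = "numeric",
                 waterFreq = "numeric", waterWeight = "numeric",
                 t1Fat = "numeric", t1Water = "numeric",
                 spirDelay = "numeric"))

setValidity("SpectralModel", function(object) {
  msg <- character(0)
  if (length(object@fatFreq) != length(object@fatWeight))
    msg <- c(msg, "fat histogram axes must match")
  if (length(object@waterFreq) != length(object@waterWeight))
    msg <- c(msg, "water histogram axes must match")
  if (length(object@fatWeight) &&
      abs(sum(object@fatWeight) - 1) > 1e-8)
    msg <- c(msg, "fat weights must sum to 1")
  if (length(object@waterWeight) &&
      abs(sum(object@waterWeight) - 1) > 1e-8)
    msg <- c(msg, "water weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Parametric synthetic maternal-abdomen phantom
#'
#' Full description of a synthetic abdomen: grid geometry, elliptical torso
#' with a subcutaneous fat ring carrying the chemical-shift species, a
#' fetal-brain ellipsoid, a ground-truth background field expressed in the
#' shim basis, optional spherical gas pockets generating dipole field
#' perturbations, and noise levels. The seed fixes all randomness.
#'
#' @slot dim grid size (voxels per axis)
#' @slot spacing voxel size (mm)
#' @slot torsoSemiaxes in-plane torso ellipse semi-axes (mm)
#' @slot fatRingThickness subcutaneous fat ring thickness (mm)
#' @slot brain fetal-brain \linkS4class{EllipsoidROI}
#' @slot backgroundCoeffs 8 ground-truth shim-basis coefficients
#' @slot gasPockets list of \code{list(center, radius, strength)}; strength
#'   in Hz * mm^3 scales the external dipole field
#' @slot noiseSd additive Gaussian field noise (Hz)
#' @slot snr magnitude signal-to-noise of the simulated echoes
#' @slot seed integer RNG seed
#' @slot chemicalShift fat chemical shift (Hz); default -430 at 3 T
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", spacing = "numeric",
                 torsoSemiaxes = "numeric", fatRingThickness = "numeric",
                 brain = "EllipsoidROI", backgroundCoeffs = "numeric",
                 gasPockets = "list", noiseSd = "numeric", snr = "numeric",
                 seed = "integer", chemicalShift = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (length(object@dim) != 3L || any(object@dim < 2L))
    msg <- c(msg, "dim must be 3 values >= 2")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (length(object@torsoSemiaxes) != 2L || any(object@torsoSemiaxes <= 0))
    msg <- c(msg, "torsoSemiaxes must be 2 positive values (mm)")
  if (object@fatRingThickness <= 0 ||
      object@fatRingThickness >= min(object@torsoSemiaxes))
    msg <- c(msg, "fatRingThickness must be positive and thinner than the torso")
  if (length(object@backgroundCoeffs) != 8L)
    msg <- c(msg, "backgroundCoeffs must have 8 entries")
  ## the brain ellipsoid must fit inside the inner (non-fat) torso region
  inner <- object@torsoSemiaxes - object@fatRingThickness
  ext <- abs(object@brain@center[1:2]) + object@brain@semiaxes[1:2]
  if (any(ext > inner))
    msg <- c(msg, "brain ellipsoid must lie inside the torso, clear of the fat ring")
  for (g in object@gasPockets)
    if (!all(c("center", "radius", "strength") %in% names(g)))
      msg <- c(msg, "each gas pocket needs center, radius, strength")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@snr <= 0) msg <- c(msg, "snr must be positive")
  if (length(msg)) msg else TRUE
})

#' Shim evaluation report
#'
#' Metrics of a residual field after shimming: SD of the residual frequency
#' over the brain ROI, the percentage of fat voxels outside the saturation
#' band, and the residual brain mean to be applied as a transmitter
#' frequency (f0) offset.
#'
#' @slot roiSdHz SD of the residual field in the brain ROI (Hz)
#' @slot fatOutFraction percent of fat voxels outside [d1, d2]
#' @slot meanOffsetHz residual brain mean (Hz)
#' @slot mode \code{"localized"} or \code{"constrained"}
#' @slot provenance list recording inputs, config and seed
#' @export
setClass("ShimReport",
  representation(roiSdHz = "numeric", fatOutFraction = "numeric",
                 meanOffsetHz = "numeric", mode = "character",
                 provenance = "list"))

setValidity("ShimReport", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("localized", "constrained"))
    msg <- c(msg, "mode must be 'localized' or 'constrained'")
  if (is.finite(object@fatOutFraction) &&
      (object@fatOutFraction < 0 || object@fatOutFraction > 100))
    msg <- c(msg, "fatOutFraction must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})
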