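## Synthetic maternal-abdomen phantom: an elliptical torso with a
## subcutaneous fat ring carrying the chemical-shift species, a fetal-brain
## ellipsoid, a smooth background field expressed in the shim basis,
## optional spherical gas pockets generating analytic external dipole
## fields, and Gaussian noise. Every stage of the pipeline can run on its
## output with no scanner data.

## evaluate expr with a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic maternal-abdomen phantom
#'
#' Defaults match a fetal field-map acquisition: 350 x 350 x 100 mm field
#' of view at the acquired 5 x 5 x 10 mm resolution (70 x 70 x 10 voxels),
#' grid centered on the isocenter.
#'
#' @param dim grid size (voxels); default \code{c(70, 70, 10)}
#' @param spacing voxel size (mm); default \code{c(5, 5, 10)}
#' @param torsoSemiaxes in-plane torso ellipse semi-axes (mm)
#' @param fatRingThickness subcutaneous fat ring thickness (mm)
#' @param brain fetal-brain \linkS4class{EllipsoidROI}
#' @param backgroundCoeffs 8 ground-truth shim-basis coefficients
#'   (coefficient units of \code{\link{shimBasis}})
#' @param gasPockets list of \code{list(center, radius, strength)}: sphere
#'   center (mm), radius (mm), dipole strength (Hz * mm^3)
#' @param noiseSd additive Gaussian field noise (Hz); default 0
#' @param snr echo magnitude signal-to-noise; default Inf (noise-free)
#' @param seed RNG seed fixing all randomness
#' @param chemicalShift fat chemical shift (Hz); default -430
#' @return a \linkS4class{PhantomSpec}
#' @export
phantomSpec <- function(dim = c(70L, 70L, 10L), spacing = c(5, 5, 10),
                        torsoSemiaxes = c(160, 120), fatRingThickness = 20,
                        brain = ellipsoidROI(c(15, 25, 0), c(40, 35, 25)),
                        backgroundCoeffs = rep(0, 8), gasPockets = list(),
                        noiseSd = 0, snr = Inf, seed = 1L,
                        chemicalShift = -430) {
  new("PhantomSpec", dim = as.integer(dim), spacing = as.numeric(spacing),
      torsoSemiaxes = as.numeric(torsoSemiaxes),
      fatRingThickness = as.numeric(fatRingThickness), brain = brain,
      backgroundCoeffs = as.numeric(backgroundCoeffs),
      gasPockets = gasPockets, noiseSd = as.numeric(noiseSd),
      snr = as.numeric(snr), seed = as.integer(seed),
      chemicalShift = as.numeric(chemicalShift))
}

## external field of a uniformly magnetized sphere (Lorentz term ignored):
## strength * (3 cos^2 theta - 1) / r^3 outside, 0 inside; theta from the
## main-field (z) axis
.dipoleField <- function(coords, center, radius, strength) {
  dx <- coords[, 1] - center[1]
  dy <- coords[, 2] - center[2]
  dz <- coords[, 3] - center[3]
  r2 <- dx * dx + dy * dy + dz * dz
  out <- numeric(nrow(coords))
  ext <- r2 > radius^2
  cos2 <- dz[ext]^2 / r2[ext]
  out[ext] <- strength * (3 * cos2 - 1) / r2[ext]^1.5
  out
}

#' Generate a synthetic phantom data set
#'
#' Builds the ground-truth field (shim-basis background plus gas-pocket
#' dipoles plus Gaussian noise), the tissue model (water inside the torso,
#' a fat ring of fat fraction 0.95 at the torso boundary), and
#' forward-simulates the dual-echo field-map pair (in-phase echo spacing)
#' and the three-point Dixon triplet. Reproducible: the spec seed fixes
#' all randomness.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param basis the \linkS4class{ShimBasis} the background coefficients
#'   refer to
#' @param te1 first field-map echo time (ms); the second is the in-phase
#'   echo \code{\link{inPhaseTE2}}
#' @param dixonTEs the three Dixon echo times (ms)
#' @return list with \code{echoes} (field-map pair), \code{dixonEchoes}
#'   (triplet), \code{field} (ground-truth \linkS4class{FieldMap}, valid
#'   over the torso), \code{brainMask}, \code{fatMask}, \code{torsoMask}
#'   (\linkS4class{RegionMask}s), \code{coeffs} (ground truth),
#'   \code{floorSd} (Hz: brain-ROI SD of the best unconstrained shim-basis
#'   fit of the true field, the floor any solver can reach), and
#'   \code{spec}
#' @export
generatePhantom <- function(spec, basis = shimBasis(), te1 = 4.6,
                            dixonTEs = c(4.6, 5.6, 6.6)) {
  stopifnot(is(spec, "PhantomSpec"))
  dm <- spec@dim
  origin <- .centeredOrigin(dm, spec@spacing)
  nVox <- prod(dm)
  coords <- .voxelCoordinates(dm, spec@spacing, origin, seq_len(nVox))

  ## tissue geometry
  a <- spec@torsoSemiaxes[1]; b <- spec@torsoSemiaxes[2]
  q <- (coords[, 1] / a)^2 + (coords[, 2] / b)^2
  torso <- q <= 1
  ai <- a - spec@fatRingThickness; bi <- b - spec@fatRingThickness
  inner <- (coords[, 1] / ai)^2 + (coords[, 2] / bi)^2 <= 1
  ring <- torso & !inner
  W <- ifelse(torso, ifelse(ring, 0.05, 1), 0)
  Fa <- ifelse(ring, 0.95, 0)
  ## gas pockets carry no signal
  for (g in spec@gasPockets) {
    r2 <- (coords[, 1] - g$center[1])^2 + (coords[, 2] - g$center[2])^2 +
      (coords[, 3] - g$center[3])^2
    W[r2 <= g$radius^2] <- 0
    Fa[r2 <= g$radius^2] <- 0
  }

  ## ground-truth field
  field <- drop(evaluateBasis(coords, basis) %*% spec@backgroundCoeffs)
  for (g in spec@gasPockets)
    field <- field + .dipoleField(coords, g$center, g$radius, g$strength)

  out <- .withSeed(spec@seed, {
    if (spec@noiseSd > 0)
      field <- field + stats::rnorm(nVox, 0, spec@noiseSd)
    simEcho <- function(te) {
      teS <- te / 1000
      s <- (W + Fa * exp(2i * pi * spec@chemicalShift * teS)) *
        exp(2i * pi * field * teS)
      if (is.finite(spec@snr))
        s <- s + complex(real = stats::rnorm(nVox, 0, 1 / spec@snr),
                         imaginary = stats::rnorm(nVox, 0, 1 / spec@snr))
      echoImage(array(s, dm), te = te, spacing = spec@spacing,
                origin = origin)
    }
    te2 <- inPhaseTE2(te1, abs(spec@chemicalShift))
    list(echoes = list(simEcho(te1), simEcho(te2)),
         dixonEchoes = lapply(dixonTEs, simEcho),
         field = field)
  })

  fmTruth <- fieldMap(array(out$field, dm), spacing = spec@spacing,
                      origin = origin, valid = array(torso, dm))
  torsoMask <- regionMask(array(torso, dm), "other", spec@spacing, origin)
  fatMask <- regionMask(array(ring, dm), "fat", spec@spacing, origin)
  brainMask <- makeEllipsoidROI(spec@brain, fmTruth)

  ## best-achievable residual floor: unregularized, unbounded fit of the
  ## true field over the brain ROI
  Ab <- buildDesignMatrix(brainMask, basis)
  bb <- fmTruth@freq[Ab@voxelIndex]
  resid <- bb - drop(Ab@values %*% qr.solve(Ab@values, bb))
  floorSd <- sqrt(mean((resid - mean(resid))^2))

  list(echoes = out$echoes, dixonEchoes = out$dixonEchoes,
       field = fmTruth, brainMask = brainMask, fatMask = fatMask,
       torsoMask = torsoMask, coeffs = spec@backgroundCoeffs,
       floorSd = floorSd, spec = spec)
}

#' Named library of phantom scenarios
#'
#' Three presets probing the regimes the solvers must handle:
#' \describe{
#'   \item{pure-SH}{noise-free background field exactly representable in
#'     the shim basis; coefficients are exactly recoverable and the fat
#'     constraints stay inactive.}
#'   \item{fat-conflict}{a gas-pocket dipole under the fetal brain forces
#'     the localized fit to large coefficients whose extrapolation drives
#'     the fat-ring residual outside the saturation band; the constrained
#'     fit must pull it back.}
#'   \item{gas}{a strong dipole adjacent to the brain ROI that no first/
#'     second-order field can fully correct: the localized residual SD
#'     stays well above the pure-SH case.}
#' }
#'
#' @param seed RNG seed stored in every spec
#' @return named list of \linkS4class{PhantomSpec} objects
#' @export
scenarioLibrary <- function(seed = 1L) {
  coeffs <- c(20, -15, 12, 30, -22, 18, 25, -20)
  list(
    "pure-SH" = phantomSpec(backgroundCoeffs = coeffs, seed = seed),
    "fat-conflict" = phantomSpec(
      backgroundCoeffs = coeffs,
      brain = ellipsoidROI(c(15, 55, 0), c(35, 30, 25)),
      gasPockets = list(list(center = c(15, 12, 0), radius = 14,
                             strength = 5e5)),
      noiseSd = 0, snr = 200, seed = seed),
    "gas" = phantomSpec(
      backgroundCoeffs = coeffs,
      gasPockets = list(list(center = c(72, 25, 0), radius = 12,
                             strength = 4e5)),
      noiseSd = 0, snr = 200, seed = seed)
  )
}
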