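#' Compute a (wrapped) B0 field map from a dual-echo acquisition
#'
#' Per-voxel off-resonance frequency from the inter-echo phase accrual:
#' the phase of \code{echo2 * Conj(echo1)} divided by \code{2*pi*dTE} with
#' dTE in seconds. Values therefore lie in \code{(-1/(2 dTE), +1/(2 dTE)]}
#' and frequencies outside that window alias (wrap). With the echo spacing
#' chosen so that water and fat are in phase (dTE = 1/|chemical shift|),
#' pure fat accrues a full cycle between echoes and reads ~0 Hz, so the
#' map shows the B0 deviation for fat and water tissue alike.
#'
#' The validity mask keeps voxels whose geometric-mean echo magnitude
#' exceeds \code{validFraction} of the 99th-percentile magnitude, excluding
#' background air without clipping low-signal fetal tissue.
#'
#' @param echo1,echo2 co-registered \linkS4class{EchoImage}s, te2 > te1
#' @param validFraction magnitude threshold as a fraction of the robust
#'   (99th percentile) maximum; default 0.05
#' @return a \linkS4class{FieldMap} with wrapped frequencies (Hz)
#' @examples
#' e1 <- echoImage(array(complex(modulus = 1, argument = 0), c(4, 4, 1)),
#'                 te = 4.6, spacing = c(5, 5, 10))
#' e2 <- echoImage(array(complex(modulus = 1, argument = pi / 2), c(4, 4, 1)),
#'                 te = 6.9, spacing = c(5, 5, 10))
#' freq(computeFieldMap(e1, e2))[1, 1, 1]  # ~108.7 Hz
#' @export
computeFieldMap <- function(echo1, echo2, validFraction = 0.05) {
  stopifnot(is(echo1, "EchoImage"), is(echo2, "EchoImage"))
  .stopGeometry(echo1, echo2, what = "echoes")
  dte <- (echo2@te - echo1@te) / 1000  # s
  if (dte <= 0)
    stop("echo2 must have the later echo time (dTE > 0)", call. = FALSE)
  phase <- Arg(echo2@data * Conj(echo1@data))
  frq <- phase / (2 * pi * dte)
  mag <- sqrt(Mod(echo1@data) * Mod(echo2@data))
  thr <- validFraction * stats::quantile(mag, 0.99, names = FALSE)
  valid <- array(mag > thr, dim(mag))
  frq[!valid & !is.finite(frq)] <- 0
  fieldMap(frq, spacing = echo1@spacing, origin = echo1@origin,
           valid = valid)
}

#' In-phase second echo time for a water-fat chemical shift
#'
#' The echo spacing that brings water and fat back in phase is one full
#' chemical-shift cycle, 1/|shift|; the second echo time is reported at
#' 0.1 ms precision as scanner interfaces quote it.
#'
#' @param te1 first echo time (ms)
#' @param chemicalShift water-fat shift (Hz), nonzero
#' @return second echo time (ms), rounded to 0.1 ms
#' @examples
#' inPhaseTE2(4.6, 434)  # 6.9
#' @export
inPhaseTE2 <- function(te1, chemicalShift) {
  if (length(chemicalShift) != 1L || !is.finite(chemicalShift) ||
      chemicalShift == 0)
    stop("chemicalShift must be a single nonzero frequency (Hz)",
         call. = FALSE)
  round(te1 + 1000 / abs(chemicalShift), 1)
}

#' Unwrap a field map slice by slice
#'
#' Converts the wrapped frequencies back to inter-echo phase (radians),
#' applies Goldstein branch-cut unwrapping per slice
#' (\code{\link{goldsteinUnwrap}}), aligns the per-slice 2*pi ambiguity by
#' minimizing the median inter-slice difference inside the valid mask, and
#' converts back to Hz.
#'
#' @param fm a wrapped \linkS4class{FieldMap}
#' @param deltaTE the echo spacing that produced it (ms)
#' @return a \linkS4class{FieldMap} with unwrapped frequencies; voxels the
#'   unwrapper could not reach are dropped from the valid mask
#' @export
unwrapFieldMap <- function(fm, deltaTE) {
  stopifnot(is(fm, "FieldMap"), deltaTE > 0)
  dte <- deltaTE / 1000
  phase <- fm@freq * (2 * pi * dte)
  u <- goldsteinUnwrap(phase, fm@valid)
  reached <- fm@valid & u$reached
  up <- u$phase
  ## anchor the remaining global 2*pi multiple so the median unwrapped
  ## phase over valid tissue lies within half a cycle: the shim fit has no
  ## 0th-order term, so an unanchored full-cycle offset would bias it
  if (any(reached)) {
    k <- round(stats::median(up[reached]) / (2 * pi))
    up <- up - 2 * pi * k
  }
  fieldMap(up / (2 * pi * dte), spacing = fm@spacing,
           origin = fm@origin, valid = reached)
}
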