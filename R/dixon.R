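## Three-point Dixon water-fat separation with a single-peak fat model.
##
## Per voxel the echoes follow s(te) = (W + F e^{i 2 pi sigma te}) e^{i phi0}
## e^{i 2 pi f0 te} with W, F >= 0 magnitudes, sigma the fat chemical shift
## and f0 the local off-resonance. For a given f0 the demodulated samples
## b_k = s_k e^{-i 2 pi f0 te_k} live (up to noise) in the fixed complex
## span of {1, u_k} with u_k = e^{i 2 pi sigma te_k}, so the least-squares
## residual is ||s||^2 - b^H P b with a projector P that does not depend on
## f0. With uniform echo spacing dTE the quadratic form collapses to a
## two-harmonic trigonometric polynomial in alpha = 2 pi f0 dTE:
##   residual(alpha) = ||s||^2 - (c0 + 2 Re(c1 e^{i alpha} + c2 e^{2 i alpha}))
## whose per-voxel constants c1, c2 come from the echo cross-products. The
## global maximizer of the trig polynomial is found on a dense grid and
## polished by vectorized Newton steps, giving machine-precision f0 without
## per-voxel iteration; W and F then follow from the fixed 2x2 Gram solve.

#' Separate water and fat from a three-point Dixon acquisition
#'
#' Solves the two-species single-peak model per voxel for the water and fat
#' magnitudes and the local off-resonance f0 (identified within
#' \code{(-1/(2 dTE), 1/(2 dTE)]}). Echoes must be uniformly spaced; the
#' echo spacing must not put the fat phasor at the same angle on every echo
#' (that degenerate spacing makes water and fat indistinguishable).
#'
#' @param echoes list of three co-registered \linkS4class{EchoImage}s with
#'   uniformly spaced echo times
#' @param chemicalShift fat resonance offset from water (Hz); default -430
#'   (3 T)
#' @return list with \code{water}, \code{fat} (nonnegative magnitude
#'   arrays), \code{f0} (Hz array), \code{residual} (model misfit array),
#'   and \code{spacing}, \code{origin}
#' @examples
#' ## forward-simulate one voxel and invert
#' te <- c(4.6, 5.6, 6.6); sig <- -430
#' s <- (0.3 + 0.7 * exp(2i * pi * sig * te / 1000)) *
#'   exp(2i * pi * 20 * te / 1000)
#' es <- lapply(1:3, function(k)
#'   echoImage(array(s[k], c(1, 1, 1)), te[k], c(5, 5, 10)))
#' d <- dixonFatWater(es)
#' c(d$water, d$fat, d$f0)  # ~0.3, 0.7, 20
#' @export
dixonFatWater <- function(echoes, chemicalShift = -430) {
  stopifnot(is.list(echoes), length(echoes) == 3L)
  for (e in echoes) stopifnot(is(e, "EchoImage"))
  .stopGeometry(echoes[[1]], echoes[[2]], echoes[[3]], what = "Dixon echoes")
  te <- vapply(echoes, function(e) e@te, 0) / 1000  # s
  dte <- diff(te)
  if (abs(dte[1] - dte[2]) > 1e-9 * dte[1])
    stop("Dixon echoes must be uniformly spaced", call. = FALSE)
  dte <- dte[1]
  if (dte <= 0) stop("echo times must be increasing", call. = FALSE)
  u <- exp(2i * pi * chemicalShift * te)
  ## degenerate spacing: fat phasor identical at all echoes
  if (max(Mod(u - u[1])) < 1e-6)
    stop("degenerate echo spacing: fat phasor is identical at all echoes",
         call. = FALSE)
  B <- cbind(rep(1 + 0i, 3), u)
  G <- Conj(t(B)) %*% B
  P <- B %*% solve(G, Conj(t(B)))  # Hermitian projector, f0-independent

  dm <- dim(echoes[[1]]@data)
  s1 <- as.vector(echoes[[1]]@data)
  s2 <- as.vector(echoes[[2]]@data)
  s3 <- as.vector(echoes[[3]]@data)
  ## c_m = sum over j-k = m of P[j,k] conj(s_j) s_k
  c1 <- P[2, 1] * Conj(s2) * s1 + P[3, 2] * Conj(s3) * s2
  c2 <- P[3, 1] * Conj(s3) * s1
  ## maximize g(alpha) = Re(c1 e^{i alpha} + c2 e^{2 i alpha}); incremental
  ## argmax over a dense grid keeps memory at O(voxels). The polynomial can
  ## carry two near-equal maxima: a single-species voxel fits exactly both
  ## as water at f0 and as fat at f0 + shift, so the runner-up (well away
  ## from the winner) is tracked too and near-ties are resolved toward the
  ## smaller |f0| (the interpretation with the field inside the mapping
  ## window).
  nGrid <- 720L
  alphaGrid <- seq(-pi, pi, length.out = nGrid + 1L)[-1L]
  n <- length(c1)
  alpha <- rep(alphaGrid[1], n); gBest <- rep(-Inf, n)
  alpha2 <- alpha; gBest2 <- gBest
  sep <- abs(2 * pi * chemicalShift * dte) / 2  # half the swap separation
  re1 <- Re(c1); im1 <- Im(c1); re2 <- Re(c2); im2 <- Im(c2)
  for (a in alphaGrid) {
    g <- re1 * cos(a) - im1 * sin(a) + re2 * cos(2 * a) - im2 * sin(2 * a)
    upd <- g > gBest
    ## displaced former winner becomes runner-up when far from new winner
    far <- upd & pmin(abs(alpha - a), 2 * pi - abs(alpha - a)) > sep
    gBest2[far] <- gBest[far]; alpha2[far] <- alpha[far]
    gBest[upd] <- g[upd]; alpha[upd] <- a
    upd2 <- !upd & g > gBest2 &
      pmin(abs(alpha - a), 2 * pi - abs(alpha - a)) > sep
    gBest2[upd2] <- g[upd2]; alpha2[upd2] <- a
  }
  polish <- function(alpha) {
    ## Newton on g'(alpha) = 0 (vectorized); g'' < 0 at a maximum
    for (it in 1:6) {
      z1 <- exp(1i * alpha); z2 <- z1 * z1
      g1 <- Re(1i * c1 * z1 + 2i * c2 * z2)
      g2 <- Re(-c1 * z1 - 4 * c2 * z2)
      step <- ifelse(g2 < 0, g1 / g2, 0)
      alpha <- alpha - pmin(pmax(step, -0.05), 0.05)
    }
    alpha
  }
  gAt <- function(alpha) {
    z1 <- exp(1i * alpha)
    Re(c1 * z1 + c2 * z1 * z1)
  }
  alpha <- polish(alpha); alpha2 <- polish(alpha2)
  tol <- 0.02 * (Mod(c1) + Mod(c2))
  swap <- is.finite(gBest2) & gAt(alpha2) > gAt(alpha) - tol &
    abs(alpha2) < abs(alpha)
  alpha[swap] <- alpha2[swap]
  f0 <- alpha / (2 * pi * dte)
  ## amplitudes from the fixed Gram system on demodulated samples
  b1 <- s1 * exp(-2i * pi * f0 * te[1])
  b2 <- s2 * exp(-2i * pi * f0 * te[2])
  b3 <- s3 * exp(-2i * pi * f0 * te[3])
  rhs1 <- b1 + b2 + b3                                   # B^H b, row 1
  rhs2 <- Conj(u[1]) * b1 + Conj(u[2]) * b2 + Conj(u[3]) * b3
  Gi <- solve(G)
  w <- Gi[1, 1] * rhs1 + Gi[1, 2] * rhs2
  f <- Gi[2, 1] * rhs1 + Gi[2, 2] * rhs2
  normSq <- Mod(s1)^2 + Mod(s2)^2 + Mod(s3)^2
  z1 <- exp(1i * alpha); z2 <- z1 * z1
  c0 <- Re(P[1, 1]) * Mod(s1)^2 + Re(P[2, 2]) * Mod(s2)^2 +
    Re(P[3, 3]) * Mod(s3)^2
  resid <- pmax(normSq - (c0 + 2 * Re(c1 * z1 + c2 * z2)), 0)
  list(water = array(Mod(w), dm), fat = array(Mod(f), dm),
       f0 = array(f0, dm), residual = array(resid, dm),
       spacing = echoes[[1]]@spacing, origin = echoes[[1]]@origin)
}

#' Segment the fat region by thresholding the Dixon fat image
#'
#' A voxel belongs to the fat mask when its fat fraction F/(W+F) exceeds
#' the threshold and its total magnitude W+F is above the noise floor
#' (a fraction of the 99th-percentile magnitude).
#'
#' @param fat,water nonnegative magnitude arrays from
#'   \code{\link{dixonFatWater}}
#' @param threshold fat-fraction threshold in (0, 1); default 0.5
#' @param magnitudeFraction noise-floor fraction of the robust maximum;
#'   default 0.05
#' @param spacing,origin grid geometry of the images (mm)
#' @return a \linkS4class{RegionMask} labeled \code{"fat"}; an empty mask
#'   is returned with a warning (constraints are then vacuous)
#' @export
segmentFat <- function(fat, water, threshold = 0.5, magnitudeFraction = 0.05,
                       spacing, origin = c(0, 0, 0)) {
  stopifnot(threshold > 0, threshold < 1,
            identical(dim(fat), dim(water)))
  total <- fat + water
  floorMag <- magnitudeFraction * stats::quantile(total, 0.99, names = FALSE)
  frac <- ifelse(total > 0, fat / total, 0)
  m <- array(frac > threshold & total > floorMag, dim(fat))
  if (!any(m))
    warning("empty fat mask: fat constraints will be vacuous", call. = FALSE)
  regionMask(m, label = "fat", spacing = spacing, origin = origin)
}

#' Rasterize an ellipsoidal ROI onto a grid
#'
#' A voxel is included when its center lies inside the ellipsoid,
#' restricted to the ROI's slice range.
#'
#' @param roi an \linkS4class{EllipsoidROI}
#' @param template a \linkS4class{FieldMap} (or any gridded object)
#'   supplying the grid geometry
#' @return a \linkS4class{RegionMask} labeled \code{"brain"}
#' @export
makeEllipsoidROI <- function(roi, template) {
  stopifnot(is(roi, "EllipsoidROI"))
  dm <- dim(.gridData(template))
  ax <- .gridAxes(dm, template@spacing, template@origin)
  qx <- ((ax$x - roi@center[1]) / roi@semiaxes[1])^2
  qy <- ((ax$y - roi@center[2]) / roi@semiaxes[2])^2
  qz <- ((ax$z - roi@center[3]) / roi@semiaxes[3])^2
  m <- outer(outer(qx, qy, `+`), qz, `+`) <= 1
  if (length(roi@sliceRange)) {
    keep <- array(FALSE, dm)
    sl <- roi@sliceRange[roi@sliceRange >= 1L & roi@sliceRange <= dm[3]]
    keep[, , sl] <- TRUE
    m <- m & keep
  }
  if (!any(m))
    stop("ellipsoid does not intersect the grid: unshimmable ROI",
         call. = FALSE)
  regionMask(m, label = "brain", spacing = template@spacing,
             origin = template@origin)
}
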