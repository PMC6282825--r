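## Independent oracles and shared fixtures, kept deliberately naive and
## separate from the package's implementation paths.

wrapPi <- function(x) x - 2 * pi * round(x / (2 * pi))

## Itoh 1-D integration along the first column, then along each row;
## valid only on residue-free slices
itohUnwrap2D <- function(w) {
  u <- w
  u[, 1] <- cumsum(c(w[1, 1], wrapPi(diff(w[, 1]))))
  for (i in seq_len(nrow(w)))
    u[i, ] <- cumsum(c(u[i, 1], wrapPi(diff(w[i, ]))))
  u
}

## exhaustive loop-integral residue detection (double loop)
residueCountOracle <- function(p) {
  n1 <- nrow(p); n2 <- ncol(p)
  count <- 0L
  for (i in seq_len(n1 - 1L)) for (j in seq_len(n2 - 1L)) {
    s <- wrapPi(p[i + 1, j] - p[i, j]) + wrapPi(p[i + 1, j + 1] - p[i + 1, j]) +
      wrapPi(p[i, j + 1] - p[i + 1, j + 1]) + wrapPi(p[i, j] - p[i, j + 1])
    count <- count + abs(as.integer(round(s / (2 * pi))))
  }
  count
}

## forward Dixon signal for one voxel
dixonForward <- function(W, Fa, f0, te, shift = -430) {
  (W + Fa * exp(2i * pi * shift * te / 1000)) * exp(2i * pi * f0 * te / 1000)
}

## dense grid search over (W, F, f0) minimizing the forward-model misfit
dixonGridOracle <- function(s, te, shift = -430,
                            wGrid = seq(0, 1.2, by = 0.05),
                            fGrid = seq(0, 1.2, by = 0.05),
                            f0Grid = seq(-495, 495, by = 5)) {
  best <- NULL; bestR <- Inf
  for (f0 in f0Grid) {
    base <- exp(2i * pi * f0 * te / 1000)
    fat <- exp(2i * pi * shift * te / 1000)
    for (W in wGrid) for (Fa in fGrid) {
      r <- sum(Mod(s - (W + Fa * fat) * base)^2)
      if (r < bestR) { bestR <- r; best <- c(W = W, F = Fa, f0 = f0) }
    }
  }
  list(par = best, residual = bestR)
}

## brute-force ellipsoid voxel membership
ellipsoidCountOracle <- function(center, semiaxes, dm, spacing, origin) {
  count <- 0L
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    p <- origin + (c(i, j, k) - 1) * spacing
    if (sum(((p - center) / semiaxes)^2) <= 1) count <- count + 1L
  }
  count
}

## small-tip Fourier response of an RF envelope: flip(f) in radians
smallTipFlipOracle <- function(pulse, offsets) {
  n <- length(pulse@envelope)
  dt <- pulse@duration / n / 1000
  t <- ((seq_len(n) - 0.5) * dt) - pulse@duration / 2000
  vapply(offsets, function(f)
    2 * pi * Mod(sum(pulse@envelope * exp(-2i * pi * f * t)) * dt), 0)
}

## streaming (Welford) population SD
streamingSdOracle <- function(x) {
  m <- 0; s <- 0; n <- 0
  for (xi in x) {
    n <- n + 1
    d <- xi - m
    m <- m + d / n
    s <- s + d * (xi - m)
  }
  sqrt(s / n)
}

## tiny geometry used across tests
tinyGrid <- function(dm = c(9, 9, 3), spacing = c(5, 5, 10)) {
  list(dm = as.integer(dm), spacing = spacing,
       origin = -(dm - 1) / 2 * spacing)
}

## a hand-built 2-coefficient toy problem with fat constraints
toyProblem2 <- function(lambda = 0.03, d1 = -30, d2 = 10) {
  set.seed(42)
  A <- cbind(runif(10, -1, 1), runif(10, -1, 1))
  sTrue <- c(12, -7)
  b <- drop(A %*% sTrue) + rnorm(10, 0, 2)
  C <- cbind(runif(4, 1, 2), runif(4, -2, -1))
  bFat <- drop(C %*% sTrue) + c(5, -35, 20, 0)
  shimProblemMatrices(A, b, lambda = lambda, lb = -50, ub = 50,
                      C = C, bFat = bFat, d1 = d1, d2 = d2)
}

## generated phantoms are reused across test files
phantomCache <- new.env(parent = emptyenv())
cachedPhantom <- function(preset, seed = 1L) {
  key <- paste0(preset, "-", seed)
  if (is.null(phantomCache[[key]]))
    phantomCache[[key]] <- generatePhantom(scenarioLibrary(seed)[[preset]])
  phantomCache[[key]]
}
pipelineCache <- new.env(parent = emptyenv())
cachedPipeline <- function(preset, seed = 1L, ...) {
  key <- paste0(preset, "-", seed)
  if (is.null(pipelineCache[[key]]))
    pipelineCache[[key]] <- runPipeline(preset, seed = seed, ...)
  pipelineCache[[key]]
}
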