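test_that("the generator is bit-reproducible under a fixed seed", {
  spec <- phantomSpec(backgroundCoeffs = c(20, -15, 12, 30, -22, 18, 25, -20),
                      noiseSd = 3, snr = 100, seed = 99L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(a$echoes[[1]]@data, b$echoes[[1]]@data)
  expect_identical(a$dixonEchoes[[3]]@data, b$dixonEchoes[[3]]@data)
  expect_identical(freq(a$field), freq(b$field))
  ## and does not disturb the caller's RNG stream
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(generatePhantom(spec)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("geometry violations are rejected at spec construction", {
  expect_error(phantomSpec(brain = ellipsoidROI(c(120, 0, 0),
                                                c(40, 35, 25))),
               "inside the torso")
  expect_error(phantomSpec(fatRingThickness = 130), "thinner")
})

test_that("the simulated echoes reproduce the ground-truth field", {
  ph <- cachedPhantom("pure-SH")
  fmW <- computeFieldMap(ph$echoes[[1]], ph$echoes[[2]])
  fm <- unwrapFieldMap(fmW, ph$echoes[[2]]@te - ph$echoes[[1]]@te)
  v <- validMask(fm) & validMask(ph$field)
  nonFat <- v & !maskArray(ph$fatMask)
  err <- abs(freq(fm) - freq(ph$field))
  expect_lt(max(err[nonFat]), 0.1)
  ## fat-ring voxels carry only the small in-phase approximation offset
  expect_lt(max(err[v & maskArray(ph$fatMask)]), 10)
})

test_that("Dixon inversion of the phantom recovers the fat ring", {
  ph <- cachedPhantom("pure-SH")
  d <- dixonFatWater(ph$dixonEchoes, ph$spec@chemicalShift)
  frac <- d$fat / pmax(d$fat + d$water, 1e-12)
  ring <- maskArray(ph$fatMask)
  torso <- maskArray(ph$torsoMask)
  expect_gt(min(frac[ring]), 0.9)
  expect_lt(max(frac[torso & !ring]), 0.1)
  ## thresholded mask size within 5% of the true ring voxel count
  m <- segmentFat(d$fat, d$water, 0.5, spacing = d$spacing,
                  origin = d$origin)
  expect_equal(sum(maskArray(m)), sum(ring), tolerance = 0.05)
})

test_that("in-bounds ground-truth coefficients are exactly recoverable", {
  ph <- cachedPhantom("pure-SH")
  fm <- unwrapFieldMap(computeFieldMap(ph$echoes[[1]], ph$echoes[[2]]),
                       ph$echoes[[2]]@te - ph$echoes[[1]]@te)
  pr <- shimProblem(fm, ph$brainMask, lambda = 0)
  s <- shimCoefficients(solveLocalized(pr))
  d <- sqrt(colMeans(pr@A^2))
  rmseNorm <- sqrt(mean((d * (s - ph$coeffs))^2)) /
    sqrt(mean((d * ph$coeffs)^2))
  expect_lt(rmseNorm, 1e-6)
  ## with the study regularization the residual stays tiny even though
  ## coefficients shift slightly along ill-conditioned directions
  s03 <- shimCoefficients(solveLocalized(shimProblem(fm, ph$brainMask,
                                                     lambda = 0.03)))
  expect_lt(max(abs(s03 - ph$coeffs)), 0.5)
})

test_that("recovery error scales with the injected field noise", {
  rmse <- vapply(c(0, 1, 5), function(sdn) {
    spec <- phantomSpec(backgroundCoeffs = c(20, -15, 12, 30, -22, 18,
                                             25, -20),
                        noiseSd = sdn, seed = 21L)
    ph <- generatePhantom(spec)
    pr <- shimProblem(ph$field, ph$brainMask, lambda = 0)
    sqrt(mean((shimCoefficients(solveLocalized(pr)) - ph$coeffs)^2))
  }, 0)
  expect_lt(rmse[1], 1e-9)
  expect_true(all(diff(rmse) > 0))
  expect_equal(rmse[3] / rmse[2], 5, tolerance = 0.25)
})

test_that("the scenario library spans the three intended regimes", {
  resPure <- cachedPipeline("pure-SH")
  resConf <- cachedPipeline("fat-conflict")
  resGas <- cachedPipeline("gas")
  ## (i) constraints inactive: both solutions coincide
  expect_equal(shimCoefficients(resPure$solutionConstrained),
               shimCoefficients(resPure$solutionLocalized),
               tolerance = 1e-6)
  ## (ii) localized drives fat out of band; constrained pulls it back
  expect_gt(resConf$localized@fatOutFraction, 0)
  expect_equal(resConf$constrained@fatOutFraction, 0)
  ## (iii) the dipole is outside the shim-basis span
  expect_gt(resGas$localized@roiSdHz, 2 * resPure$localized@roiSdHz)
  expect_gt(resGas$localized@roiSdHz, 1)
})

test_that("solvers reach the recorded best-fit floor", {
  ph <- cachedPhantom("gas")
  res <- cachedPipeline("gas")
  expect_lt(res$localized@roiSdHz, 1.05 * ph$floorSd + 0.05)
  expect_gt(res$localized@roiSdHz, 0.95 * ph$floorSd - 0.05)
})
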