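g <- tinyGrid(c(5, 2, 1), c(5, 5, 10))

test_that("ROI SD is the population SD over masked valid voxels", {
  fm <- fieldMap(array(7, g$dm), g$spacing, g$origin)
  mask <- regionMask(array(TRUE, g$dm), "brain", g$spacing, g$origin)
  expect_equal(roiSD(fm, mask), 0)
  ## two voxels at 0 and 20 -> population SD 10
  f <- array(0, g$dm); f[2, 1, 1] <- 20
  m2 <- array(FALSE, g$dm); m2[1:2, 1, 1] <- TRUE
  expect_equal(roiSD(fieldMap(f, g$spacing, g$origin),
                     regionMask(m2, "brain", g$spacing, g$origin)), 10)
  expect_error(roiSD(fm, regionMask(array(FALSE, g$dm), "brain",
                                    g$spacing, g$origin)), "empty")
})

test_that("ROI SD matches an independent streaming-variance oracle", {
  res <- cachedPipeline("fat-conflict")
  v <- freq(res$residualLocalized)[maskArray(res$brainMask) &
                                     validMask(res$residualLocalized)]
  expect_equal(res$localized@roiSdHz, streamingSdOracle(v),
               tolerance = 1e-9)
})

test_that("fat out-of-band counts with closed band endpoints", {
  f <- array(0, c(10, 1, 1))
  f[1:3] <- c(-400, 150, 101)   # 3 outside
  f[4] <- 100                   # exactly at d2: inside
  f[5] <- -350                  # exactly at d1: inside
  fm <- fieldMap(f, c(5, 5, 10))
  mask <- regionMask(array(TRUE, c(10, 1, 1)), "fat", c(5, 5, 10))
  expect_equal(fatOutOfBand(fm, mask, -350, 100), 30)
  allIn <- fieldMap(array(0, c(10, 1, 1)), c(5, 5, 10))
  expect_equal(fatOutOfBand(allIn, mask, -350, 100), 0)
})

test_that("water-fat shift arithmetic matches the closed form", {
  expect_equal(wfsPixels(0, etl = 73, fSwitch = 490), 0)
  ## 434 Hz, 490 Hz switching (1.0204 ms spacing), 73 echoes -> 32.3 px
  expect_equal(wfsPixels(434, etl = 73, fSwitch = 490), 32.33,
               tolerance = 1e-3)
  expect_equal(wfsPixels(434, etl = 146, fSwitch = 490),
               2 * wfsPixels(434, etl = 73, fSwitch = 490))
  expect_equal(wfsPixels(434, echoSpacing = 1.0204, etl = 73),
               434 * 73 * 1.0204 / 1000)
})

test_that("displacement maps are linear in the residual", {
  f <- array(10, c(4, 4, 1))
  fm <- fieldMap(f, c(5, 5, 10))
  d <- displacementMap(fm, echoSpacing = 1.0204, etl = 73)
  expect_equal(d[1, 1, 1], 0.745, tolerance = 1e-3)
  expect_equal(attr(d, "phaseAxis"), 2L)
  z <- displacementMap(fieldMap(array(0, c(4, 4, 1)), c(5, 5, 10)),
                       1.0204, 73)
  expect_true(all(z == 0))
  d2 <- displacementMap(fieldMap(2 * f, c(5, 5, 10)), 1.0204, 73)
  expect_equal(as.numeric(d2), as.numeric(2 * d))
})

test_that("the pipeline is deterministic and reports serialize losslessly", {
  res1 <- cachedPipeline("pure-SH")
  res2 <- runPipeline("pure-SH", seed = 1L)
  expect_identical(res1$localized@roiSdHz, res2$localized@roiSdHz)
  expect_identical(shimCoefficients(res1$solutionConstrained),
                   shimCoefficients(res2$solutionConstrained))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writeShimReport(res1$localized, f1)
  writeShimReport(res2$localized, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- readShimReport(f1)
  expect_equal(back@roiSdHz, res1$localized@roiSdHz)
  expect_equal(back@fatOutFraction, res1$localized@fatOutFraction)
  expect_equal(back@mode, "localized")
})

test_that("the library-wide metric ordering holds", {
  for (preset in c("pure-SH", "fat-conflict", "gas")) {
    res <- cachedPipeline(preset)
    expect_lte(res$constrained@fatOutFraction,
               res$localized@fatOutFraction + 1e-9)
    expect_lte(res$constrained@roiSdHz, 1.2 * res$localized@roiSdHz + 0.01)
  }
})
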