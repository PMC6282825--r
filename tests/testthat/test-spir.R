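test_that("pulse construction obeys flip calibration", {
  expect_equal(max(Mod(designSpirPulse(flip = 0)@envelope)), 0)
  ## small-tip: simulated on-resonance rotation equals the nominal flip
  p10 <- designSpirPulse(7.5, 6.2, 10, 550)
  prof <- blochProfile(p10, -550)
  flipSim <- acos(prof@mz) * 180 / pi
  expect_equal(flipSim, 10, tolerance = 0.1)
  ## and at 110 degrees the center reaches cos(110)
  p110 <- designSpirPulse(7.5, 6.2, 110, 550)
  mzc <- blochProfile(p110, -550)@mz
  expect_equal(mzc, cos(110 * pi / 180), tolerance = 0.02)
})

test_that("far off-resonance magnetization is untouched", {
  p <- designSpirPulse(7.5, 6.2, 110, 550)
  prof <- blochProfile(p, c(-550 + 5000, -550 - 5000))
  expect_true(all(prof@mz >= 0.99))
})

test_that("the profile matches the small-tip Fourier oracle at 10 degrees", {
  p <- designSpirPulse(7.5, 6.2, 10, 550)
  offs <- seq(-550 - 300, -550 + 300, by = 10)  # main lobe
  prof <- blochProfile(p, offs)
  flipOracle <- smallTipFlipOracle(p, offs)
  expect_equal(prof@mz, cos(flipOracle), tolerance = 0.02)
})

test_that("a real symmetric envelope at zero offset gives a symmetric profile", {
  p <- designSpirPulse(7.5, 6.2, 110, 0)
  offs <- seq(10, 1000, by = 30)
  expect_equal(blochProfile(p, offs)@mz, blochProfile(p, -offs)@mz,
               tolerance = 1e-9)
})

test_that("profiles stay physical: mz within [-1, 1]", {
  p <- designSpirPulse(7.5, 6.2, 170, 300)
  prof <- blochProfile(p, seq(-2000, 1000, by = 7))
  expect_true(all(prof@mz >= -1 - 1e-9 & prof@mz <= 1 + 1e-9))
})

test_that("saturation bands are well-behaved in level and duration", {
  p <- designSpirPulse(7.5, 6.2, 110, 550)
  prof <- blochProfile(p, seq(-1800, 300, by = 2))
  b95 <- saturationBand(prof, 0.95)
  b90 <- saturationBand(prof, 0.90)
  ## monotone in level: the 90% band contains the 95% band
  expect_lte(b90@low, b95@low)
  expect_gte(b90@high, b95@high)
  ## degenerate band at level 1
  b1 <- saturationBand(prof, 1)
  expect_lt(b1@high - b1@low, 1)
  ## fat re-expression subtracts the chemical shift
  expect_equal(b95@fatLow, b95@low + 430)
  ## halving the duration at fixed tbp doubles the width within 5%
  w1 <- spirFatConstraints(duration = 7.5)
  w2 <- spirFatConstraints(duration = 3.75)
  expect_equal((w2@fatHigh - w2@fatLow) / (w1@fatHigh - w1@fatLow), 2,
               tolerance = 0.05)
})

test_that("signal-vs-offset curves reproduce the sweep behavior", {
  m <- spectralModel()
  sw <- signalVsOffset(m, c(seq(743, 543, by = -40), 503, 483))
  ## fat signal non-increasing while the band approaches the fat line
  fatHigh <- sw$fat[sw$offset >= 543]
  expect_true(all(diff(fatHigh) <= 1e-9))
  ## water only attenuates at low offsets
  expect_lt(sw$water[sw$offset == 483], sw$water[sw$offset == 543])
  expect_gt(min(sw$water[sw$offset >= 543]) / sw$water[sw$offset == 743],
            0.99)
  ## empty fat histogram gives zero fat signal
  m0 <- new("SpectralModel", fatFreq = numeric(0), fatWeight = numeric(0),
            waterFreq = m@waterFreq, waterWeight = m@waterWeight,
            t1Fat = 380, t1Water = 2000, spirDelay = m@spirDelay)
  sw0 <- signalVsOffset(m0, c(743, 583))
  expect_equal(sw0$fat, c(0, 0))
})

test_that("the default spectral model nulls fat at excitation", {
  m <- spectralModel()
  ## delay chosen so mz = cos(110 deg) recovers exactly to zero
  mz0 <- cos(110 * pi / 180)
  expect_equal(1 - (1 - mz0) * exp(-m@spirDelay / m@t1Fat), 0,
               tolerance = 1e-12)
  expect_equal(m@spirDelay, 112, tolerance = 0.01)
})
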