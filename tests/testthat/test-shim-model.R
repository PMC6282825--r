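test_that("basis terms vanish at the isocenter and obey the scale convention", {
  B <- evaluateBasis(c(0, 0, 0))
  expect_equal(unname(drop(B)), rep(0, 8))
  ## unit coefficient gives `scale` Hz at the reference radius on the
  ## principal axis of each term
  r0 <- 200
  expect_equal(unname(evaluateBasis(c(r0, 0, 0))[, "X"]), 1)
  expect_equal(unname(evaluateBasis(c(0, 0, r0))[, "Z2"]), 1)
  expect_equal(unname(evaluateBasis(c(r0, 0, r0) / sqrt(2))[, "ZX"]), 1)
  expect_equal(unname(evaluateBasis(c(r0, 0, 0))[, "X2-Y2"]), 1)
  sc <- shimBasis(scale = 10)
  expect_equal(unname(evaluateBasis(c(r0, 0, 0), sc)[, "X"]), 10)
})

test_that("every term is harmonic (numeric Laplacian vanishes)", {
  h <- 2  # mm
  pts <- rbind(c(37, -22, 54), c(-80, 60, -10), c(5, 5, 5))
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, ]
    lap <- evaluateBasis(p + c(h, 0, 0)) + evaluateBasis(p - c(h, 0, 0)) +
      evaluateBasis(p + c(0, h, 0)) + evaluateBasis(p - c(0, h, 0)) +
      evaluateBasis(p + c(0, 0, h)) + evaluateBasis(p - c(0, 0, h)) -
      6 * evaluateBasis(p)
    scale <- pmax(abs(evaluateBasis(p)), 1e-3)
    expect_lt(max(abs(lap) / scale / h^2), 1e-6)
  }
})

test_that("design matrix equals per-voxel evaluation in x-fastest order", {
  g <- tinyGrid(c(8, 7, 3))
  set.seed(11)
  m <- array(runif(prod(g$dm)) < 0.3, g$dm)
  m[1] <- TRUE
  mask <- regionMask(m, "brain", g$spacing, g$origin)
  D <- buildDesignMatrix(mask)
  expect_equal(D@voxelIndex, which(m))  # deterministic order
  for (r in sample(nrow(D@values), 5)) {
    idx <- D@voxelIndex[r] - 1L
    ijk <- c(idx %% g$dm[1], (idx %/% g$dm[1]) %% g$dm[2],
             idx %/% (g$dm[1] * g$dm[2])) + 1L
    p <- g$origin + (ijk - 1) * g$spacing
    expect_equal(D@values[r, ], drop(evaluateBasis(p)))
  }
})

test_that("x-symmetric masks zero the odd columns", {
  g <- tinyGrid(c(9, 9, 3))
  m <- array(FALSE, g$dm); m[3:7, 4:6, 2] <- TRUE  # symmetric about x=0
  D <- buildDesignMatrix(regionMask(m, "brain", g$spacing, g$origin))
  expect_equal(sum(D@values[, "X"]), 0)
  expect_equal(sum(D@values[, "ZX"]), 0)
  expect_equal(sum(D@values[, "XY"]), 0)
})

test_that("empty masks error for the brain but stay vacuous for fat", {
  g <- tinyGrid()
  empty <- regionMask(array(FALSE, g$dm), "fat", g$spacing, g$origin)
  expect_error(buildDesignMatrix(empty), "empty")
  D <- buildDesignMatrix(empty, onEmpty = "vacuous")
  expect_equal(nrow(D@values), 0L)
})

test_that("projection is the identity at s = 0 and cancels representable fields", {
  g <- tinyGrid(c(12, 12, 4))
  coords <- fetalshim:::.voxelCoordinates(g$dm, g$spacing, g$origin,
                                          seq_len(prod(g$dm)))
  sTrue <- c(30, -20, 10, 40, -25, 15, 35, -30)
  fm <- fieldMap(array(drop(evaluateBasis(coords) %*% sTrue), g$dm),
                 g$spacing, g$origin)
  expect_equal(freq(projectShim(fm, shimBasis(), rep(0, 8))), freq(fm))
  r <- projectShim(fm, shimBasis(), sTrue)
  expect_lt(max(abs(freq(r))), 1e-9)
})

test_that("projection is linear and composes additively in s", {
  g <- tinyGrid(c(10, 10, 3))
  set.seed(3)
  fm <- fieldMap(array(rnorm(prod(g$dm), 0, 30), g$dm), g$spacing, g$origin)
  s1 <- rnorm(8, 0, 20); s2 <- rnorm(8, 0, 20)
  r12 <- projectShim(fm, shimBasis(), s1 + s2)
  rSeq <- projectShim(projectShim(fm, shimBasis(), s1), shimBasis(), s2)
  expect_equal(freq(r12), freq(rSeq), tolerance = 1e-12)
  ## out-of-bounds coefficients only warn
  expect_warning(projectShim(fm, shimBasis(), rep(2000, 8),
                             limits = shimLimits()), "bounds")
})
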