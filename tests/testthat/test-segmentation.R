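# small uniform-sphere fixture: tumor SUV in a background SUV
sphereFixture <- function(tumorSUV = 10, bgSUV = 1, radius = 18.75,
                          dims = c(24, 24, 36), spacing = c(4.07, 4.07, 2.5)) {
  origin <- spacing / 2
  center <- dims * spacing / 2
  vol0 <- SUVVolume(array(bgSUV, dims), spacing = spacing, origin = origin)
  m <- sphereMask(vol0, center, 2 * radius)
  v <- voxelValues(vol0)
  v[voxelValues(m)] <- tumorSUV
  list(volume = SUVVolume(v, spacing = spacing, origin = origin),
       mask = m, center = center)
}

test_that("adaptive threshold matches hand-computed cases", {
  vol <- SUVVolume(array(10, c(3, 3, 3)))
  est <- VOIMask(array(TRUE, c(3, 3, 3)))
  expect_equal(nestleThreshold(vol, est, backgroundMean = 1), 4.0)
  expect_equal(nestleThreshold(vol, est, backgroundMean = 0), 3.0)
  for (s in c(2, 7.3, 21)) {
    volS <- SUVVolume(array(s, c(3, 3, 3)))
    expect_equal(nestleThreshold(volS, est, 0), 0.3 * s)
  }
  # {10, 9, 8, 5, 3}: core = values > 7 -> {10, 9, 8}, mean 9 -> 0.3*9 + 1
  v <- array(0.1, c(5, 1, 1)); v[, 1, 1] <- c(10, 9, 8, 5, 3)
  volH <- SUVVolume(v)
  estH <- VOIMask(array(TRUE, c(5, 1, 1)))
  expect_equal(nestleThreshold(volH, estH, 1), 3.7)
  expect_error(nestleThreshold(volH, estH, -1), "non-negative")
  expect_error(nestleThreshold(volH, VOIMask(array(FALSE, c(5, 1, 1))), 1),
               "empty")
})

test_that("threshold is affine in the background level", {
  set.seed(3)
  v <- array(runif(60, 1, 12), c(5, 4, 3))
  vol <- SUVVolume(v)
  est <- VOIMask(array(runif(60) < 0.5, c(5, 4, 3)))
  if (!any(voxelValues(est))) est <- VOIMask(array(TRUE, c(5, 4, 3)))
  for (delta in c(0.1, 1, 2.5)) {
    expect_equal(nestleThreshold(vol, est, 1 + delta) -
                 nestleThreshold(vol, est, 1), delta, tolerance = 1e-12)
  }
})

test_that("noiseless sphere converges to threshold 4.0 and the right volume", {
  for (radius in c(10, 15, 20, 25, 30)) {
    fx <- sphereFixture(radius = radius)
    del <- delineateTumor(fx$volume, fx$center)
    expect_true(del@converged)
    expect_equal(del@threshold, 4.0, tolerance = 1e-12)
    got <- sum(voxelValues(del@mask)) * voxelVolumeMm3(fx$volume) / 1000
    analytic <- 4 / 3 * pi * (radius / 10)^3
    tol <- surfaceVoxelCount(voxelValues(fx$mask)) *
      voxelVolumeMm3(fx$volume) / 1000
    expect_lt(abs(got - analytic), tol)
    expect_gt(del@threshold, del@backgroundMean)
  }
})

test_that("scaling intensities scales the threshold and keeps the mask", {
  fx <- sphereFixture()
  del1 <- delineateTumor(fx$volume, fx$center)
  for (c0 in c(0.5, 3)) {
    volC <- SUVVolume(voxelValues(fx$volume) * c0,
                      spacing = voxelSpacing(fx$volume),
                      origin = voxelOrigin(fx$volume))
    delC <- delineateTumor(volC, fx$center)
    expect_equal(delC@threshold, c0 * del1@threshold, tolerance = 1e-9)
    expect_identical(voxelValues(delC@mask), voxelValues(del1@mask))
  }
})

test_that("raising the weight never grows the converged mask", {
  ph <- generatePhantom(phantomSpec(seed = 31L, noiseSD = 0))
  masks <- lapply(c(0.3, 0.45, 0.6), function(w) {
    del <- delineateTumor(ph$volume, c(60, 100, 50),
                          segmentationConfig(weight = w),
                          organMasks = ph$truth@organMasks)
    voxelValues(del@mask)
  })
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
})

test_that("two-compartment phantom matches the brute-force reference", {
  dims <- c(16, 16, 16); spacing <- c(4, 4, 4)
  origin <- spacing / 2
  center <- dims * spacing / 2
  vol0 <- SUVVolume(array(1, dims), spacing = spacing, origin = origin)
  inner <- voxelValues(sphereMask(vol0, center, 16))
  rim <- voxelValues(sphereMask(vol0, center, 32)) & !inner
  v <- array(1, dims); v[rim] <- 6; v[inner] <- 12
  vol <- SUVVolume(v, spacing = spacing, origin = origin)

  del <- delineateTumor(vol, center)
  seedIdx <- round((center - origin) / spacing) + 1
  ref <- oracleDelineate(v, spacing, as.integer(seedIdx))
  expect_equal(del@threshold, ref$threshold, tolerance = 1e-12)
  expect_identical(voxelValues(del@mask), ref$mask)
})

test_that("one-shot mode and error paths behave as specified", {
  fx <- sphereFixture()
  one <- delineateTumor(fx$volume, fx$center,
                        segmentationConfig(maxIterations = 1L))
  expect_equal(one@iterations, 1L)
  expect_error(delineateTumor(fx$volume, c(-50, 0, 0)), "outside the grid")
  zero <- fx$volume
  expect_error(delineateTumor(SUVVolume(array(0, c(4, 4, 4))), c(1, 1, 1)),
               "positive")
})

test_that("explicit background masks are honoured", {
  fx <- sphereFixture()
  bg <- VOIMask(!voxelValues(fx$mask), spacing = voxelSpacing(fx$volume),
                origin = voxelOrigin(fx$volume))
  del <- delineateTumor(fx$volume, fx$center,
                        segmentationConfig(backgroundMode = "explicit_mask"),
                        backgroundMask = bg)
  expect_equal(del@threshold, 4.0, tolerance = 1e-12)
  expect_error(
    delineateTumor(fx$volume, fx$center,
                   segmentationConfig(backgroundMode = "explicit_mask")),
    "requires a backgroundMask")
})
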