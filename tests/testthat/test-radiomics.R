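test_that("conventional features match hand arithmetic", {
  vol <- SUVVolume(array(5, c(5, 5, 4)), spacing = c(4.07, 4.07, 2.5))
  f <- conventionalFeatures(vol, VOIMask(array(TRUE, c(5, 5, 4)),
                                         spacing = c(4.07, 4.07, 2.5)))
  expect_equal(unname(f["mtv_cm3"]), 100 * (4.07^2 * 2.5) / 1000,
               tolerance = 1e-12)
  expect_equal(unname(f["tlg_g"]), 5 * 100 * (4.07^2 * 2.5) / 1000,
               tolerance = 1e-12)
  expect_equal(unname(f[c("max_suv", "mean_suv", "median_suv")]),
               c(5, 5, 5))
  expect_equal(unname(f["cov_suv"]), 0)

  v <- array(1, c(3, 1, 1)); v[, 1, 1] <- c(2, 4, 6)
  f2 <- conventionalFeatures(SUVVolume(v), VOIMask(array(TRUE, c(3, 1, 1))))
  expect_equal(unname(f2["mean_suv"]), 4)
  expect_equal(unname(f2["median_suv"]), 4)
  expect_equal(unname(f2["cov_suv"]), sqrt(8 / 3) / 4, tolerance = 1e-12)

  expect_error(conventionalFeatures(SUVVolume(v),
                                    VOIMask(array(FALSE, c(3, 1, 1)))),
               "empty")
  expect_error(conventionalFeatures(SUVVolume(array(0, c(2, 2, 2))),
                                    VOIMask(array(TRUE, c(2, 2, 2)))),
               "undefined")
})

test_that("intensity histogram follows the half-open binning convention", {
  v <- array(1, c(4, 1, 1)); v[, 1, 1] <- c(1, 1, 2, 3)
  h <- intensityHistogram(SUVVolume(v), VOIMask(array(TRUE, c(4, 1, 1))),
                          histogramConfig(nBins = 2L))
  expect_equal(h$p, c(0.5, 0.5))  # 2 falls in the second bin [2, 3]

  con <- intensityHistogram(SUVVolume(array(4, c(3, 3, 3))),
                            VOIMask(array(TRUE, c(3, 3, 3))))
  expect_equal(con$p[1], 1)
  expect_true(con$degenerate)

  # 64 values filling 64 bins exactly uniformly
  v64 <- array(seq(0.5, 63.5), c(64, 1, 1))
  h64 <- intensityHistogram(SUVVolume(v64), VOIMask(array(TRUE, c(64, 1, 1))))
  expect_equal(h64$p, rep(1 / 64, 64))
  expect_equal(sum(h64$p), 1, tolerance = 1e-12)
})

test_that("histogram features match closed forms", {
  hf <- histogramFeatures(rep(1 / 64, 64), seq_len(64))
  expect_equal(unname(hf["entropy_bits"]), 6)
  expect_equal(unname(hf["uniformity"]), 1 / 64)

  one <- histogramFeatures(c(1, rep(0, 63)), seq_len(64))
  expect_equal(unname(one["entropy_bits"]), 0)
  expect_equal(unname(one["uniformity"]), 1)
  expect_true(attr(one, "degenerate"))
  expect_equal(unname(one[c("skewness", "kurtosis")]), c(0, 0))

  two <- histogramFeatures(c(0.5, 0.5), c(0, 1))
  expect_equal(unname(two["entropy_bits"]), 1)
  expect_equal(unname(two["uniformity"]), 0.5)
  expect_equal(unname(two["skewness"]), 0)
  expect_equal(unname(two["kurtosis"]), -2)

  expect_error(histogramFeatures(c(0, 0), c(0, 1)), "empty")
  expect_error(histogramFeatures(c(0.7, 0.7), c(0, 1)), "sum to 1")
})

test_that("all ten features agree with brute force on 200 random VOIs", {
  set.seed(42)
  for (rep in 1:200) {
    fx <- randomMaskedVolume()
    fv <- featureVector(tumorFeatures(fx$volume, fx$mask))
    ref <- oracleFeatures(voxelValues(fx$volume)[voxelValues(fx$mask)],
                          voxelVolumeMm3(fx$volume))
    expect_equal(fv, ref, tolerance = 1e-9)
  }
})

test_that("features transform correctly under intensity scaling", {
  set.seed(7)
  fx <- randomMaskedVolume()
  f1 <- featureVector(tumorFeatures(fx$volume, fx$mask))
  for (c0 in c(0.25, 3)) {
    volC <- SUVVolume(voxelValues(fx$volume) * c0,
                      spacing = voxelSpacing(fx$volume))
    f2 <- featureVector(tumorFeatures(volC, fx$mask))
    linear <- c("max_suv", "mean_suv", "median_suv", "tlg_g")
    invariant <- c("mtv_cm3", "cov_suv", "kurtosis", "skewness", "entropy",
                   "uniformity")
    expect_equal(f2[linear], c0 * f1[linear], tolerance = 1e-9)
    expect_equal(f2[invariant], f1[invariant], tolerance = 1e-9)
  }
})

test_that("uniformity and entropy are coupled at their extremes", {
  set.seed(11)
  for (rep in 1:20) {
    fx <- randomMaskedVolume()
    fv <- featureVector(tumorFeatures(fx$volume, fx$mask))
    expect_gte(fv[["uniformity"]], 1 / 64 - 1e-12)
    expect_lte(fv[["entropy"]], 6 + 1e-12)
    expect_gte(fv[["entropy"]], 0)
  }
  # uniformity = 1 iff entropy = 0 (degenerate); minimum uniformity at max entropy
  hf <- histogramFeatures(rep(1 / 64, 64), seq_len(64))
  expect_equal(unname(hf["uniformity"]), 1 / 64)
  hf0 <- histogramFeatures(c(rep(0, 63), 1), seq_len(64))
  expect_equal(unname(hf0["entropy_bits"]), 0)
  expect_equal(unname(hf0["uniformity"]), 1)
})

test_that("measured CoV rises with the generator texture SD", {
  covs <- vapply(c(0.5, 1.5, 2.5), function(ts) {
    ph <- generatePhantom(phantomSpec(seed = 21L, noiseSD = 0,
                                      tumorTextureSD = ts))
    unname(conventionalFeatures(ph$volume, ph$truth@tumorMask)["cov_suv"])
  }, numeric(1))
  expect_true(all(diff(covs) > 0))
})

test_that("TLG identity holds on arbitrary delineations", {
  ph <- generatePhantom(phantomSpec(seed = 13L))
  del <- delineateTumor(ph$volume, c(60, 100, 50),
                        organMasks = ph$truth@organMasks)
  fs <- tumorFeatures(ph$volume, del@mask)
  expect_equal(fs@tlgG, fs@mtvCm3 * fs@meanSUV, tolerance = 1e-12)
})
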