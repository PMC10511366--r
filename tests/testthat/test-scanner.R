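# Synthetic scanner: phantom and tree rasterisation with exact ground truth,
# PSF/noise model, repeat-pair simulation.

test_that("tube phantom rasterises with exact plateaus and true diameters", {
  spec <- singleTubePhantom(lumen = 6, wall = 1)
  ph <- rasterizeTubePhantom(spec)
  gt <- ph$groundTruth
  v <- voxelData(ph$volume)
  sp <- voxelSpacing(ph$volume)
  # deep-lumen voxels carry HU(lumen) exactly (anti-aliasing only at edges)
  tb <- spec@tubes[[1]]
  cen <- tb@center
  civ <- round(cen / sp) + 1
  expect_identical(v[civ[1], civ[2], civ[3]], spec@huLumen)
  expect_identical(v[1, 1, 1], spec@huBackground)
  # area-equivalent diameter of the GT lumen in a central slice
  sl <- voxelData(gt@lumenMask)[, , civ[3]]
  d <- 2 * sqrt(sum(sl) * sp[1] * sp[2] / pi)
  expect_lt(abs(d - 6), 0.5)
  # masks disjoint
  expect_true(all(voxelData(gt@lumenMask) * voxelData(gt@wallMask) == 0))
})

test_that("invalid tube placement is rejected", {
  sp <- c(0.6, 0.6, 0.7)
  out <- phantomSpec(list(tubeSpec(6, 1, 30, center = c(0, 0, 0))),
                     c(20L, 20L, 20L), sp)
  expect_error(rasterizeTubePhantom(out), "outside the grid")
  over <- phantomSpec(list(
    tubeSpec(4, 1, 8, center = c(6, 6, 6)),
    tubeSpec(4, 1, 8, center = c(7, 6, 6))), c(24L, 24L, 24L), c(0.5, 0.5, 0.5))
  expect_error(rasterizeTubePhantom(over), "overlapping")
})

test_that("airway tree generation follows the bifurcation rules", {
  spec <- treeSpec(maxGeneration = 0L)
  r <- rasterizeAirwayTree(spec, seed = 1)
  expect_equal(nrow(r$groundTruth@branches), 1)
  expect_equal(r$groundTruth@branches$generation, 0)

  spec2 <- treeSpec(maxGeneration = 2L)
  r2 <- rasterizeAirwayTree(spec2, seed = 1)
  br <- r2$groundTruth@branches
  expect_equal(nrow(br), 7)
  expect_equal(as.integer(table(br$generation)), c(1, 2, 4))
  expect_equal(br$lumenDiameter[br$generation == 1][1],
               spec2@rootDiameter * spec2@diameterRatio)
  # determinism
  r3 <- rasterizeAirwayTree(spec2, seed = 1)
  expect_identical(voxelData(r2$volume), voxelData(r3$volume))
  # escape detection
  small <- treeSpec(maxGeneration = 2L, dim = c(24L, 24L, 24L))
  expect_error(rasterizeAirwayTree(small, seed = 1), "escapes")
})

test_that("branch counts follow 2^(g+1) - 1 for no-jitter trees", {
  for (g in 0:3) {
    spec <- treeSpec(rootDiameter = 4, maxGeneration = as.integer(g),
                     minDiameter = 0.5, dim = c(96L, 96L, 96L),
                     spacing = c(0.5, 0.5, 0.5))
    segs <- AirwayMeasure:::withSeed(1, AirwayMeasure:::.growTree(spec))
    expect_equal(length(segs), 2^(g + 1) - 1)
  }
})

test_that("scanner model reproduces its stated blur and noise", {
  v <- imageVolume(array(0, c(64, 64, 64)), c(0.6, 0.6, 0.7))
  # identity when disabled
  out0 <- applyScannerModel(v, scannerModel(fwhm = 0, noiseSD = 0), seed = 1)
  expect_identical(voxelData(out0), voxelData(v))
  # Monte-Carlo noise SD over ~2.6e5 voxels
  out <- applyScannerModel(v, scannerModel(fwhm = 0, noiseSD = 25), seed = 3)
  expect_lt(abs(sd(voxelData(out)) - 25) / 25, 0.02)
  # Gaussian edge-spread: 10-90% distance of a blurred step is ~1.09 x FWHM
  step <- array(0, c(120, 8, 8))
  step[61:120, , ] <- 1000
  sv <- imageVolume(step, c(0.1, 0.5, 0.5))
  b <- applyScannerModel(sv, scannerModel(fwhm = 0.8, noiseSD = 0), seed = 1)
  prof <- voxelData(b)[, 4, 4]
  x <- seq_along(prof) * 0.1
  width <- approx(prof, x, xout = 900, ties = "ordered")$y -
    approx(prof, x, xout = 100, ties = "ordered")$y
  expect_lt(abs(width - 0.8 * 1.0885) / (0.8 * 1.0885), 0.15)
  # different seeds give independent realisations
  n1 <- voxelData(applyScannerModel(v, scannerModel(0, 25), seed = 1))
  n2 <- voxelData(applyScannerModel(v, scannerModel(0, 25), seed = 2))
  expect_lt(abs(cor(as.numeric(n1), as.numeric(n2))), 0.01)
})

test_that("repeat pairs scale TLV with inflation and add noise in quadrature", {
  spec <- treeSpec(maxGeneration = 1L, dim = c(56L, 56L, 64L))
  model <- scannerModel(fwhm = 0, noiseSD = 20)
  # identical seeds, no inflation: identical scans
  pr <- simulateRepeatPair(spec, model, inflationFactor = 1, seeds = c(5, 5))
  expect_identical(voxelData(pr$scan1), voxelData(pr$scan2))
  expect_equal(pr$tlv[2] / pr$tlv[1], 1)
  # different noise seeds: voxelwise difference SD = sqrt(2) x noise SD
  pr2 <- simulateRepeatPair(spec, model, inflationFactor = 1, seeds = c(5, 6))
  dsd <- sd(voxelData(pr2$scan1) - voxelData(pr2$scan2))
  expect_lt(abs(dsd - sqrt(2) * 20) / (sqrt(2) * 20), 0.03)
  # inflation scales the TLV surrogate (larger tree: smaller raster error)
  pr3 <- simulateRepeatPair(treeSpec(maxGeneration = 2L), model,
                            inflationFactor = 1.2, seeds = c(5, 6))
  expect_lt(abs(pr3$tlv[2] / pr3$tlv[1] - 1.2) / 1.2, 0.02)
})
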