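# Bronchial measurements: centreline sampling, cross-sections, aggregation,
# Pi10, scan summaries, segmentation scoring.

test_that("centreline sampling spaces points at the requested step", {
  pts <- cbind(0, 0, seq(0, 2.6, by = 0.1))
  sc <- sampleCenterline(pts, step = 0.5, excludeEnds = FALSE)
  expect_equal(nrow(sc$positions), 6)           # 0, 0.5, ..., 2.5
  expect_equal(sc$positions[, 3], seq(0, 2.5, by = 0.5), tolerance = 1e-6)
  expect_equal(sc$tangents, matrix(rep(c(0, 0, 1), each = 6), ncol = 3),
               tolerance = 1e-6)
  # bifurcation exclusion leaves nothing on a 0.8 mm stub
  stub <- cbind(0, 0, seq(0, 0.8, by = 0.1))
  expect_equal(nrow(sampleCenterline(stub, step = 0.5)$positions), 0)
})

test_that("cross-sections recover annulus radii within 0.15 mm", {
  spec <- singleTubePhantom(lumen = 6, wall = 1)
  ph <- rasterizeTubePhantom(spec)
  gt <- ph$groundTruth
  tb <- spec@tubes[[1]]
  cs <- measureCrossSection(gt@lumenMask, gt@wallMask, tb@center, c(0, 0, 1))
  expect_true(cs$valid)
  expect_lt(abs(cs$rIn - 3.0), 0.15)
  expect_lt(abs(cs$rOut - 4.0), 0.15)
  # centre outside the lumen flags the section invalid
  off <- measureCrossSection(gt@lumenMask, gt@wallMask,
                             tb@center + c(5, 0, 0), c(0, 0, 1))
  expect_false(off$valid)
})

test_that("branch aggregation follows the area-averaging convention", {
  secs <- data.frame(x = 0, y = 0, z = 1:5, rIn = 2.0, rOut = 2.5,
                     valid = TRUE)
  b <- aggregateBranch(secs, id = 1L, generation = 2L, length = 2)
  expect_equal(b$LA, pi * 4, tolerance = 1e-9)
  expect_equal(b$WA, pi * (2.5^2 - 4), tolerance = 1e-9)
  expect_equal(b$WAP, 100 * (2.5^2 - 4) / 2.5^2, tolerance = 1e-9)
  expect_equal(b$SRWA, sqrt(b$WA), tolerance = 1e-9)
  expect_equal(b$Pi, 2 * pi * 2, tolerance = 1e-9)
  # zero wall
  z <- aggregateBranch(data.frame(x = 0, y = 0, z = 1:3, rIn = 2, rOut = 2,
                                  valid = TRUE))
  expect_equal(z$WA, 0)
  expect_equal(z$WAP, 0)
  expect_equal(z$SRWA, 0)
  # areas are averaged, not radii: r_in {2, 4} gives LA = 10 pi, not 9 pi
  two <- aggregateBranch(data.frame(x = 0, y = 0, z = 1:2, rIn = c(2, 4),
                                    rOut = c(2, 4), valid = TRUE))
  expect_equal(two$LA, 10 * pi, tolerance = 1e-9)
  # no valid sections: excluded
  expect_null(aggregateBranch(data.frame(x = 0, y = 0, z = 1, rIn = NA,
                                         rOut = NA, valid = FALSE)))
})

test_that("WAP recomputed from exported LA and WA matches exactly", {
  set.seed(3)
  secs <- data.frame(x = 0, y = 0, z = 1:20, rIn = runif(20, 1, 3),
                     rOut = runif(20, 3, 4), valid = TRUE)
  b <- aggregateBranch(secs)
  expect_equal(b$WAP, 100 * b$WA / (b$WA + b$LA), tolerance = 1e-12)
})

test_that("Pi10 recovers an exact linear law and ignores the trachea", {
  br <- data.frame(generation = rep(1:6, each = 3),
                   Pi = rep(c(6, 8, 12), 6))
  br$SRWA <- 0.2 * br$Pi + 1.0
  expect_equal(computePi10(br), 3.0, tolerance = 1e-9)
  # constant SRWA: slope 0
  flat <- data.frame(generation = 1:4, Pi = c(5, 7, 9, 11), SRWA = 2.2)
  expect_equal(computePi10(flat), 2.2, tolerance = 1e-9)
  # a wild trachea row must not move Pi10
  withTrachea <- rbind(br, data.frame(generation = 0, Pi = 30, SRWA = 99))
  expect_equal(computePi10(withTrachea), 3.0, tolerance = 1e-9)
  # duplication invariance of the regression
  expect_equal(computePi10(rbind(br, br)), computePi10(br), tolerance = 1e-12)
  expect_error(computePi10(data.frame(generation = 2, Pi = 5, SRWA = 1)),
               "undefined")
})

test_that("scan summaries aggregate per generation", {
  meas <- data.frame(id = 1:7, generation = c(0, 1, 1, 2, 2, 2, 2),
                     length = 10, nSections = 10, meanRIn = 2, meanROut = 2.5,
                     LA = c(50, 30, 34, 20, 22, 24, 26), WA = 10,
                     WAP = 25, SRWA = sqrt(10), Pi = c(25, 19, 21, 15, 16, 17, 18))
  s <- summarizeScan(meas, tlv = 5.5)
  expect_equal(s@tac, 7)
  expect_equal(unname(s@genLA[["1"]]), 32)
  expect_equal(s@maxGeneration, 2)
  # single-branch scan: Pi10 absent, only generation 0
  s0 <- summarizeScan(meas[1, ], tlv = 5)
  expect_true(is.na(s0@pi10))
  expect_equal(names(s0@genLA), "0")
})

test_that("segmentation metrics match closed forms on constructed masks", {
  spec <- treeSpec(maxGeneration = 1L, dim = c(56L, 56L, 64L))
  r <- rasterizeAirwayTree(spec, seed = 1)
  gt <- largestComponent(r$groundTruth@lumenMask)
  ct <- r$groundTruth@trees[[1]]
  same <- segmentationMetrics(gt, gt, ct)
  expect_equal(same$dice, 1.0)
  expect_equal(same$completeness, 100)
  expect_lt(same$leakage, 1e-9)
  # prediction covering half of the GT voxels: Dice = 2/3
  v <- voxelData(gt)
  idx <- which(v != 0)
  half <- array(0, dim(v))
  half[idx[seq_len(floor(length(idx) / 2))]] <- 1
  halfMask <- binaryMask(half, voxelSpacing(gt))
  d <- 2 * sum(half * v) / (sum(half) + sum(v))
  expect_equal(segmentationMetrics(halfMask, gt, ct)$dice, d,
               tolerance = 1e-9)
  expect_lt(abs(d - 2 / 3), 0.01)
})

test_that("a disjoint spurious tube appears as centreline leakage", {
  cyl <- digitalCylinder(radius = 3, nz = 58)
  v <- voxelData(cyl)
  d <- dim(v)
  # append a detached parallel tube of half the length
  spur <- array(0, d + c(14, 0, 0))
  spur[seq_len(d[1]), , seq_len(d[3])] <- v
  for (k in 30:58) for (j in seq_len(d[2])) {
    i <- seq_len(14) + d[1]
    spur[i, j, k] <- as.numeric((((i - 1) - (d[1] + 6)) * 0.6)^2 +
                                  ((j - 1 - (d[2] - 1) / 2) * 0.6)^2 <= 2^2)
  }
  gtBig <- array(0, d + c(14, 0, 0))
  gtBig[seq_len(d[1]), , ] <- v
  gtMask <- binaryMask(gtBig, voxelSpacing(cyl))
  predMask <- binaryMask(spur, voxelSpacing(cyl))
  gtTree <- extractBranches(cyl, findTracheaSeed(cyl))
  # shift gt tree into the padded frame (identical origin, so no change)
  sm <- segmentationMetrics(predMask, gtMask, gtTree)
  lt <- 56 * 0.7
  ls <- 28 * 0.7
  expect_lt(abs(sm$leakage - 100 * ls / (lt + ls)) / (100 * ls / (lt + ls)),
            0.12)
  expect_equal(sm$completeness, 100)
})

test_that("measured diameters converge with finer in-plane resampling", {
  spec <- singleTubePhantom(lumen = 4, wall = 1)
  ph <- rasterizeTubePhantom(spec)
  gt <- ph$groundTruth
  tb <- spec@tubes[[1]]
  errs <- sapply(c(0.5, 0.25, 0.125), function(h) {
    cs <- measureCrossSection(gt@lumenMask, gt@wallMask, tb@center,
                              c(0, 0, 1), inPlaneStep = h)
    abs(cs$rIn - 2.0)
  })
  expect_true(all(diff(errs) <= 1e-9 + 0.02))   # non-increasing within noise
  expect_lt(errs[3], 0.1)
})
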