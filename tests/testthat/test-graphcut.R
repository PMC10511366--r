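# Coupled-surface graph cut: mesh extraction, column costs, global
# optimality against an exhaustive oracle, mask rasterisation.

test_that("initial surface of a digital sphere is accurate and outward", {
  sph <- digitalSphere(r = 10)
  mesh <- extractInitialSurface(sph$mask)
  dist <- sqrt(rowSums(sweep(mesh@vertices, 2, sph$centre)^2))
  expect_lt(mean(abs(dist - 10)), 1)
  out <- rowSums(mesh@normals * sweep(mesh@vertices, 2, sph$centre))
  expect_true(all(out > 0))
  nrm <- sqrt(rowSums(mesh@normals^2))
  expect_equal(nrm, rep(1, length(nrm)), tolerance = 1e-6)
})

test_that("degenerate masks are rejected at surface extraction", {
  empty <- binaryMask(array(0, c(5, 5, 5)))
  expect_error(extractInitialSurface(empty), "empty")
  two <- array(0, c(9, 9, 9))
  two[2:3, 2:3, 2:3] <- 1
  two[7:8, 7:8, 7:8] <- 1
  expect_error(extractInitialSurface(binaryMask(two)), "components")
})

test_that("column costs are zero-derivative flat on constant volumes and use
           a sentinel out of bounds", {
  sph <- digitalSphere(r = 6, pad = 3)
  mesh <- extractInitialSurface(sph$mask)
  const <- imageVolume(array(100, dim(voxelData(sph$mask))))
  params <- graphCutParams(lIn = 1, lOut = 8, step = 0.5)
  cg <- buildColumns(mesh, const, params)
  inb <- is.finite(cg@intensity)
  finite <- cg@costIn < AirwayMeasure:::.BIGCOST / 2
  # interior samples all share the zero-derivative cost
  expect_true(all(abs(cg@costIn[finite]) < 1e-9))
  # out-of-volume samples carry the sentinel
  expect_true(any(!finite))
  expect_true(all(cg@costIn[!finite] == AirwayMeasure:::.BIGCOST))
})

test_that("inner cost dips at the lumen-wall edge of a noise-free annulus", {
  spec <- singleTubePhantom(lumen = 5, wall = 1.2)
  ph <- rasterizeTubePhantom(spec)
  blurred <- applyScannerModel(ph$volume, scannerModel(fwhm = 0.8, noiseSD = 0))
  init <- AirwayMeasure:::erodeMask(ph$groundTruth@lumenMask)
  mesh <- extractInitialSurface(init)
  params <- graphCutParams(lIn = 0.9, lOut = 3.6, step = 0.15)
  cg <- buildColumns(mesh, blurred, params)
  tb <- spec@tubes[[1]]
  rel <- sweep(cg@base, 2, tb@center)
  tpar <- rel %*% tb@axis
  radial <- sqrt(rowSums((rel - tpar %*% t(tb@axis))^2))
  sel <- which(abs(tpar) < tb@length / 2 - 4)
  rAtK <- vapply(sel, function(v) {
    k <- which.min(cg@costIn[v, ])
    radial[v] + cg@offsets[k] * sum(cg@dir[v, ] * rel[v, ] / radial[v])
  }, 0)
  # the argmin tracks the lumen-wall edge: every central column localises it
  # within two sample steps of the true radius (the PSF shifts the gradient
  # peak slightly inward and the discrete argmin adds at most one step), and
  # the across-column mean position is unbiased to within one step
  expect_true(all(abs(rAtK - 2.5) <= 2 * params@step))
  expect_lte(abs(mean(rAtK) - 2.5), params@step)
})

test_that("solver energy equals exhaustive enumeration on random graphs", {
  for (seed in 1:40) {
    set.seed(seed + 500)
    n <- sample(2:4, 1)
    K <- sample(3:6, 1)
    g <- randomColumnGraph(n, K, seed)
    params <- graphCutParams(delta = sample(0:2, 1), p = sample(0:3, 1),
                             q = sample(0:3, 1), sMin = sample(0:1, 1),
                             sPref = sample(1:3, 1))
    if (params@sPref < params@sMin) params@sPref <- params@sMin
    pair <- solveOptimalSurfaces(g, params)
    expect_equal(pair@energy, enumerateSurfaceEnergy(g, params),
                 tolerance = 1e-9)
  }
})

test_that("solver agrees with an independent max-flow library", {
  skip_if_not_installed("igraph")
  # cross-check the min-cut kernel itself on random capacitated graphs
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    m <- sample(n:(3 * n), 1)
    from <- sample(n - 1, m, TRUE)
    to <- sample(2:n, m, TRUE)
    keep <- from != to
    cap <- round(runif(sum(keep), 0, 10), 3)
    mf <- AirwayMeasure:::cpp_maxflow(from[keep], to[keep], cap, n, 1L, n)
    g <- igraph::make_graph(rbind(from[keep], to[keep]), n = n,
                            directed = TRUE)
    ref <- igraph::max_flow(g, 1, n, capacity = cap)
    expect_equal(mf$flow, ref$value, tolerance = 1e-8)
  }
})

test_that("single-column solve minimises costs with ties toward lower index", {
  K <- 8
  cIn <- matrix(c(3, 1, 1, 2, 5, 5, 5, 5), 1, K)
  cOut <- matrix(c(9, 9, 0, 4, 0, 9, 9, 9), 1, K)
  g <- new("ColumnGraph", base = matrix(0, 1, 3),
           dir = matrix(c(0, 0, 1), 1, 3),
           offsets = seq(0, by = 0.3, length.out = K), intensity = cIn,
           costIn = cIn, costOut = cOut, edges = matrix(integer(0), ncol = 2),
           step = 0.3)
  p0 <- graphCutParams(p = 0, q = 0, sMin = 0, sPref = 7)
  pair <- solveOptimalSurfaces(g, p0)
  expect_equal(pair@kIn, 2L)    # tie between 2 and 3 broken downward
  expect_equal(pair@kOut, 3L)   # tie between 3 and 5 broken downward
  # infeasible separation
  expect_error(solveOptimalSurfaces(g, graphCutParams(sMin = K, sPref = K)),
               "infeasible")
})

test_that("delta = 0 forces flat surfaces chosen by column-summed cost", {
  set.seed(7)
  n <- 5; K <- 6
  g <- randomColumnGraph(n, K, seed = 7)
  g@edges <- cbind(1:4, 2:5)
  params <- graphCutParams(delta = 0, p = 0, q = 0, sMin = 0, sPref = K - 1)
  pair <- solveOptimalSurfaces(g, params)
  expect_equal(length(unique(pair@kIn)), 1)
  expect_equal(length(unique(pair@kOut)), 1)
  # reduced oracle: 1-D search over flat assignments
  sums <- sapply(seq_len(K), function(k) sum(g@costIn[, k]))
  sumsO <- sapply(seq_len(K), function(k) sum(g@costOut[, k]))
  best <- Inf
  for (ki in seq_len(K)) for (ko in ki:K)
    best <- min(best, sums[ki] + sumsO[ko])
  expect_equal(pair@energy, best, tolerance = 1e-9)
})

test_that("solutions respect constraints and smoothness is monotone in p", {
  prev <- Inf
  g <- randomColumnGraph(4, 6, seed = 11)
  for (p in c(0, 1, 4, 16)) {
    params <- graphCutParams(delta = 5, p = p, q = 0, sMin = 1, sPref = 5)
    pair <- solveOptimalSurfaces(g, params)
    expect_true(all(pair@kOut - pair@kIn >= 1))
    rough <- sum(abs(pair@kIn[g@edges[, 1]] - pair@kIn[g@edges[, 2]])) +
      sum(abs(pair@kOut[g@edges[, 1]] - pair@kOut[g@edges[, 2]]))
    expect_lte(rough, prev)
    prev <- rough
  }
})

test_that("surface rasterisation yields nested annular masks", {
  spec <- singleTubePhantom(lumen = 5, wall = 1.2)
  ph <- rasterizeTubePhantom(spec)
  scan <- applyScannerModel(ph$volume, scannerModel(0.8, 15), seed = 2)
  ctx <- phantomContext(scan, ph$groundTruth)[[1]]
  params <- graphCutParams(wIn = 1, wOut = 1, delta = 3, p = 50, q = 5,
                           sMin = 1, sPref = 8, lIn = 0.9, lOut = 3.6,
                           step = 0.15)
  cg <- buildColumns(ctx$mesh, scan, params)
  pair <- solveOptimalSurfaces(cg, params)
  masks <- surfacesToMasks(pair, ctx$mesh@faces, ctx$grid)
  lum <- voxelData(masks$lumen)
  wal <- voxelData(masks$wall)
  expect_gt(sum(lum), 0)
  expect_gt(sum(wal), 0)
  expect_true(all(lum * wal == 0))
  # wall voxel radial distances stay within the annulus (plus sampling slack)
  tb <- spec@tubes[[1]]
  idx <- which(wal != 0, arr.ind = TRUE)
  pts <- AirwayMeasure:::indexToWorld(masks$wall, idx - 1)
  rel <- sweep(pts, 2, tb@center)
  tpar <- rel %*% tb@axis
  rad <- sqrt(rowSums((rel - tpar %*% t(tb@axis))^2))
  core <- abs(tpar) < tb@length / 2 - 4
  expect_gt(min(rad[core]), 2.5 - 3 * params@step)
  expect_lt(max(rad[core]), 3.7 + 3 * params@step)
})
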