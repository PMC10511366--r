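# Phantom tuning: the measurement-error objective and the TPE optimiser.

quadSpace <- function() {
  new("ParamSpace",
      bounds = data.frame(name = "x", lower = 0, upper = 1, log = FALSE,
                          integer = FALSE),
      fixed = list())
}

test_that("diameter error matches its closed form", {
  # surfaces displaced +0.5 mm on a 6 mm lumen / 8 mm total tube
  expect_equal(diameterError(7, 9, 6, 8), (1 / 6 + 1 / 8) / 2,
               tolerance = 1e-12)
  expect_equal(diameterError(6, 8, 6, 8), 0)
})

test_that("oracle surfaces reach the rasterisation floor", {
  spec <- defaultPhantomSpec()
  ph <- rasterizeTubePhantom(spec)
  scan <- applyScannerModel(ph$volume, scannerModel(0.8, 25), seed = 7)
  ctx <- phantomContext(scan, ph$groundTruth)
  params <- graphCutParams(lIn = 0.9, lOut = 3.6, step = 0.15, sMin = 1)
  errs <- sapply(seq_along(ctx), function(ti) {
    cx <- ctx[[ti]]
    tb <- spec@tubes[[ti]]
    cg <- buildColumns(cx$mesh, scan, params)
    rel <- sweep(cg@base, 2, tb@center)
    tpar <- rel %*% tb@axis
    rb <- sqrt(rowSums((rel - tpar %*% t(tb@axis))^2))
    radU <- (rel - tpar %*% t(tb@axis)) / rb
    cosT <- pmax(rowSums(cg@dir * radU), 0.2)
    kFor <- function(rT) {
      k <- round(((rT - rb) / cosT - cg@offsets[1]) / params@step) + 1
      as.integer(pmin(pmax(k, 1), length(cg@offsets)))
    }
    pair <- new("SurfacePair", kIn = kFor(tb@lumenDiameter / 2),
                kOut = kFor(tb@lumenDiameter / 2 + tb@wallThickness),
                energy = 0, graph = cg)
    masks <- surfacesToMasks(pair, cx$mesh@faces, cx$grid)
    secs <- do.call(rbind, lapply(seq_len(nrow(cx$samples$positions)),
      function(j) measureCrossSection(masks$lumen, masks$wall,
                                      cx$samples$positions[j, ],
                                      cx$samples$tangents[j, ],
                                      inPlaneStep = 0.15,
                                      halfWidth = cx$gtTotal / 2 + 2)))
    ok <- secs$valid
    diameterError(2 * mean(secs$rIn[ok]), 2 * mean(secs$rOut[ok]),
                  tb@lumenDiameter, tb@lumenDiameter + 2 * tb@wallThickness)
  })
  expect_lt(mean(errs), 0.01)
})

test_that("objective returns a sentinel, not an exception, on failure", {
  spec <- singleTubePhantom(lumen = 4, wall = 1)
  ph <- rasterizeTubePhantom(spec)
  ctx <- phantomContext(ph$volume, ph$groundTruth)
  # a solver that always fails
  badCtx <- ctx
  badCtx[[1]]$samples$positions <- badCtx[[1]]$samples$positions[0, , drop = FALSE]
  params <- graphCutParams(lIn = 0.9, lOut = 3.6, step = 0.15)
  val <- measurementError(params, ph$volume, ph$groundTruth, context = badCtx)
  expect_identical(val, AirwayMeasure:::.FAIL_SENTINEL)
  expect_error(measurementError("nonsense", ph$volume, ph$groundTruth,
                                context = ctx))
})

test_that("TPE finds the quadratic minimum and is deterministic", {
  obj <- function(v) (v[["x"]] - 0.3)^2
  res <- tpeOptimize(obj, quadSpace(), nTrials = 60, nStartup = 10, seed = 5)
  expect_lte(res@bestValue, 0.01)
  expect_equal(nrow(res@history), 60)
  expect_equal(res@bestValue, min(res@history$value))
  res2 <- tpeOptimize(obj, quadSpace(), nTrials = 60, nStartup = 10, seed = 5)
  expect_identical(res@history, res2@history)
})

test_that("TPE with nTrials <= nStartup reduces to uniform random search", {
  obj <- function(v) (v[["x"]] - 0.3)^2
  a <- tpeOptimize(obj, quadSpace(), nTrials = 15, nStartup = 15, seed = 9)
  b <- tpeOptimize(obj, quadSpace(), nTrials = 15, nStartup = 99, seed = 9)
  expect_identical(a@history, b@history)
  # and the draws are the plain uniform stream
  xs <- AirwayMeasure:::withSeed(9, stats::runif(1))
  expect_equal(a@history$x[1], xs, tolerance = 1e-12)
})

test_that("best objective is non-increasing in the trial budget", {
  obj <- function(v) (v[["x"]] - 0.62)^2 + 0.05 * sin(20 * v[["x"]])
  prev <- Inf
  for (n in c(10, 25, 40)) {
    r <- tpeOptimize(obj, quadSpace(), nTrials = n, nStartup = 10, seed = 3)
    expect_lte(r@bestValue, prev + 1e-12)
    prev <- r@bestValue
  }
})

test_that("TPE beats uniform random search on most seed pairs", {
  obj <- function(v) (v[["x"]] - 0.3)^2
  wins <- 0
  for (s in 1:60) {
    tpe <- tpeOptimize(obj, quadSpace(), nTrials = 60, nStartup = 10, seed = s)
    unif <- tpeOptimize(obj, quadSpace(), nTrials = 60, nStartup = 60,
                        seed = s + 10000)
    if (tpe@bestValue < unif@bestValue) wins <- wins + 1
  }
  expect_gte(wins / 60, 0.7)
})

test_that("integer dimensions are rounded at evaluation", {
  sp <- new("ParamSpace",
            bounds = data.frame(name = c("x", "k"), lower = c(0, 1),
                                upper = c(1, 4.49), log = FALSE,
                                integer = c(FALSE, TRUE)),
            fixed = list())
  seen <- NULL
  obj <- function(v) { seen <<- c(seen, v[["k"]]); v[["x"]]^2 }
  tpeOptimize(obj, sp, nTrials = 8, nStartup = 8, seed = 2)
  expect_true(all(seen == round(seen)))
})
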