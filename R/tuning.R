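# Phantom-based tuning of the graph-cut parameters: a measurement-error
# objective against known tube dimensions, minimised by a Tree-structured
# Parzen Estimator over the parameter space.

.FAIL_SENTINEL <- 10   # objective value returned when a segmentation fails

#' Default tuning space for the graph-cut parameters
#'
#' Searches the cost weights, smoothness penalty/constraint and separation
#' penalty on log or linear scales; the column geometry (sample step and
#' extents) and the minimum separation stay fixed. Geometry defaults target
#' sub-voxel phantom accuracy: 0.12 mm sample step spanning 0.9 mm inward to
#' 4.2 mm outward of the initial surface, minimum wall one sample.
#'
#' @return A \linkS4class{ParamSpace}.
#' @export
defaultParamSpace <- function() {
  # bounds calibrated on pilot phantom runs; w2In >= 0 because the inner
  # edge of a PSF-blurred wall is only ever displaced inward, and q is kept
  # below the data-cost scale so the separation penalty nudges rather than
  # overrides the outer edge evidence
  bounds <- data.frame(
    name = c("wOut", "p", "delta", "q", "sPref", "w2In", "w2Out"),
    lower = c(0.5, 1, 2, 2, 5, 0, -0.3),
    upper = c(3, 100, 4.49, 50, 8.49, 0.3, 0.3),
    log = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    integer = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  # wIn is the energy's scale gauge (multiplying every weight and penalty by
  # a constant leaves the minimiser unchanged), so it is pinned rather than
  # searched
  new("ParamSpace", bounds = bounds,
      fixed = list(wIn = 1, step = 0.12, lIn = 0.9, lOut = 3.6, sMin = 1))
}

#' Assemble GraphCutParams from a tuning vector
#'
#' @param v named numeric vector over the space's searched dimensions.
#' @param space a \linkS4class{ParamSpace}.
#' @return A \linkS4class{GraphCutParams}.
#' @export
paramsFromVector <- function(v, space) {
  all <- c(as.list(v), space@fixed)
  intd <- space@bounds$name[space@bounds$integer]
  for (nm in intd) all[[nm]] <- round(all[[nm]])
  do.call(graphCutParams, all[names(all) %in% names(formals(graphCutParams))])
}

#' Relative diameter error of one tube
#'
#' The per-tube objective contribution:
#' ( |d_lumen - d_lumen_GT| / d_lumen_GT +
#'   |d_total - d_total_GT| / d_total_GT ) / 2.
#'
#' @param dLumen,dTotal measured diameters, mm.
#' @param gtLumen,gtTotal true diameters, mm.
#' @return Mean unsigned relative error (unitless fraction).
#' @export
diameterError <- function(dLumen, dTotal, gtLumen, gtTotal) {
  (abs(dLumen - gtLumen) / gtLumen + abs(dTotal - gtTotal) / gtTotal) / 2
}

#' Precompute per-tube segmentation context for a phantom
#'
#' For each tube: the ground-truth lumen mask component, its 1-voxel erosion
#' (the deliberately imperfect initial segmentation), the initial surface
#' mesh, the ground-truth centreline samples trimmed clear of the tube ends,
#' and a fine local measurement grid.
#'
#' @param phantom the scanned phantom \linkS4class{ImageVolume}.
#' @param gt the phantom's \linkS4class{GroundTruth}.
#' @param measureSpacing isotropic spacing (mm) of the local measurement grid.
#' @param meshDensity target initial-surface density (vertices per mm^2);
#'   balances column-graph size against angular resolution.
#' @return list of per-tube contexts, for \code{\link{measurementError}}.
#' @export
phantomContext <- function(phantom, gt, measureSpacing = 0.2,
                           meshDensity = Inf) {
  lab <- labelComponents(gt@lumenMask)
  ctx <- vector("list", length(gt@trees))
  for (ti in seq_along(gt@trees)) {
    pts <- branchPoints(gt@trees[[ti]], 1L)
    mid <- pts[ceiling(nrow(pts) / 2), ]
    iv <- round(mid / gt@lumenMask@spacing) + 1
    l <- lab[iv[1], iv[2], iv[3]]
    if (l == 0) stop("tube centreline not inside the ground-truth lumen")
    tubeMask <- maskLike(gt@lumenMask, lab == l)
    init <- erodeMask(tubeMask)
    if (sum(init@values) == 0) stop("erosion emptied tube ", ti)
    mesh <- extractInitialSurface(init, targetDensity = meshDensity)
    gtRow <- gt@branches[ti, ]
    rOut <- gtRow$totalDiameter / 2
    # centreline samples clear of the rounded tube ends
    sc <- sampleCenterline(pts, step = 0.5, excludeEnds = FALSE)
    arc <- sqrt(rowSums(sweep(sc$positions, 2, sc$positions[1, ])^2))
    keep <- arc > rOut + 1 & arc < max(arc) - rOut - 1
    sc$positions <- sc$positions[keep, , drop = FALSE]
    sc$tangents <- sc$tangents[keep, , drop = FALSE]
    # fine local grid around the tube for sub-voxel mask measurement
    lo <- apply(pts, 2, min) - rOut - 3
    hi <- apply(pts, 2, max) + rOut + 3
    dims <- as.integer(ceiling((hi - lo) / measureSpacing)) + 1L
    grid <- imageVolume(array(0, dim = dims), rep(measureSpacing, 3), lo)
    ctx[[ti]] <- list(mesh = mesh, samples = sc, grid = grid,
                      gtLumen = gtRow$lumenDiameter,
                      gtTotal = gtRow$totalDiameter)
  }
  ctx
}

#' Phantom measurement error of a parameter setting
#'
#' Runs the coupled-surface graph cut per tube from the eroded ground-truth
#' lumen, rasterises the surfaces, measures lumen and total diameters along
#' the true centreline, and averages \code{\link{diameterError}} over tubes.
#' Any tube whose segmentation or measurement fails yields a large sentinel
#' value instead of an exception, so a tuner can continue.
#'
#' @param params a \linkS4class{GraphCutParams}.
#' @param phantom the scanned phantom volume.
#' @param gt its \linkS4class{GroundTruth}.
#' @param context optional precomputed \code{\link{phantomContext}}.
#' @param detail return per-tube diameters instead of the scalar objective.
#' @return The scalar objective (or a per-tube data.frame when
#'   \code{detail = TRUE}).
#' @export
measurementError <- function(params, phantom, gt, context = NULL,
                             detail = FALSE) {
  if (!is(params, "GraphCutParams")) stop("params must be GraphCutParams")
  validObject(params)
  if (is.null(context)) context <- phantomContext(phantom, gt)
  rows <- vector("list", length(context))
  for (ti in seq_along(context)) {
    cx <- context[[ti]]
    res <- tryCatch({
      cg <- buildColumns(cx$mesh, phantom, params)
      pair <- solveOptimalSurfaces(cg, params)
      masks <- surfacesToMasks(pair, cx$mesh@faces, cx$grid)
      secs <- do.call(rbind, lapply(seq_len(nrow(cx$samples$positions)),
        function(j) measureCrossSection(masks$lumen, masks$wall,
                                        cx$samples$positions[j, ],
                                        cx$samples$tangents[j, ],
                                        inPlaneStep = 0.125,
                                        halfWidth = cx$gtTotal / 2 + 2)))
      ok <- secs$valid
      if (sum(ok) < 3) stop("too few valid cross-sections")
      data.frame(tube = ti, dLumen = 2 * mean(secs$rIn[ok]),
                 dTotal = 2 * mean(secs$rOut[ok]),
                 gtLumen = cx$gtLumen, gtTotal = cx$gtTotal)
    }, error = function(e) NULL)
    if (is.null(res)) {
      if (detail) res <- data.frame(tube = ti, dLumen = NA, dTotal = NA,
                                    gtLumen = cx$gtLumen, gtTotal = cx$gtTotal)
      else return(.FAIL_SENTINEL)
    }
    rows[[ti]] <- res
  }
  tab <- do.call(rbind, rows)
  if (detail) return(tab)
  mean(diameterError(tab$dLumen, tab$dTotal, tab$gtLumen, tab$gtTotal))
}

# truncated-normal helpers on [lo, hi]
.rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}
.dtnorm <- function(x, mean, sd, lo, hi) {
  z <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  stats::dnorm(x, mean, sd) / pmax(z, 1e-300)
}

#' Tree-structured Parzen Estimator optimisation
#'
#' Minimises a black-box objective over a box-bounded space. The first
#' \code{nStartup} trials are sampled uniformly (in log space for log-scaled
#' dimensions). Thereafter the history is split at the ceil(gamma n)-th best
#' value into good and bad sets; each set is modelled per dimension as a
#' mixture of truncated normal kernels centred at the observed values with
#' bandwidth = dimension range / sqrt(set size). \code{nCandidates} draws
#' from the good density are scored by the good/bad density ratio and the
#' argmax is evaluated next. Deterministic given the seed.
#'
#' @param objective function taking a named numeric vector (integer
#'   dimensions already rounded) and returning a scalar to minimise.
#' @param space a \linkS4class{ParamSpace}.
#' @param nTrials total number of objective evaluations (>= 1).
#' @param gamma fraction of the history modelled as "good" (0 < gamma < 1).
#' @param nStartup uniform startup trials; \code{nTrials <= nStartup} is
#'   plain uniform random search.
#' @param nCandidates candidate draws per TPE step.
#' @param seed RNG seed; the full trial history is reproducible from it.
#' @return A \linkS4class{TuningResult}.
#' @export
tpeOptimize <- function(objective, space, nTrials = 40, gamma = 0.25,
                        nStartup = 10, nCandidates = 24, seed = 1L) {
  stopifnot(nTrials >= 1, gamma > 0, gamma < 1)
  b <- space@bounds
  nd <- nrow(b)
  lo <- b$lower; lo[b$log] <- log(lo[b$log])
  hi <- b$upper; hi[b$log] <- log(hi[b$log])
  toRaw <- function(x) {
    out <- ifelse(b$log, exp(x), x)
    stats::setNames(out, b$name)
  }
  evalRaw <- function(raw) {
    raw[b$integer] <- round(raw[b$integer])
    objective(raw)
  }
  X <- matrix(NA_real_, nTrials, nd)   # transformed coordinates
  val <- numeric(nTrials)
  withSeed(seed, {
    for (tr in seq_len(nTrials)) {
      if (tr <= nStartup) {
        x <- lo + stats::runif(nd) * (hi - lo)
      } else {
        nDone <- tr - 1
        nGood <- ceiling(gamma * nDone)
        ord <- order(val[seq_len(nDone)])
        goodI <- ord[seq_len(nGood)]
        badI <- ord[-seq_len(nGood)]
        if (length(badI) == 0) badI <- goodI
        cand <- matrix(NA_real_, nCandidates, nd)
        score <- numeric(nCandidates)
        bwG <- (hi - lo) / sqrt(length(goodI))
        bwB <- (hi - lo) / sqrt(length(badI))
        for (dd in seq_len(nd)) {
          centres <- X[goodI, dd]
          pick <- centres[sample.int(length(centres), nCandidates,
                                     replace = TRUE)]
          cand[, dd] <- .rtnorm(nCandidates, pick, bwG[dd], lo[dd], hi[dd])
          lg <- vapply(cand[, dd], function(xx)
            mean(.dtnorm(xx, X[goodI, dd], bwG[dd], lo[dd], hi[dd])), 0)
          lb <- vapply(cand[, dd], function(xx)
            mean(.dtnorm(xx, X[badI, dd], bwB[dd], lo[dd], hi[dd])), 0)
          score <- score + log(pmax(lg, 1e-300)) - log(pmax(lb, 1e-300))
        }
        x <- cand[which.max(score), ]
      }
      X[tr, ] <- x
      val[tr] <- evalRaw(toRaw(x))
    }
  })
  raw <- X
  for (d in which(b$log)) raw[, d] <- exp(raw[, d])
  hist <- as.data.frame(raw)
  names(hist) <- b$name
  hist$trial <- seq_len(nTrials)
  hist$value <- val
  best <- which.min(val)
  bestRaw <- toRaw(X[best, ])
  bestRaw[b$integer] <- round(bestRaw[b$integer])
  new("TuningResult", best = bestRaw, bestValue = val[best],
      history = hist, seed = as.numeric(seed))
}

#' Tune graph-cut parameters against a phantom
#'
#' Convenience wrapper: builds the phantom context once and runs
#' \code{\link{tpeOptimize}} on \code{\link{measurementError}}.
#'
#' @param phantom scanned phantom volume.
#' @param gt its ground truth.
#' @param space a \linkS4class{ParamSpace}.
#' @param nTrials,seed,... passed to \code{\link{tpeOptimize}}.
#' @return list with \code{result} (\linkS4class{TuningResult}) and
#'   \code{params} (the best \linkS4class{GraphCutParams}).
#' @export
tuneOnPhantom <- function(phantom, gt, space = defaultParamSpace(),
                          nTrials = 40, seed = 1L, ...) {
  ctx <- phantomContext(phantom, gt)
  obj <- function(v)
    measurementError(paramsFromVector(v, space), phantom, gt, context = ctx)
  res <- tpeOptimize(obj, space, nTrials = nTrials, seed = seed, ...)
  list(result = res, params = paramsFromVector(res@best, space))
}
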