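# Synthetic CT scanner: anti-aliased rasterisation of tube phantoms and
# bifurcating airway trees with exact ground truth, plus a PSF + noise model
# emulating a low-dose helical protocol. Partial-volume fractions come from
# 3x3x3 supersampling of each voxel.

#' @rdname tubeSpec
#' @export
tubeSpec <- function(lumenDiameter, wallThickness, length,
                     axis = c(0, 0, 1), center = c(0, 0, 0)) {
  new("TubeSpec", lumenDiameter = lumenDiameter, wallThickness = wallThickness,
      length = length, axis = axis / sqrt(sum(axis^2)), center = center)
}

#' Constructors for synthetic-scanner specifications
#'
#' \code{tubeSpec} describes one air-filled tube with a soft-tissue wall;
#' \code{phantomSpec} a set of tubes in foam; \code{treeSpec} a recursive
#' bifurcating airway tree; \code{scannerModel} the PSF/noise model.
#'
#' @param lumenDiameter,wallThickness,length tube geometry, mm.
#' @param axis,center tube axis direction and centre position (mm).
#' @param tubes list of \code{TubeSpec}.
#' @param dim integer(3) grid shape.
#' @param spacing numeric(3) voxel spacing, mm.
#' @param huLumen,huWall,huBackground HU plateaus of air, wall and foam.
#' @param rootDiameter,wallFraction,diameterRatio,lengthDiameterRatio,halfAngle
#'   tree geometry; see \linkS4class{TreeSpec}.
#' @param maxGeneration,minDiameter,angleJitter,lengthJitter tree growth limits.
#' @param fwhm,noiseSD scanner PSF full width at half maximum (mm) and
#'   additive Gaussian noise SD (HU).
#' @return The corresponding S4 specification object.
#' @name tubeSpec
#' @export
phantomSpec <- function(tubes, dim, spacing = c(0.6, 0.6, 0.7),
                        huLumen = -1000, huWall = -50, huBackground = -850) {
  new("PhantomSpec", tubes = tubes, dim = as.integer(dim),
      spacing = as.numeric(spacing), huLumen = huLumen, huWall = huWall,
      huBackground = huBackground)
}

#' @rdname tubeSpec
#' @export
treeSpec <- function(rootDiameter = 6, wallFraction = 0.4,
                     diameterRatio = 0.78, lengthDiameterRatio = 3,
                     halfAngle = 35, maxGeneration = 2L, minDiameter = 1,
                     angleJitter = 0, lengthJitter = 0,
                     dim = c(72L, 72L, 72L), spacing = c(0.6, 0.6, 0.7),
                     huLumen = -1000, huWall = -50, huBackground = -850) {
  new("TreeSpec", rootDiameter = rootDiameter, wallFraction = wallFraction,
      diameterRatio = diameterRatio, lengthDiameterRatio = lengthDiameterRatio,
      halfAngle = halfAngle, maxGeneration = as.integer(maxGeneration),
      minDiameter = minDiameter, angleJitter = angleJitter,
      lengthJitter = lengthJitter, dim = as.integer(dim),
      spacing = as.numeric(spacing), huLumen = huLumen, huWall = huWall,
      huBackground = huBackground)
}

#' @rdname tubeSpec
#' @export
scannerModel <- function(fwhm = 0.8, noiseSD = 25) {
  new("ScannerModel", fwhm = fwhm, noiseSD = noiseSD, noiseType = "gaussian")
}

#' Default 8-tube phantom
#'
#' Eight airway-mimicking tubes spanning lumen diameters 3-6 mm and wall
#' thicknesses 0.5-1.5 mm, on the default 0.6 x 0.6 x 0.7 mm grid. This is the
#' package's surrogate for a physical airway phantom with known dimensions;
#' thin and thick walls are deliberately paired against both small and large
#' lumens.
#'
#' @param length tube length, mm.
#' @return A \linkS4class{PhantomSpec} with 8 tubes.
#' @export
defaultPhantomSpec <- function(length = 20) {
  lumen <- c(3.0, 3.4, 3.9, 4.3, 4.7, 5.1, 5.6, 6.0)
  wall <- c(0.6, 1.1, 0.5, 1.3, 0.8, 1.5, 1.0, 1.2)
  spacing <- c(0.6, 0.6, 0.7)
  dimv <- c(110L, 58L, as.integer(ceiling((length + 10) / spacing[3])))
  ext <- (dimv - 1) * spacing
  cx <- (seq_len(4) - 0.5) / 4 * ext[1]
  cy <- c(0.28, 0.72) * ext[2]
  tubes <- vector("list", 8)
  for (i in seq_len(8)) {
    col <- ((i - 1) %% 4) + 1
    row <- ((i - 1) %/% 4) + 1
    tubes[[i]] <- tubeSpec(lumen[i], wall[i], length,
                           center = c(cx[col], cy[row], ext[3] / 2))
  }
  phantomSpec(tubes, dimv, spacing)
}

# distance from points to a capsule segment [a, b] (t clamped -> rounded
# caps); used for airway-tree segments
.segDist <- function(px, py, pz, a, b) {
  d <- b - a
  len2 <- sum(d^2)
  vx <- px - a[1]; vy <- py - a[2]; vz <- pz - a[3]
  t <- (vx * d[1] + vy * d[2] + vz * d[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  dx <- vx - t * d[1]; dy <- vy - t * d[2]; dz <- vz - t * d[3]
  sqrt(dx * dx + dy * dy + dz * dz)
}

# radial distance and axial-inside flag for a flat-ended cylinder [a, b];
# used for phantom tubes (annular cross-section along the whole length)
.cylDist <- function(px, py, pz, a, b) {
  d <- b - a
  len2 <- sum(d^2)
  vx <- px - a[1]; vy <- py - a[2]; vz <- pz - a[3]
  t <- (vx * d[1] + vy * d[2] + vz * d[3]) / len2
  dx <- vx - t * d[1]; dy <- vy - t * d[2]; dz <- vz - t * d[3]
  list(radial = sqrt(dx * dx + dy * dy + dz * dz), axial = t >= 0 & t <= 1)
}

# supersampling offsets (27 x 3) in voxel-fraction units
.ssOffsets <- function() {
  o <- c(-1 / 3, 0, 1 / 3)
  as.matrix(expand.grid(x = o, y = o, z = o))
}

#' Rasterise a tube phantom
#'
#' Renders each tube as an annulus in cross-section with analytic
#' partial-volume anti-aliasing (voxel value = HU mixture weighted by the
#' subsampled in-lumen / in-wall fraction) and returns exact ground truth.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{volume} (\linkS4class{ImageVolume}) and
#'   \code{groundTruth} (\linkS4class{GroundTruth}).
#' @export
rasterizeTubePhantom <- function(spec) {
  validObject(spec)
  d <- spec@dim
  sp <- spec@spacing
  vol0 <- imageVolume(array(0, dim = d), sp)
  ax <- gridAxes(vol0)
  extent <- (d - 1) * sp
  fracL <- array(0, dim = d)
  fracW <- array(0, dim = d)
  gtL <- array(0, dim = d)
  gtW <- array(0, dim = d)
  owner <- array(0L, dim = d)
  offs <- .ssOffsets()
  trees <- list()
  br <- NULL
  for (ti in seq_along(spec@tubes)) {
    tb <- spec@tubes[[ti]]
    rIn <- tb@lumenDiameter / 2
    rOut <- rIn + tb@wallThickness
    a <- tb@center - tb@axis * tb@length / 2
    b <- tb@center + tb@axis * tb@length / 2
    # flat-ended cylinder: radial extent contributes per axis only by the
    # component perpendicular to the tube axis
    marg <- rOut * sqrt(pmax(0, 1 - tb@axis^2))
    lo <- pmin(a, b) - marg
    hi <- pmax(a, b) + marg
    if (any(lo < -1e-9) || any(hi > extent + 1e-9))
      stop("tube ", ti, " outside the grid")
    ix <- which(ax[[1]] >= lo[1] - sp[1] & ax[[1]] <= hi[1] + sp[1])
    iy <- which(ax[[2]] >= lo[2] - sp[2] & ax[[2]] <= hi[2] + sp[2])
    iz <- which(ax[[3]] >= lo[3] - sp[3] & ax[[3]] <= hi[3] + sp[3])
    nb <- c(length(ix), length(iy), length(iz))
    px0 <- array(rep(ax[[1]][ix], times = nb[2] * nb[3]), dim = nb)
    py0 <- array(rep(rep(ax[[2]][iy], each = nb[1]), times = nb[3]), dim = nb)
    pz0 <- array(rep(ax[[3]][iz], each = nb[1] * nb[2]), dim = nb)
    cntL <- array(0, dim = nb)
    cntW <- array(0, dim = nb)
    for (o in seq_len(nrow(offs))) {
      cd <- .cylDist(px0 + offs[o, 1] * sp[1], py0 + offs[o, 2] * sp[2],
                     pz0 + offs[o, 3] * sp[3], a, b)
      inL <- cd$axial & cd$radial <= rIn
      cntL <- cntL + inL
      cntW <- cntW + (!inL & cd$axial & cd$radial <= rOut)
    }
    fracL[ix, iy, iz] <- fracL[ix, iy, iz] + cntL / 27
    fracW[ix, iy, iz] <- fracW[ix, iy, iz] + cntW / 27
    cd0 <- .cylDist(px0, py0, pz0, a, b)
    gl <- cd0$axial & cd0$radial < rIn
    gw <- !gl & cd0$axial & cd0$radial < rOut
    prevOwner <- owner[ix, iy, iz]
    if (any(prevOwner != 0 & (gl | gw))) stop("overlapping tubes")
    ow <- prevOwner
    ow[gl | gw] <- ti
    owner[ix, iy, iz] <- ow
    gtL[ix, iy, iz] <- gtL[ix, iy, iz] + gl
    gtW[ix, iy, iz] <- gtW[ix, iy, iz] + gw
    npts <- max(2L, floor(tb@length / 0.5) + 1L)
    tpts <- seq(0, 1, length.out = npts)
    pts <- cbind(a[1] + tpts * (b[1] - a[1]), a[2] + tpts * (b[2] - a[2]),
                 a[3] + tpts * (b[3] - a[3]))
    trees[[ti]] <- newCenterlineTree(list(list(id = 1L, parent = NA_integer_,
                                               generation = 0L, points = pts)))
    br <- rbind(br, data.frame(tree = ti, id = 1L, generation = 0L,
                               lumenDiameter = tb@lumenDiameter,
                               totalDiameter = 2 * rOut, length = tb@length))
  }
  hu <- spec@huBackground + fracL * (spec@huLumen - spec@huBackground) +
    fracW * (spec@huWall - spec@huBackground)
  gt <- new("GroundTruth",
            lumenMask = binaryMask(gtL, sp), wallMask = binaryMask(gtW, sp),
            trees = trees, branches = br)
  list(volume = imageVolume(hu, sp), groundTruth = gt)
}

# rotate vector v by angle (deg) toward unit vector b (both unit, orthogonal)
.rot <- function(v, b, angleDeg) {
  th <- angleDeg * pi / 180
  cos(th) * v + sin(th) * b
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# grow the segment list of a bifurcating tree; jitters consume RNG
.growTree <- function(spec) {
  segs <- list()
  extent <- (spec@dim - 1) * spec@spacing
  rootR <- spec@rootDiameter / 2
  rootROut <- rootR * (1 + spec@wallFraction)
  start <- c(extent[1] / 2, extent[2] / 2, extent[3] - rootROut - 1.5)
  recurse <- function(start, dir, bvec, diam, gen, parent) {
    len <- spec@lengthDiameterRatio * diam
    if (spec@lengthJitter > 0)
      len <- len * (1 + spec@lengthJitter * stats::runif(1, -1, 1))
    end <- start + dir * len
    id <- length(segs) + 1L
    segs[[id]] <<- list(id = id, parent = parent, generation = gen,
                        start = start, end = end, rIn = diam / 2,
                        rOut = diam / 2 * (1 + spec@wallFraction), len = len)
    childDiam <- diam * spec@diameterRatio
    if (gen < spec@maxGeneration && childDiam >= spec@minDiameter) {
      for (sgn in c(1, -1)) {
        ang <- spec@halfAngle
        if (spec@angleJitter > 0)
          ang <- ang * (1 + spec@angleJitter * stats::runif(1, -1, 1))
        cdir <- .rot(dir, sgn * bvec, ang)
        cdir <- cdir / sqrt(sum(cdir^2))
        cb <- .cross3(cdir, bvec)
        cb <- cb / sqrt(sum(cb^2))
        recurse(end, cdir, cb, childDiam, gen + 1L, id)
      }
    }
  }
  recurse(start, c(0, 0, -1), c(1, 0, 0), spec@rootDiameter, 0L, NA_integer_)
  for (s in segs) {
    lo <- pmin(s$start, s$end) - s$rOut
    hi <- pmax(s$start, s$end) + s$rOut
    if (any(lo < -1e-9) || any(hi > extent + 1e-9))
      stop("tree escapes the grid (segment ", s$id, ")")
  }
  if (2 * min(vapply(segs, `[[`, 0, "rIn")) < 2 * max(spec@spacing[1:2]))
    warning("smallest branch diameter is below 2x the in-plane spacing")
  segs
}

#' Rasterise a bifurcating airway tree
#'
#' Recursive symmetric bifurcation from a root segment growing caudally:
#' child diameter = parent diameter x \code{diameterRatio}, branch length
#' proportional to its diameter, branching plane rotated 90 degrees per
#' generation. Segments are rendered as capsules (cylinders with spherical
#' caps), which rounds every bifurcation by a sphere of the parent radius.
#' Anti-aliased like \code{\link{rasterizeTubePhantom}}.
#'
#' @param spec a \linkS4class{TreeSpec}.
#' @param seed RNG seed for the angle/length jitters (irrelevant when both
#'   jitters are 0, but still fixed for reproducibility).
#' @return list with \code{volume}, \code{groundTruth}.
#' @export
rasterizeAirwayTree <- function(spec, seed = 1L) {
  validObject(spec)
  segs <- withSeed(seed, .growTree(spec))
  d <- spec@dim
  sp <- spec@spacing
  vol0 <- imageVolume(array(0, dim = d), sp)
  ax <- gridAxes(vol0)
  offs <- .ssOffsets()
  cntL <- array(0L, dim = d)
  cntW <- array(0L, dim = d)
  bbox <- lapply(segs, function(s) {
    lo <- pmin(s$start, s$end) - s$rOut - max(sp)
    hi <- pmax(s$start, s$end) + s$rOut + max(sp)
    list(ix = which(ax[[1]] >= lo[1] & ax[[1]] <= hi[1]),
         iy = which(ax[[2]] >= lo[2] & ax[[2]] <= hi[2]),
         iz = which(ax[[3]] >= lo[3] & ax[[3]] <= hi[3]))
  })
  classify <- function(shift) {
    inL <- array(FALSE, dim = d)
    inW <- array(FALSE, dim = d)
    for (si in seq_along(segs)) {
      s <- segs[[si]]
      bb <- bbox[[si]]
      nb <- c(length(bb$ix), length(bb$iy), length(bb$iz))
      px <- array(rep(ax[[1]][bb$ix] + shift[1], times = nb[2] * nb[3]),
                  dim = nb)
      py <- array(rep(rep(ax[[2]][bb$iy] + shift[2], each = nb[1]),
                      times = nb[3]), dim = nb)
      pz <- array(rep(ax[[3]][bb$iz] + shift[3], each = nb[1] * nb[2]),
                  dim = nb)
      dist <- .segDist(px, py, pz, s$start, s$end)
      inL[bb$ix, bb$iy, bb$iz] <- inL[bb$ix, bb$iy, bb$iz] | (dist <= s$rIn)
      inW[bb$ix, bb$iy, bb$iz] <- inW[bb$ix, bb$iy, bb$iz] | (dist <= s$rOut)
    }
    list(L = inL, W = inW & !inL)
  }
  for (o in seq_len(nrow(offs))) {
    cl <- classify(offs[o, ] * sp)
    cntL <- cntL + cl$L
    cntW <- cntW + cl$W
  }
  fracL <- cntL / 27
  fracW <- cntW / 27
  hu <- spec@huBackground + fracL * (spec@huLumen - spec@huBackground) +
    fracW * (spec@huWall - spec@huBackground)
  cl0 <- classify(c(0, 0, 0))
  branches <- lapply(segs, function(s) {
    npts <- max(2L, floor(s$len / 0.5) + 1L)
    tpts <- seq(0, 1, length.out = npts)
    pts <- cbind(s$start[1] + tpts * (s$end[1] - s$start[1]),
                 s$start[2] + tpts * (s$end[2] - s$start[2]),
                 s$start[3] + tpts * (s$end[3] - s$start[3]))
    list(id = s$id, parent = s$parent, generation = s$generation, points = pts)
  })
  br <- do.call(rbind, lapply(segs, function(s)
    data.frame(tree = 1L, id = s$id, generation = s$generation,
               lumenDiameter = 2 * s$rIn, totalDiameter = 2 * s$rOut,
               length = s$len)))
  gt <- new("GroundTruth",
            lumenMask = binaryMask(cl0$L, sp), wallMask = binaryMask(cl0$W, sp),
            trees = list(newCenterlineTree(branches)), branches = br)
  list(volume = imageVolume(hu, sp), groundTruth = gt)
}

#' Apply the scanner model to an ideal volume
#'
#' Gaussian blur with the stated FWHM (separable, reflecting boundary) then
#' additive Gaussian noise with the stated SD; deterministic given the seed.
#'
#' @param ideal an \linkS4class{ImageVolume}.
#' @param model a \linkS4class{ScannerModel}.
#' @param seed RNG seed for the noise.
#' @return An \linkS4class{ImageVolume}.
#' @export
applyScannerModel <- function(ideal, model, seed = 1L) {
  validObject(model)
  v <- ideal@values
  d <- dim(v)
  if (model@fwhm > 0) {
    sigma <- model@fwhm / (2 * sqrt(2 * log(2)))
    flat <- as.numeric(v)
    for (axis in 1:3) {
      sv <- sigma / ideal@spacing[axis]
      flat <- cpp_convolve_axis(flat, d, gaussKernel1d(sv), axis - 1L)
    }
    v <- array(flat, dim = d)
  }
  if (model@noiseSD > 0)
    v <- v + withSeed(seed, array(stats::rnorm(length(v), 0, model@noiseSD),
                                  dim = d))
  imageVolume(v, ideal@spacing, ideal@origin)
}

#' Simulate a short-term repeat-scan pair
#'
#' The second scan re-renders the same tree (same topology and jitters) with
#' every linear dimension scaled by \code{inflationFactor^(1/3)} and an
#' independent noise realisation, emulating a difference in inspiration
#' level. The total-lung-volume surrogate is proportional to the rasterised
#' lumen volume, so TLV2/TLV1 equals the inflation factor up to rasterisation
#' error.
#'
#' @param spec a \linkS4class{TreeSpec} for the first scan.
#' @param model a \linkS4class{ScannerModel}.
#' @param inflationFactor volume ratio scan2/scan1 (> 0); 1 = same inflation.
#' @param seeds integer pair: noise seeds for scan 1 and scan 2.
#' @param treeSeed seed for the tree jitters, shared by both scans.
#' @param tlvScale litres of surrogate lung per mm^3 of airway lumen; the
#'   default puts the default tree near a realistic 5.5 L.
#' @return list with \code{scan1}, \code{scan2}, \code{gt1}, \code{gt2},
#'   \code{tlv} (litres, length 2).
#' @export
simulateRepeatPair <- function(spec, model, inflationFactor = 1,
                               seeds = c(1L, 2L), treeSeed = seeds[1],
                               tlvScale = 4.3e-3) {
  stopifnot(inflationFactor > 0)
  s <- inflationFactor^(1 / 3)
  spec2 <- spec
  spec2@rootDiameter <- spec@rootDiameter * s
  spec2@minDiameter <- spec@minDiameter * s
  r1 <- rasterizeAirwayTree(spec, seed = treeSeed)
  r2 <- rasterizeAirwayTree(spec2, seed = treeSeed)
  scan1 <- applyScannerModel(r1$volume, model, seed = seeds[1])
  scan2 <- applyScannerModel(r2$volume, model, seed = seeds[2])
  tlv <- vapply(list(r1, r2), function(r)
    sum(r$groundTruth@lumenMask@values) * prod(voxelSpacing(r$volume)) *
      tlvScale, 0)
  list(scan1 = scan1, scan2 = scan2, gt1 = r1$groundTruth,
       gt2 = r2$groundTruth, tlv = tlv)
}
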