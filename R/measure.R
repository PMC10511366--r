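# Bronchial parameter measurement: cross-sections every 0.5 mm along branch
# centrelines, branch-level aggregation (LA, WA, WAP, SRWA, Pi), Pi10,
# per-scan summaries, and segmentation scoring against ground truth.

#' Sample a branch centreline at regular arc-length intervals
#'
#' Arc-length parameterised samples at 0, step, 2 step, ... along the
#' (lightly smoothed) centreline, inclusive of the start and exclusive of a
#' final partial step. Tangents come from central differences. The first and
#' last samples within one step of a branch end are dropped, excluding the
#' non-tubular cross-sections at bifurcations.
#'
#' @param points k x 3 matrix of ordered centreline points (mm), e.g. from
#'   \code{\link{branchPoints}}.
#' @param step sampling interval, mm.
#' @param excludeEnds drop samples within one step of either end (default
#'   TRUE; set FALSE for free-standing tubes).
#' @return list with \code{positions} (m x 3) and \code{tangents} (m x 3);
#'   zero rows when the branch is shorter than one step after exclusions.
#' @export
sampleCenterline <- function(points, step = 0.5, excludeEnds = TRUE) {
  empty <- list(positions = matrix(numeric(0), ncol = 3),
                tangents = matrix(numeric(0), ncol = 3))
  if (is.null(points) || nrow(points) < 2) return(empty)
  # moving-average smoothing of the voxel-snapped polyline
  pts <- points
  if (nrow(pts) >= 5) {
    sm <- pts
    for (i in 2:(nrow(pts) - 1))
      sm[i, ] <- (pts[i - 1, ] + pts[i, ] + pts[i + 1, ]) / 3
    pts <- sm
  }
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (total <= 0) return(empty)
  svals <- seq(0, total, by = step)
  if (excludeEnds)
    svals <- svals[svals >= step - 1e-9 & svals <= total - step + 1e-9]
  if (!length(svals)) return(empty)
  interp <- function(s) {
    i <- findInterval(s, arc, rightmost.closed = TRUE)
    i <- min(max(i, 1), length(seg))
    w <- if (seg[i] > 0) (s - arc[i]) / seg[i] else 0
    pts[i, ] + w * (pts[i + 1, ] - pts[i, ])
  }
  pos <- t(vapply(svals, interp, numeric(3)))
  eps <- min(step / 2, total / 4)
  tan <- t(vapply(svals, function(s) {
    a <- interp(max(0, s - eps)); b <- interp(min(total, s + eps))
    d <- b - a
    d / max(sqrt(sum(d^2)), 1e-12)
  }, numeric(3)))
  list(positions = pos, tangents = tan)
}

#' Measure one airway cross-section
#'
#' Resamples the lumen and wall masks on a plane perpendicular to the
#' tangent (bilinear, then thresholded at 0.5), keeps the connected in-plane
#' region containing the centre point, and converts region areas to
#' area-equivalent radii: r_in = sqrt(A_lumen / pi),
#' r_out = sqrt((A_lumen + A_wall) / pi). The section is invalid when the
#' centre point is not inside the lumen region or the plane leaves the
#' volume.
#'
#' @param lumen,wall aligned \linkS4class{BinaryMask}s.
#' @param position,tangent centre point (mm) and unit tangent.
#' @param inPlaneStep in-plane resampling step, mm.
#' @param halfWidth half-width of the sampling plane, mm.
#' @return data.frame row: x, y, z, rIn, rOut, valid.
#' @export
measureCrossSection <- function(lumen, wall, position, tangent,
                                inPlaneStep = 0.25, halfWidth = 10) {
  stopifnot(sqrt(sum(tangent^2)) > 0)
  bas <- planeBasis(tangent)
  gr <- seq(-halfWidth, halfWidth, by = inPlaneStep)
  m <- length(gr)
  uu <- rep(gr, times = m)
  vv <- rep(gr, each = m)
  pts <- cbind(position[1] + uu * bas$u[1] + vv * bas$v[1],
               position[2] + uu * bas$u[2] + vv * bas$v[2],
               position[3] + uu * bas$u[3] + vv * bas$v[3])
  lum <- interpolateAt(lumen, pts)
  wal <- interpolateAt(wall, pts)
  lum[is.na(lum)] <- 0
  wal[is.na(wal)] <- 0
  lumB <- matrix(lum >= 0.5, m, m)
  walB <- matrix(wal >= 0.5, m, m) & !lumB
  ctr <- (m + 1) / 2
  invalid <- data.frame(x = position[1], y = position[2], z = position[3],
                        rIn = NA_real_, rOut = NA_real_, valid = FALSE)
  if (!lumB[ctr, ctr]) return(invalid)
  # 8-connected 2D labelling via the 3D kernel on a depth-1 slab
  lab2 <- function(b) {
    array(cpp_label_components(as.integer(b), c(m, m, 1L), 26L), dim = c(m, m))
  }
  lumLab <- lab2(lumB)
  lumRegion <- lumLab == lumLab[ctr, ctr]
  uniLab <- lab2(lumB | walB)
  uniRegion <- uniLab == uniLab[ctr, ctr]
  cellA <- inPlaneStep^2
  aLum <- sum(lumRegion) * cellA
  aTot <- sum(uniRegion) * cellA
  data.frame(x = position[1], y = position[2], z = position[3],
             rIn = sqrt(aLum / pi), rOut = sqrt(aTot / pi), valid = TRUE)
}

#' Aggregate cross-sections into branch-level bronchial parameters
#'
#' Per-section areas are computed first and then averaged (the average of
#' areas, not the area of the average radius): LA_i = pi r_in_i^2,
#' total_i = pi r_out_i^2, WA_i = total_i - LA_i, Pi_i = 2 pi r_in_i.
#' Branch LA, WA and Pi are means over valid sections;
#' WAP = 100 WA / (WA + LA); SRWA = sqrt(WA).
#'
#' @param sections data.frame of cross-section rows
#'   (\code{\link{measureCrossSection}}).
#' @param id,generation,length branch metadata.
#' @return One-row data.frame (a branch measurement), or NULL when no valid
#'   section exists.
#' @export
aggregateBranch <- function(sections, id = NA_integer_,
                            generation = NA_integer_, length = NA_real_) {
  ok <- sections$valid & !is.na(sections$rIn)
  if (!any(ok)) return(NULL)
  rIn <- sections$rIn[ok]
  rOut <- sections$rOut[ok]
  la <- mean(pi * rIn^2)
  tot <- mean(pi * rOut^2)
  wa <- tot - la
  pin <- mean(2 * pi * rIn)
  data.frame(id = id, generation = generation, length = length,
             nSections = sum(ok), meanRIn = mean(rIn), meanROut = mean(rOut),
             LA = la, WA = wa, WAP = 100 * wa / (wa + la), SRWA = sqrt(wa),
             Pi = pin)
}

#' Pi10 from branch measurements
#'
#' Ordinary least squares of SRWA on the internal perimeter Pi over branches
#' of generations 1 through 6 (the trachea is excluded); Pi10 is the fitted
#' SRWA at Pi = 10 mm.
#'
#' @param branches data.frame of branch measurements with columns
#'   \code{generation}, \code{SRWA}, \code{Pi}.
#' @return Pi10 in mm.
#' @export
computePi10 <- function(branches) {
  b <- branches[branches$generation >= 1 & branches$generation <= 6, ,
                drop = FALSE]
  if (nrow(b) < 2 || length(unique(b$Pi)) < 2)
    stop("Pi10 undefined: fewer than 2 distinct perimeters in generations 1-6")
  fit <- stats::lm(SRWA ~ Pi, data = b)
  unname(stats::coef(fit)[1] + 10 * stats::coef(fit)[2])
}

#' Measure every branch of a tree against lumen and wall masks
#'
#' Runs \code{\link{sampleCenterline}} and \code{\link{measureCrossSection}}
#' for each branch and aggregates with \code{\link{aggregateBranch}};
#' branches with no valid cross-section are excluded.
#'
#' @param tree a \linkS4class{CenterlineTree}.
#' @param lumen,wall aligned \linkS4class{BinaryMask}s.
#' @param step centreline sampling interval, mm.
#' @param inPlaneStep in-plane resampling step, mm.
#' @param halfWidth sampling plane half-width, mm.
#' @return data.frame of branch measurements.
#' @export
measureTree <- function(tree, lumen, wall, step = 0.5, inPlaneStep = 0.25,
                        halfWidth = 10) {
  m <- branchMeta(tree)
  out <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    sc <- sampleCenterline(branchPoints(tree, m$id[i]), step = step)
    if (nrow(sc$positions) == 0) next
    secs <- do.call(rbind, lapply(seq_len(nrow(sc$positions)), function(j)
      measureCrossSection(lumen, wall, sc$positions[j, ], sc$tangents[j, ],
                          inPlaneStep = inPlaneStep, halfWidth = halfWidth)))
    out[[i]] <- aggregateBranch(secs, id = m$id[i],
                                generation = m$generation[i],
                                length = m$length[i])
  }
  do.call(rbind, out)
}

#' Summarise a measured scan
#'
#' Per-generation arithmetic means of branch LA and WAP, the total airway
#' count (TAC, branches with a valid measurement), Pi10 (absent when
#' undefined) and the deepest generation. TLV is an externally supplied
#' scalar in litres.
#'
#' @param measurements data.frame of branch measurements
#'   (\code{\link{measureTree}}).
#' @param tlv total lung volume, litres.
#' @return A \linkS4class{ScanSummary}.
#' @export
summarizeScan <- function(measurements, tlv = NA_real_) {
  stopifnot(nrow(measurements) >= 1)
  gens <- sort(unique(measurements$generation))
  genLA <- vapply(gens, function(g)
    mean(measurements$LA[measurements$generation == g]), 0)
  genWAP <- vapply(gens, function(g)
    mean(measurements$WAP[measurements$generation == g]), 0)
  names(genLA) <- names(genWAP) <- as.character(gens)
  pi10 <- tryCatch(computePi10(measurements), error = function(e) NA_real_)
  new("ScanSummary", genLA = genLA, genWAP = genWAP, pi10 = pi10,
      tac = nrow(measurements), tlv = tlv, maxGeneration = max(gens))
}

#' Score a segmentation against ground truth
#'
#' Dice overlap of the masks, centreline completeness (percentage of
#' ground-truth centreline length whose points fall inside the predicted
#' mask) and centreline leakage (percentage of the predicted mask's own
#' centreline length falling outside the ground-truth mask; the predicted
#' centreline comes from \code{\link{extractBranches}} on the prediction).
#'
#' @param pred,gt aligned \linkS4class{BinaryMask}s.
#' @param gtCenterline the ground-truth \linkS4class{CenterlineTree}.
#' @param predCenterline optional precomputed centreline of \code{pred};
#'   extracted when omitted.
#' @return data.frame with dice, completeness, leakage.
#' @export
segmentationMetrics <- function(pred, gt, gtCenterline,
                                predCenterline = NULL) {
  P <- pred@values != 0
  G <- gt@values != 0
  if (!any(P) || !any(G)) stop("empty mask")
  dice <- 2 * sum(P & G) / (sum(P) + sum(G))
  inMask <- function(mask, pts) {
    iv <- round(worldToIndex(mask, pts)) + 1
    d <- dim(mask@values)
    ok <- iv[, 1] >= 1 & iv[, 2] >= 1 & iv[, 3] >= 1 &
      iv[, 1] <= d[1] & iv[, 2] <= d[2] & iv[, 3] <= d[3]
    res <- rep(FALSE, nrow(pts))
    res[ok] <- mask@values[iv[ok, , drop = FALSE]] != 0
    res
  }
  lengthInside <- function(tree, mask) {
    tot <- 0; ins <- 0
    for (id in branchMeta(tree)$id) {
      pts <- branchPoints(tree, id)
      if (is.null(pts) || nrow(pts) < 2) next
      seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2))
      mid <- (pts[-1, , drop = FALSE] + pts[-nrow(pts), , drop = FALSE]) / 2
      inside <- inMask(mask, mid)
      tot <- tot + sum(seg)
      ins <- ins + sum(seg[inside])
    }
    c(total = tot, inside = ins)
  }
  comp <- lengthInside(gtCenterline, pred)
  completeness <- 100 * comp["inside"] / comp["total"]
  if (is.null(predCenterline)) {
    # centreline of every predicted component, so that disjoint spurious
    # structures contribute to leakage
    lab <- labelComponents(pred)
    leak <- c(total = 0, inside = 0)
    for (l in seq_len(max(lab))) {
      cm <- maskLike(pred, lab == l)
      ct <- extractBranches(cm, findTracheaSeed(cm))
      leak <- leak + lengthInside(ct, gt)
    }
  } else {
    leak <- lengthInside(predCenterline, gt)
  }
  leakage <- 100 * (leak[["total"]] - leak[["inside"]]) / leak[["total"]]
  data.frame(dice = dice, completeness = unname(completeness),
             leakage = unname(leakage))
}
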