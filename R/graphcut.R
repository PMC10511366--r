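# Coupled two-surface optimal-surface graph cut. The inner (lumen) and outer
# (wall) surfaces pick one sample per column; smoothness and separation terms
# are encoded in a boundary-of-closed-set min-cut construction solved by
# igraph's max-flow, which yields the global optimum.

.BIGCOST <- 1e8    # sentinel replacing +Inf for out-of-volume samples
.INFCAP <- 1e12    # "infinite" arc capacity for hard constraints

#' Graph-cut parameter constructor
#'
#' @param wIn,wOut inner/outer first-derivative cost weights.
#' @param w2In,w2Out optional second-derivative weights (default 0; positive
#'   values add a ridge-sensitivity term to the corresponding cost).
#' @param delta hard smoothness constraint (max neighbour index difference).
#' @param p smoothness penalty per unit index difference.
#' @param q one-sided separation penalty per sample beyond \code{sPref}.
#' @param sMin,sPref minimum and preferred inner/outer separation (samples).
#' @param lIn,lOut column extent inward/outward of the base (mm).
#' @param step sample step along the column (mm).
#' @return A \linkS4class{GraphCutParams}.
#' @export
graphCutParams <- function(wIn = 1, wOut = 1, w2In = 0, w2Out = 0, delta = 2,
                           p = 0.5, q = 0.5, sMin = 1, sPref = 4,
                           lIn = 3, lOut = 5, step = 0.3) {
  new("GraphCutParams", wIn = wIn, wOut = wOut, w2In = w2In, w2Out = w2Out,
      delta = round(delta), p = p, q = q, sMin = round(sMin),
      sPref = round(sPref), lIn = lIn, lOut = lOut, step = step)
}

#' Build sampling columns from a surface mesh
#'
#' Casts one straight column per mesh vertex along its outward normal,
#' sampling the volume by trilinear interpolation at \code{step} mm from
#' \code{-lIn} to \code{+lOut} around the base. The inner-surface cost
#' rewards dark-to-bright transitions (lumen air into wall), the outer cost
#' bright-to-dark (wall into parenchyma): with the central-difference
#' derivative g', cost_in(k) = -wIn g'(k) and cost_out(k) = +wOut g'(k),
#' plus optional second-derivative terms. Samples outside the volume carry a
#' large finite sentinel cost.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param volume the \linkS4class{ImageVolume} to sample.
#' @param params a \linkS4class{GraphCutParams}.
#' @return A \linkS4class{ColumnGraph}.
#' @export
buildColumns <- function(mesh, volume, params) {
  offsets <- seq(-params@lIn, params@lOut, by = params@step)
  K <- length(offsets)
  if (K < 2) stop("fewer than 2 samples per column; shrink step")
  n <- nrow(mesh@vertices)
  nrm <- sqrt(rowSums(mesh@normals^2))
  if (any(nrm < 1e-9)) stop("degenerate normal")
  pts <- matrix(0, n * K, 3)
  for (k in seq_len(K))
    pts[(k - 1) * n + seq_len(n), ] <- mesh@vertices + offsets[k] * mesh@normals
  intens <- matrix(interpolateAt(volume, pts), nrow = n, ncol = K)
  h <- params@step
  g1 <- matrix(NA_real_, n, K)
  g1[, 2:(K - 1)] <- (intens[, 3:K] - intens[, 1:(K - 2)]) / (2 * h)
  g1[, 1] <- (intens[, 2] - intens[, 1]) / h
  g1[, K] <- (intens[, K] - intens[, K - 1]) / h
  costIn <- -params@wIn * g1
  costOut <- params@wOut * g1
  if (params@w2In != 0 || params@w2Out != 0) {
    g2 <- matrix(NA_real_, n, K)
    g2[, 2:(K - 1)] <- (intens[, 3:K] - 2 * intens[, 2:(K - 1)] +
                          intens[, 1:(K - 2)]) / h^2
    g2[is.na(g2)] <- 0
    costIn <- costIn + params@w2In * g2
    costOut <- costOut + params@w2Out * g2
  }
  costIn[!is.finite(costIn)] <- .BIGCOST
  costOut[!is.finite(costOut)] <- .BIGCOST
  new("ColumnGraph", base = mesh@vertices, dir = mesh@normals,
      offsets = offsets, intensity = intens, costIn = costIn,
      costOut = costOut, edges = mesh@edges, step = params@step)
}

#' Energy of a coupled-surface configuration
#'
#' The objective minimised by \code{\link{solveOptimalSurfaces}}: summed
#' per-column inner and outer costs, plus p times the summed neighbour index
#' differences of both surfaces, plus q times the separation exceeding
#' sPref, summed over columns.
#'
#' @param graph a \linkS4class{ColumnGraph}.
#' @param kIn,kOut 1-based sample indices per column.
#' @param params a \linkS4class{GraphCutParams}.
#' @return The scalar energy (Inf when a hard constraint is violated).
#' @export
surfaceEnergy <- function(graph, kIn, kOut, params) {
  n <- nrow(graph@costIn)
  e <- graph@edges
  if (any(kOut - kIn < params@sMin)) return(Inf)
  if (nrow(e) && (any(abs(kIn[e[, 1]] - kIn[e[, 2]]) > params@delta) ||
                  any(abs(kOut[e[, 1]] - kOut[e[, 2]]) > params@delta)))
    return(Inf)
  dataE <- sum(graph@costIn[cbind(seq_len(n), kIn)]) +
    sum(graph@costOut[cbind(seq_len(n), kOut)])
  smoothE <- if (nrow(e))
    params@p * (sum(abs(kIn[e[, 1]] - kIn[e[, 2]])) +
                  sum(abs(kOut[e[, 1]] - kOut[e[, 2]]))) else 0
  sepE <- params@q * sum(pmax(0, (kOut - kIn) - params@sPref))
  dataE + smoothE + sepE
}

#' Solve for the globally optimal coupled surfaces
#'
#' Minimises \code{\link{surfaceEnergy}} subject to the hard constraints
#' |k(u) - k(v)| <= delta per surface per neighbour pair and
#' k_out - k_in >= sMin per column, by the standard transformation to a
#' minimum s-t cut: one node chain per column per surface, infinite
#' intra-column monotonicity arcs, inter-column arcs encoding delta and p,
#' and inter-surface arcs encoding sMin and q. Ties are broken toward
#' smaller sample indices via an infinitesimal index penalty.
#'
#' @param graph a \linkS4class{ColumnGraph}.
#' @param params a \linkS4class{GraphCutParams}.
#' @return A \linkS4class{SurfacePair} with the realised energy.
#' @export
solveOptimalSurfaces <- function(graph, params) {
  cIn <- graph@costIn
  cOut <- graph@costOut
  n <- nrow(cIn)
  K <- ncol(cIn)
  # max-flow needs non-negative capacities; shifting a column's costs by a
  # constant changes every configuration's energy equally (each column picks
  # exactly one sample per surface), so the minimiser is unchanged
  cIn <- cIn - apply(cIn, 1, min)
  cOut <- cOut - apply(cOut, 1, min)
  delta <- as.integer(round(params@delta))
  sMin <- as.integer(round(params@sMin))
  sPref <- as.integer(round(params@sPref))
  if (sMin > K - 1) stop("infeasible constraints: sMin exceeds K - 1")
  # node ids: surface s in {0 inner, 1 outer}, column v, level k (0-based):
  # id = s*n*K + (v-1)*K + k + 1; then source, sink
  nid <- function(s, v, k) s * n * K + (v - 1L) * K + k + 1L
  SRC <- 2L * n * K + 1L
  SNK <- 2L * n * K + 2L
  eps <- 1e-7 * max(1, stats::median(abs(cIn[cIn < .BIGCOST / 2]), na.rm = TRUE),
                    na.rm = TRUE)
  lev <- rep(0:(K - 1), each = n)
  vcol <- rep(seq_len(n), times = K)

  from <- list(); to <- list(); cap <- list(); ei <- 0
  add <- function(f, t, cp) {
    ei <<- ei + 1
    from[[ei]] <<- f; to[[ei]] <<- t; cap[[ei]] <<- cp
  }
  for (s in 0:1) {
    cost <- if (s == 0) cIn else cOut
    # data arcs: n(v,k) -> n(v,k+1), last level -> sink; cutting the arc at
    # level k selects sample k for the column (plus the eps tie-break)
    f <- nid(s, vcol, lev)
    t2 <- ifelse(lev < K - 1, nid(s, vcol, lev + 1L), SNK)
    add(f, t2, cost[cbind(vcol, lev + 1L)] + eps * lev)
    # source -> base level, monotonicity reverse arcs
    add(rep(SRC, n), nid(s, seq_len(n), 0L), rep(.INFCAP, n))
    if (K > 1) {
      lv <- rep(0:(K - 2), each = n)
      vc <- rep(seq_len(n), times = K - 1)
      add(nid(s, vc, lv + 1L), nid(s, vc, lv), rep(.INFCAP, n * (K - 1)))
    }
    e <- graph@edges
    if (nrow(e)) {
      for (dirpair in list(e, e[, 2:1, drop = FALSE])) {
        u <- dirpair[, 1]; w <- dirpair[, 2]
        # smoothness penalty p: arc n(u,k) -> n(w,k), k >= 1
        if (params@p > 0) {
          for (k in 1:(K - 1))
            add(nid(s, u, k), nid(s, w, k), rep(params@p, length(u)))
        }
        # hard constraint: surface(u) >= k forces surface(w) >= k - delta
        if (delta < K - 1) {
          for (k in (delta + 1):(K - 1))
            add(nid(s, u, k), nid(s, w, k - delta), rep(.INFCAP, length(u)))
        }
      }
    }
  }
  # separation: k_out >= k_in + sMin (with sMin = 0 this still couples the
  # surfaces so that the outer never dips below the inner)
  if (sMin > 0)
    add(rep(SRC, n), nid(1L, seq_len(n), sMin), rep(.INFCAP, n))
  if (K - 1 - sMin >= 1)
    for (k in 1:(K - 1 - sMin))
      add(nid(0L, seq_len(n), k), nid(1L, seq_len(n), k + sMin),
          rep(.INFCAP, n))
  if (sMin > 0)
    for (k in (K - sMin):(K - 1))
      add(nid(0L, seq_len(n), k), rep(SNK, n), rep(.INFCAP, n))
  # one-sided separation penalty beyond sPref
  if (params@q > 0 && sPref + 1 <= K - 1) {
    for (k in (sPref + 1):(K - 1))
      add(nid(1L, seq_len(n), k), nid(0L, seq_len(n), k - sPref),
          rep(params@q, n))
  }
  from <- unlist(from); to <- unlist(to); cap <- unlist(cap)
  mf <- cpp_maxflow(as.integer(from), as.integer(to), as.numeric(cap),
                    SNK, SRC, SNK)
  srcSide <- mf$sourceSide
  # node ids lay out k fastest within a column, so a K x n reshape puts one
  # column chain per matrix column; the 1-based surface index is the number
  # of levels on the source side
  inSide <- matrix(srcSide[seq_len(n * K)], nrow = K, ncol = n)
  outSide <- matrix(srcSide[n * K + seq_len(n * K)], nrow = K, ncol = n)
  kIn <- colSums(inSide)          # 1-based sample index
  kOut <- colSums(outSide)
  kIn <- pmax(1L, as.integer(kIn))
  kOut <- pmax(1L, as.integer(kOut))
  energy <- surfaceEnergy(graph, kIn, kOut, params)
  new("SurfacePair", kIn = kIn, kOut = kOut, energy = energy, graph = graph)
}

#' Rasterise coupled surfaces to lumen and wall masks
#'
#' Moves every column base to its inner and outer surface positions, samples
#' the deformed meshes densely, and classifies voxels against the sampled
#' surfaces: the interior of the inner surface is lumen, the interior of the
#' outer surface minus the lumen is wall. A voxel claimed by both surfaces is
#' lumen. Voxels cut by a surface are assigned by the side of the local
#' surface plane their centre falls on.
#'
#' @param pair a \linkS4class{SurfacePair}.
#' @param faces the face matrix of the mesh the columns came from.
#' @param grid an \linkS4class{ImageVolume} supplying the output geometry
#'   (any volume on the target grid).
#' @return list with \code{lumen} and \code{wall} \linkS4class{BinaryMask}s.
#' @export
surfacesToMasks <- function(pair, faces, grid) {
  g <- pair@graph
  offs <- g@offsets
  innerV <- g@base + offs[pair@kIn] * g@dir
  outerV <- g@base + offs[pair@kOut] * g@dir
  d <- dim(grid@values)
  inside <- function(verts) {
    samp <- .sampleSurface(verts, faces, 0.35 * min(grid@spacing))
    vox <- worldToIndex(grid, samp$points)
    iv <- round(vox) + 1
    ok <- iv[, 1] >= 1 & iv[, 2] >= 1 & iv[, 3] >= 1 &
      iv[, 1] <= d[1] & iv[, 2] <= d[2] & iv[, 3] <= d[3]
    iv <- iv[ok, , drop = FALSE]
    pts <- samp$points[ok, , drop = FALSE]
    nrm <- samp$normals[ok, , drop = FALSE]
    lin <- iv[, 1] + d[1] * ((iv[, 2] - 1) + d[2] * (iv[, 3] - 1))
    centre <- indexToWorld(grid, iv - 1)
    rel <- centre - pts
    dot <- rowSums(rel * nrm)
    dist2 <- rowSums(rel^2)
    ord <- order(lin, dist2)
    first <- !duplicated(lin[ord])
    lin1 <- lin[ord][first]
    dot1 <- dot[ord][first]
    shell <- integer(prod(d))
    shell[lin1] <- 1L
    ext <- cpp_fill_from_border(shell, d)
    res <- ext == 0L                     # interior or shell
    res[lin1[dot1 >= 0]] <- FALSE        # shell voxels with centre outside
    array(res, dim = d)
  }
  insideInner <- inside(innerV)
  insideOuter <- inside(outerV) | insideInner
  list(lumen = maskLike(grid, insideInner),
       wall = maskLike(grid, insideOuter & !insideInner))
}

# Dense point sampling of a triangle mesh with a curved point-normal
# correction: flat triangles inscribe a curved surface and bias samples
# inward by the chord sagitta (~L^2/8r), so interior samples are displaced
# along the interpolated vertex normal by the quadratic bulge term
# sum_{i<j} b_i b_j (v_j - v_i).(n_j - n_i)/2, which restores the sagitta
# exactly on spheres and cylinders to second order.
.sampleSurface <- function(verts, faces, target) {
  vn <- .vertexNormals(verts, faces)
  a <- verts[faces[, 1], , drop = FALSE]
  b <- verts[faces[, 2], , drop = FALSE]
  c <- verts[faces[, 3], , drop = FALSE]
  na <- vn[faces[, 1], , drop = FALSE]
  nb <- vn[faces[, 2], , drop = FALSE]
  nc <- vn[faces[, 3], , drop = FALSE]
  wab <- rowSums((b - a) * (nb - na)) / 2
  wac <- rowSums((c - a) * (nc - na)) / 2
  wbc <- rowSums((c - b) * (nc - nb)) / 2
  maxEdge <- pmax(sqrt(rowSums((b - a)^2)), sqrt(rowSums((c - a)^2)),
                  sqrt(rowSums((c - b)^2)))
  nsub <- pmax(1L, as.integer(ceiling(maxEdge / target)))
  ptsL <- list(); nrmL <- list(); li <- 0
  for (ns in sort(unique(nsub))) {
    sel <- which(nsub == ns)
    bar <- NULL
    for (i in 0:ns) for (j in 0:(ns - i))
      bar <- rbind(bar, c(i, j, ns - i - j) / ns)
    for (bi in seq_len(nrow(bar))) {
      li <- li + 1
      b1 <- bar[bi, 1]; b2 <- bar[bi, 2]; b3 <- bar[bi, 3]
      flat <- b1 * a[sel, , drop = FALSE] + b2 * b[sel, , drop = FALSE] +
        b3 * c[sel, , drop = FALSE]
      nInt <- b1 * na[sel, , drop = FALSE] + b2 * nb[sel, , drop = FALSE] +
        b3 * nc[sel, , drop = FALSE]
      nInt <- nInt / pmax(sqrt(rowSums(nInt^2)), 1e-12)
      bulge <- b1 * b2 * wab[sel] + b1 * b3 * wac[sel] + b2 * b3 * wbc[sel]
      ptsL[[li]] <- flat + bulge * nInt
      nrmL[[li]] <- nInt
    }
  }
  list(points = do.call(rbind, ptsL), normals = do.call(rbind, nrmL))
}
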