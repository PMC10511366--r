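# Initial-surface extraction: a closed triangle mesh of the mask boundary
# (voxel-face mesh at the 0.5 level), Laplacian-smoothed, with outward
# normals and optional vertex-clustering decimation.

# triangle list for the boundary faces of a binary array, oriented outward
.boundaryFaceTriangles <- function(v, d) {
  shifted <- function(axis, by) {
    # neighbour value at +by along `axis`: out[i] = v[i + by], 0 past the edge
    out <- array(0, dim = d)
    n <- d[axis]
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    src <- ix; dst <- ix
    if (by > 0) { dst[[axis]] <- 1:(n - by); src[[axis]] <- (1 + by):n }
    else { dst[[axis]] <- (1 - by):n; src[[axis]] <- 1:(n + by) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
    out
  }
  cornerId <- function(u) u[, 1] + (d[1] + 1) * (u[, 2] + (d[2] + 1) * u[, 3])
  tris <- vector("list", 6)
  ti <- 0
  for (axis in 1:3) for (sgn in c(1, -1)) {
    nb <- shifted(axis, sgn)          # neighbour value in direction +sgn
    bnd <- which(v == 1 & nb == 0, arr.ind = TRUE)
    if (nrow(bnd) == 0) next
    # corner coords: voxel i (1-based) spans corners (i-1)..i per axis
    base <- bnd - 1L
    face <- base
    if (sgn > 0) face[, axis] <- face[, axis] + 1L
    oth <- setdiff(1:3, axis)
    mk <- function(da, db) {
      u <- face
      u[, oth[1]] <- u[, oth[1]] + da
      u[, oth[2]] <- u[, oth[2]] + db
      cornerId(u)
    }
    c00 <- mk(0L, 0L); c10 <- mk(1L, 0L); c11 <- mk(1L, 1L); c01 <- mk(0L, 1L)
    # outward orientation: counter-clockwise seen from outside
    if ((axis == 1 && sgn > 0) || (axis == 2 && sgn < 0) ||
        (axis == 3 && sgn > 0)) {
      t1 <- cbind(c00, c10, c11); t2 <- cbind(c00, c11, c01)
    } else {
      t1 <- cbind(c00, c11, c10); t2 <- cbind(c00, c01, c11)
    }
    ti <- ti + 1
    tris[[ti]] <- rbind(t1, t2)
  }
  do.call(rbind, tris[seq_len(ti)])
}

# vertex positions (mm) from corner ids
.cornerPos <- function(ids, d, spacing, origin) {
  ux <- ids %% (d[1] + 1)
  r <- ids %/% (d[1] + 1)
  uy <- r %% (d[2] + 1)
  uz <- r %/% (d[2] + 1)
  cbind((ux - 0.5) * spacing[1] + origin[1],
        (uy - 0.5) * spacing[2] + origin[2],
        (uz - 0.5) * spacing[3] + origin[3])
}

.faceNormals <- function(verts, faces) {
  a <- verts[faces[, 1], , drop = FALSE]
  b <- verts[faces[, 2], , drop = FALSE]
  c <- verts[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

# area-weighted outward vertex normals
.vertexNormals <- function(verts, faces) {
  fn <- .faceNormals(verts, faces)
  n <- matrix(0, nrow(verts), 3)
  for (j in 1:3) {
    agg <- rowsum(fn, faces[, j])
    idx <- as.integer(rownames(agg))
    n[idx, ] <- n[idx, ] + agg
  }
  len <- sqrt(rowSums(n^2))
  bad <- len < 1e-12
  n[bad, ] <- matrix(rep(c(0, 0, 1), sum(bad)), ncol = 3, byrow = TRUE)
  len[bad] <- 1
  n / len
}

.meshEdges <- function(faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# lambda-weighted Laplacian smoothing over the vertex adjacency
.laplacianSmooth <- function(verts, edges, iterations = 10, lambda = 0.5) {
  n <- nrow(verts)
  deg <- tabulate(c(edges[, 1], edges[, 2]), n)
  deg[deg == 0] <- 1
  for (it in seq_len(iterations)) {
    acc <- matrix(0, n, 3)
    a1 <- rowsum(verts[edges[, 2], , drop = FALSE], edges[, 1])
    acc[as.integer(rownames(a1)), ] <- acc[as.integer(rownames(a1)), ] + a1
    a2 <- rowsum(verts[edges[, 1], , drop = FALSE], edges[, 2])
    acc[as.integer(rownames(a2)), ] <- acc[as.integer(rownames(a2)), ] + a2
    verts <- verts + lambda * (acc / deg - verts)
  }
  verts
}

#' Extract the initial lumen surface from a mask
#'
#' Builds a closed triangulated isosurface of the mask boundary (the 0.5
#' level between foreground and background voxels), Laplacian-smooths it, and
#' orients normals outward. Optionally decimates by vertex clustering to a
#' target surface density.
#'
#' @param lumen a non-empty single-component \linkS4class{BinaryMask}.
#' @param smoothIterations Laplacian smoothing iterations (lambda 0.5).
#' @param targetDensity target vertices per mm^2 of surface; clustering is
#'   only applied when the raw voxel-face mesh exceeds ~1.3x this density.
#' @return A \linkS4class{SurfaceMesh}.
#' @export
extractInitialSurface <- function(lumen, smoothIterations = 10,
                                  targetDensity = 2) {
  v <- lumen@values
  if (sum(v) == 0) stop("empty mask")
  lab <- labelComponents(lumen)
  if (max(lab) > 1)
    stop("mask has ", max(lab), " components; take the largest first")
  d <- dim(v)
  tris <- .boundaryFaceTriangles(v, d)
  ids <- sort(unique(as.vector(tris)))
  faces <- matrix(match(as.vector(tris), ids), ncol = 3)
  verts <- .cornerPos(ids, d, lumen@spacing, lumen@origin)
  # surface area estimate from face normals for the density decision
  area <- sum(sqrt(rowSums(.faceNormals(verts, faces)^2))) / 2
  if (nrow(verts) / max(area, 1e-9) > 1.3 * targetDensity) {
    h <- 1 / sqrt(targetDensity)
    cell <- floor(sweep(verts, 2, apply(verts, 2, min), "-") / h)
    key <- paste(cell[, 1], cell[, 2], cell[, 3])
    grp <- match(key, unique(key))
    nv <- rowsum(verts, grp) / as.vector(table(grp)[as.character(
      sort(unique(grp)))])
    nf <- matrix(grp[as.vector(faces)], ncol = 3)
    ok <- nf[, 1] != nf[, 2] & nf[, 2] != nf[, 3] & nf[, 1] != nf[, 3]
    faces <- nf[ok, , drop = FALSE]
    faces <- unique(faces)
    verts <- nv
  }
  edges <- .meshEdges(faces)
  verts <- .laplacianSmooth(verts, edges, iterations = smoothIterations)
  normals <- .vertexNormals(verts, faces)
  new("SurfaceMesh", vertices = verts, normals = normals,
      faces = faces, edges = edges)
}
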