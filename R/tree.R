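# Airway tree decomposition: component cleanup, trachea seed detection,
# front-propagation branch extraction, Weibel generations, terminal pruning.

#' Build a CenterlineTree from branch records
#'
#' @param branches list of records with fields id, parent (NA for the root),
#'   generation, points (k x 3 matrix, mm).
#' @return A \linkS4class{CenterlineTree}.
#' @export
newCenterlineTree <- function(branches) {
  meta <- do.call(rbind, lapply(branches, function(b)
    data.frame(id = as.integer(b$id), parent = as.integer(b$parent),
               generation = as.integer(b$generation),
               length = polylineLength(b$points),
               npoints = nrow(b$points))))
  pts <- stats::setNames(lapply(branches, `[[`, "points"),
                         vapply(branches, function(b) as.character(b$id), ""))
  new("CenterlineTree", meta = meta, points = pts)
}

# ids of branches with no children
.leafIds <- function(tree) {
  m <- tree@meta
  setdiff(m$id, m$parent[!is.na(m$parent)])
}

#' Keep the largest connected component of a mask
#'
#' Retains the largest 26-connected component; among equally sized components
#' the one containing the smallest linear voxel index wins (component labels
#' are assigned in scan order, so the smallest label wins ties).
#'
#' @param mask a non-empty \linkS4class{BinaryMask}.
#' @return A \linkS4class{BinaryMask}.
#' @export
largestComponent <- function(mask) {
  if (sum(mask@values) == 0) stop("empty mask")
  lab <- labelComponents(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes == max(sizes))[1]
  maskLike(mask, lab == keep)
}

#' Find a trachea seed voxel
#'
#' The centroid of the largest in-mask region within the most cranial 5
#' percent of axial slices (largest z), snapped to the nearest in-mask voxel.
#' Falls back to the globally most cranial foreground voxel when the cranial
#' band holds none.
#'
#' @param mask a non-empty \linkS4class{BinaryMask}.
#' @return integer(3), 1-based voxel index of the seed.
#' @export
findTracheaSeed <- function(mask) {
  v <- mask@values
  if (sum(v) == 0) stop("empty mask")
  d <- dim(v)
  z0 <- max(1L, ceiling(d[3] * 0.95))
  band <- v
  band[, , seq_len(z0 - 1L)] <- 0
  if (sum(band) == 0) {
    idx <- which(v != 0, arr.ind = TRUE)
    return(as.integer(idx[which.max(idx[, 3]), ]))
  }
  lab <- labelComponents(maskLike(mask, band))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes == max(sizes))[1]
  idx <- which(lab == keep, arr.ind = TRUE)
  cen <- colMeans(idx)
  d2 <- colSums((t(idx) - cen)^2)
  as.integer(idx[which.min(d2), ])
}

#' Extract branches by front propagation
#'
#' Propagates a wavefront from the seed by geodesic (within-mask) distance,
#' 26-connected and weighted by the physical spacing. The distance field is
#' quantised into shells; within each shell, 26-connected components are
#' tracked from shell to shell. When a front splits into two or more
#' components that each persist for at least two consecutive shells, a branch
#' point is declared and child branches start. Each branch's centreline point
#' per shell is the component centroid snapped to the nearest in-mask voxel
#' of that component.
#'
#' @param mask a \linkS4class{BinaryMask} (single connected component; apply
#'   \code{\link{largestComponent}} first).
#' @param seed 1-based voxel index triple inside the mask, e.g. from
#'   \code{\link{findTracheaSeed}}.
#' @param shellWidth shell thickness in mm; defaults to the largest voxel
#'   spacing so that shells stay connected across anisotropic steps.
#' @return A \linkS4class{CenterlineTree} (generations via
#'   \code{\link{assignGenerations}} are already assigned).
#' @export
extractBranches <- function(mask, seed, shellWidth = NULL) {
  v <- mask@values
  d <- dim(v)
  seedLin <- (seed[1] - 1L) + d[1] * ((seed[2] - 1L) + d[2] * (seed[3] - 1L))
  if (v[seed[1], seed[2], seed[3]] == 0) stop("seed outside mask")
  if (is.null(shellWidth)) shellWidth <- max(mask@spacing)
  dist <- cpp_geodesic_dist(as.integer(v != 0), d, mask@spacing,
                            as.integer(seedLin))
  dist <- array(dist, dim = d)
  inMask <- dist >= 0
  shell <- array(-1L, dim = d)
  shell[inMask] <- as.integer(floor(dist[inMask] / shellWidth))
  shellIds <- sort(unique(shell[shell >= 0L]))

  # per-shell 26-connected components, as lists of linear voxel indices
  compsOf <- function(s) {
    m <- array(0L, dim = d)
    m[shell == s] <- 1L
    lab <- array(cpp_label_components(m, d, 26L), dim = d)
    n <- max(lab)
    lapply(seq_len(n), function(l) which(lab == l))
  }

  # does any voxel pair between two index sets touch (26-adjacency)?
  touches <- function(aIdx, bSet) {
    arr <- arrayInd(aIdx, d)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      ii <- arr[, 1] + dx; jj <- arr[, 2] + dy; kk <- arr[, 3] + dz
      ok <- ii >= 1 & jj >= 1 & kk >= 1 & ii <= d[1] & jj <= d[2] & kk <= d[3]
      if (!any(ok)) next
      lin <- ii[ok] + d[1] * ((jj[ok] - 1) + d[2] * (kk[ok] - 1))
      if (any(lin %in% bSet)) return(TRUE)
    }
    FALSE
  }

  centroidPoint <- function(idx) {
    arr <- arrayInd(idx, d)
    cen <- colMeans(arr)
    d2 <- colSums((t(arr) - cen)^2)
    best <- arr[which.min(d2), ]
    (best - 1) * mask@spacing + mask@origin
  }

  branches <- list()   # id -> list(id, parent, points (list), voxels (list))
  newBranch <- function(parent) {
    id <- length(branches) + 1L
    branches[[id]] <<- list(id = id, parent = parent, points = list(),
                            voxels = list())
    id
  }
  rootId <- newBranch(NA_integer_)
  # fronts: list of (branch id, voxel set of its component in previous shell)
  fronts <- list(list(branch = rootId, voxels = NULL))

  compsNext <- NULL
  for (si in seq_along(shellIds)) {
    s <- shellIds[si]
    comps <- if (is.null(compsNext)) compsOf(s) else compsNext
    compsNext <- if (si < length(shellIds)) compsOf(shellIds[si + 1]) else list()
    # assign each component to the front it touches (first shell: all to root)
    assign <- integer(length(comps))
    if (si == 1L) {
      assign[] <- 1L
    } else {
      for (ci in seq_along(comps)) {
        for (fi in seq_along(fronts)) {
          if (touches(comps[[ci]], fronts[[fi]]$voxels)) { assign[ci] <- fi; break }
        }
      }
    }
    newFronts <- list()
    for (fi in seq_along(fronts)) {
      mine <- which(assign == fi)
      if (length(mine) == 0) next              # front terminates
      br <- fronts[[fi]]$branch
      if (length(mine) >= 2 && si > 1L) {
        # candidate split: children must persist into the next shell
        persists <- vapply(mine, function(ci) {
          length(compsNext) > 0 &&
            any(vapply(compsNext, function(cn) touches(comps[[ci]], cn), TRUE))
        }, TRUE)
        if (sum(persists) >= 2) {
          # committed split: persisting components found child branches,
          # non-persisting ones are absorbed by the largest persisting child
          mainCi <- mine[persists][which.max(lengths(comps[mine[persists]]))]
          for (ci in mine) {
            if (persists[match(ci, mine)]) {
              cid <- newBranch(br)
              vox <- comps[[ci]]
              branches[[cid]]$points[[1]] <- centroidPoint(vox)
              branches[[cid]]$voxels <- list(vox)
              newFronts[[length(newFronts) + 1L]] <-
                list(branch = cid, voxels = vox)
            } else {
              # merge stray voxels into the nearest persisting child's branch
              branches[[br]]$voxels[[length(branches[[br]]$voxels) + 1L]] <-
                comps[[ci]]
            }
          }
          next
        }
      }
      # no committed split: branch continues through the union of components
      vox <- unlist(comps[mine], use.names = FALSE)
      branches[[br]]$points[[length(branches[[br]]$points) + 1L]] <-
        centroidPoint(vox)
      branches[[br]]$voxels[[length(branches[[br]]$voxels) + 1L]] <- vox
      newFronts[[length(newFronts) + 1L]] <- list(branch = br, voxels = vox)
    }
    fronts <- newFronts
    if (length(fronts) == 0) break
  }

  gen <- integer(length(branches))
  for (b in branches)          # ids are created parent-first
    gen[b$id] <- if (is.na(b$parent)) 0L else gen[b$parent] + 1L
  recs <- lapply(branches, function(b) {
    pts <- do.call(rbind, b$points)
    if (is.null(pts)) pts <- matrix(numeric(0), ncol = 3)
    list(id = b$id, parent = b$parent, generation = gen[b$id], points = pts,
         voxels = unlist(b$voxels, use.names = FALSE))
  })
  # drop branches that never accumulated a point (guard; should not happen)
  keep <- vapply(recs, function(r) nrow(r$points) > 0, TRUE)
  recs <- recs[keep]
  tree <- newCenterlineTree(recs)
  tree@points <- stats::setNames(lapply(recs, `[[`, "points"),
                                 vapply(recs, function(r) as.character(r$id), ""))
  attr(tree@points, "voxels") <- stats::setNames(
    lapply(recs, `[[`, "voxels"),
    vapply(recs, function(r) as.character(r$id), ""))
  assignGenerations(tree)
}

#' Assign Weibel generations
#'
#' Root (trachea) gets generation 0; every child gets its parent's generation
#' plus one, so a trifurcation's children all share the same generation.
#'
#' @param tree a \linkS4class{CenterlineTree}.
#' @return The tree with generations filled in.
#' @export
assignGenerations <- function(tree) {
  m <- tree@meta
  m$generation <- NA_integer_
  root <- m$id[is.na(m$parent)]
  m$generation[m$id == root] <- 0L
  repeat {
    todo <- which(is.na(m$generation))
    if (!length(todo)) break
    done <- FALSE
    for (i in todo) {
      pg <- m$generation[m$id == m$parent[i]]
      if (!is.na(pg)) { m$generation[i] <- pg + 1L; done <- TRUE }
    }
    if (!done) stop("disconnected branch records")
  }
  tree@meta <- m
  tree
}

#' Prune short terminal branches
#'
#' Removes, in a single pass, every leaf branch strictly shorter than
#' \code{minLength} mm. Parents of removed leaves are never merged with a
#' surviving sibling and the root is never removed, so Weibel generation
#' indices of surviving branches are unchanged. The single pass makes pruning
#' idempotent.
#'
#' @param tree a \linkS4class{CenterlineTree}.
#' @param minLength length threshold in mm (default 2.0; a 2.0 mm leaf is
#'   kept, anything shorter is discarded).
#' @return The pruned \linkS4class{CenterlineTree}.
#' @export
pruneShortTerminal <- function(tree, minLength = 2.0) {
  m <- tree@meta
  leaves <- .leafIds(tree)
  drop <- m$id[m$id %in% leaves & m$length < minLength & !is.na(m$parent)]
  if (!length(drop)) return(tree)
  keep <- !(m$id %in% drop)
  tree@meta <- m[keep, , drop = FALSE]
  tree@points <- tree@points[as.character(m$id[keep])]
  tree
}
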