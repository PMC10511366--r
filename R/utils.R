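#' Construct an image volume
#'
#' @param values 3D numeric array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) physical position of voxel (0,0,0) in mm.
#' @return An \linkS4class{ImageVolume}.
#' @export
imageVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), axisOrder = "xyz")
}

#' Construct a binary mask
#'
#' @param values 3D array coercible to 0/1.
#' @inheritParams imageVolume
#' @return A \linkS4class{BinaryMask}.
#' @export
binaryMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- array(as.numeric(values != 0), dim = dim(values))
  new("BinaryMask", values = v, spacing = as.numeric(spacing),
      origin = as.numeric(origin), axisOrder = "xyz")
}

# mask sharing geometry with a reference volume
maskLike <- function(vol, values) {
  binaryMask(values, spacing = vol@spacing, origin = vol@origin)
}

# physical mm coordinates of 0-based voxel indices (n x 3)
indexToWorld <- function(vol, idx) {
  sweep(sweep(idx, 2, vol@spacing, "*"), 2, vol@origin, "+")
}

# continuous 0-based voxel coordinates of world positions (n x 3)
worldToIndex <- function(vol, pts) {
  sweep(sweep(pts, 2, vol@origin, "-"), 2, vol@spacing, "/")
}

# voxel centre coordinate vectors along each axis (mm)
gridAxes <- function(vol) {
  d <- dim(vol@values)
  lapply(1:3, function(a) (seq_len(d[a]) - 1) * vol@spacing[a] + vol@origin[a])
}

#' Trilinear interpolation of a volume at physical points
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param pts n x 3 matrix of world positions (mm).
#' @return numeric(n); NA for points outside the grid.
#' @export
interpolateAt <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  cpp_trilinear(as.numeric(vol@values), dim(vol@values),
                worldToIndex(vol, pts))
}

# run code with a temporary RNG state seeded by `seed`
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# 6-connected binary erosion by one voxel
erodeMask <- function(mask, iterations = 1L) {
  v <- mask@values
  d <- dim(v)
  for (it in seq_len(iterations)) {
    out <- v
    sh <- function(arr, axis, by) {
      res <- array(0, dim = d)
      n <- d[axis]
      src <- seq_len(n - abs(by))
      if (by > 0) dst <- src + by else dst <- src
      if (by > 0) srcI <- src else srcI <- src + abs(by)
      ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      ixd <- ix; ixd[[axis]] <- dst
      ixs <- ix; ixs[[axis]] <- srcI
      res[ixd[[1]], ixd[[2]], ixd[[3]]] <- arr[ixs[[1]], ixs[[2]], ixs[[3]]]
      res
    }
    for (axis in 1:3) {
      out <- out * sh(v, axis, 1) * sh(v, axis, -1)
    }
    v <- out
  }
  maskLike(mask, v)
}

# connected-component labels of a mask (26-connected by default)
labelComponents <- function(mask, connectivity = 26L) {
  lab <- cpp_label_components(as.integer(mask@values != 0), dim(mask@values),
                              as.integer(connectivity))
  array(lab, dim = dim(mask@values))
}

# Gaussian kernel with given sigma in voxel units, radius 3 sigma, normalised
gaussKernel1d <- function(sigmaVox) {
  r <- max(1L, ceiling(3 * sigmaVox))
  k <- stats::dnorm(seq(-r, r), sd = sigmaVox)
  k / sum(k)
}

# orthonormal in-plane basis perpendicular to a tangent vector
planeBasis <- function(tangent) {
  t <- tangent / sqrt(sum(tangent^2))
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(t[2] * ref[3] - t[3] * ref[2],
         t[3] * ref[1] - t[1] * ref[3],
         t[1] * ref[2] - t[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(t[2] * u[3] - t[3] * u[2],
         t[3] * u[1] - t[1] * u[3],
         t[1] * u[2] - t[2] * u[1])
  list(u = u, v = v, t = t)
}

# polyline length (sum of inter-point distances)
polylineLength <- function(pts) {
  if (is.null(pts) || nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}
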