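# Shared fixtures: digital solids, tiny column graphs, and an independent
# exhaustive-enumeration oracle for the coupled-surface energy.

# solid sphere mask of radius r voxels centred in a cubic grid
digitalSphere <- function(r = 10, pad = 5, spacing = c(1, 1, 1)) {
  n <- 2 * (r + pad) + 1
  cen <- r + pad
  arr <- array(0, c(n, n, n))
  for (k in seq_len(n)) for (j in seq_len(n)) {
    i <- seq_len(n)
    arr[, j, k] <- as.numeric((i - 1 - cen)^2 + (j - 1 - cen)^2 +
                                (k - 1 - cen)^2 <= r^2)
  }
  list(mask = binaryMask(arr, spacing), centre = cen * spacing)
}

# solid z-aligned cylinder mask; reaches the top slice so the trachea-seed
# heuristic finds its cranial end
digitalCylinder <- function(radius = 3, nz = 58, spacing = c(0.6, 0.6, 0.7),
                            fromSlice = 2) {
  nxy <- 2 * ceiling(radius / spacing[1]) + 9
  cx <- (nxy - 1) / 2
  arr <- array(0, c(nxy, nxy, nz))
  for (k in fromSlice:nz) for (j in seq_len(nxy)) {
    i <- seq_len(nxy)
    arr[i, j, k] <- as.numeric(((i - 1 - cx) * spacing[1])^2 +
                                 ((j - 1 - cx) * spacing[2])^2 <= radius^2)
  }
  binaryMask(arr, spacing)
}

# random small column graph for oracle comparisons
randomColumnGraph <- function(n, K, seed) {
  set.seed(seed)
  cIn <- matrix(as.numeric(sample(0:20, n * K, TRUE)), n, K)
  cOut <- matrix(as.numeric(sample(0:20, n * K, TRUE)), n, K)
  edges <- if (n >= 2) {
    e <- t(utils::combn(n, 2))
    e[sample(nrow(e), min(nrow(e), n)), , drop = FALSE]
  } else matrix(integer(0), ncol = 2)
  new("ColumnGraph", base = matrix(0, n, 3),
      dir = matrix(rep(c(0, 0, 1), each = n), n, 3),
      offsets = seq(0, by = 0.3, length.out = K), intensity = cIn,
      costIn = cIn, costOut = cOut, edges = edges, step = 0.3)
}

# independent oracle: enumerate all feasible per-column (kIn, kOut) states
# jointly across columns and take the minimum energy
enumerateSurfaceEnergy <- function(graph, params) {
  n <- nrow(graph@costIn)
  K <- ncol(graph@costIn)
  st <- expand.grid(kIn = seq_len(K), kOut = seq_len(K))
  st <- st[st$kOut - st$kIn >= params@sMin, ]
  S <- nrow(st)
  dc <- sapply(seq_len(n), function(v)
    graph@costIn[v, st$kIn] + graph@costOut[v, st$kOut] +
      params@q * pmax(0, (st$kOut - st$kIn) - params@sPref))
  dIn <- abs(outer(st$kIn, st$kIn, "-"))
  dOut <- abs(outer(st$kOut, st$kOut, "-"))
  pc <- params@p * (dIn + dOut)
  pc[dIn > params@delta | dOut > params@delta] <- Inf
  combos <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  tot <- numeric(nrow(combos))
  for (v in seq_len(n)) tot <- tot + dc[combos[, v], v]
  e <- graph@edges
  if (nrow(e)) for (r in seq_len(nrow(e)))
    tot <- tot + pc[cbind(combos[, e[r, 1]], combos[, e[r, 2]])]
  min(tot)
}

# quick single-tube phantom for segmentation tests
singleTubePhantom <- function(lumen = 4, wall = 1, length = 18) {
  sp <- c(0.6, 0.6, 0.7)
  ext <- c(16, 16, length + 8)
  dims <- as.integer(ceiling(ext / sp))
  tube <- tubeSpec(lumen, wall, length, center = (dims - 1) * sp / 2)
  phantomSpec(list(tube), dims, sp)
}
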