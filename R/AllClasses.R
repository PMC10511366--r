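#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib AirwayMeasure, .registration = TRUE
NULL

#' 3D scalar image volume
#'
#' Container for a 3D CT-like scalar grid with physical geometry. Attenuation
#' is stored in Hounsfield units (HU). Voxel \code{(i, j, k)} (0-based) sits at
#' physical position \code{index * spacing + origin} (mm); the third axis is
#' cranio-caudal with increasing z pointing cranially.
#'
#' @slot values 3D numeric array of voxel values (HU for scans).
#' @slot spacing numeric(3), voxel edge length in mm along each axis; all > 0.
#' @slot origin numeric(3), physical position (mm) of voxel (0,0,0).
#' @slot axisOrder single string tagging the axis convention; always "xyz".
#'
#' @aliases ImageVolume-class
#' @export
setClass("ImageVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 axisOrder = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), axisOrder = "xyz"))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (!identical(object@axisOrder, "xyz"))
    msg <- c(msg, "axisOrder must be 'xyz'")
  if (length(msg)) msg else TRUE
})

#' Binary voxel mask
#'
#' An \linkS4class{ImageVolume} whose values are restricted to \{0, 1\}.
#' Used for airway lumen and wall segmentations; shares grid geometry with the
#' scan it annotates.
#'
#' @aliases BinaryMask-class
#' @export
setClass("BinaryMask", contains = "ImageVolume")

setValidity("BinaryMask", function(object) {
  v <- object@values
  if (!all(v == 0 | v == 1)) "mask values must be 0 or 1" else TRUE
})

#' Triangulated surface mesh
#'
#' Closed triangle mesh of an initial (lumen) surface: vertex positions in mm,
#' outward unit normals, faces as 1-based vertex index triples, and the
#' symmetric vertex adjacency as an edge list.
#'
#' @slot vertices n x 3 numeric matrix (mm).
#' @slot normals n x 3 numeric matrix of outward unit normals.
#' @slot faces m x 3 integer matrix of vertex indices.
#' @slot edges e x 2 integer matrix of unique undirected vertex pairs.
#'
#' @aliases SurfaceMesh-class
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", normals = "matrix", faces = "matrix",
                 edges = "matrix"))

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (!identical(dim(object@normals), dim(object@vertices)))
    msg <- c(msg, "normals must match vertices in shape")
  nrm <- sqrt(rowSums(object@normals^2))
  if (length(nrm) && any(abs(nrm - 1) > 1e-6))
    msg <- c(msg, "normals must be unit length")
  if (length(object@faces) && max(object@faces) > nrow(object@vertices))
    msg <- c(msg, "face indices out of range")
  if (length(msg)) msg else TRUE
})

#' Coupled-surface graph-cut parameters
#'
#' Parameters of the two-surface optimal-surface graph cut. Sample positions
#' along each column run from \code{-lIn} to \code{+lOut} mm around the column
#' base in steps of \code{step} mm (K samples). Index units below are samples.
#'
#' @slot wIn inner-surface first-derivative weight (rewards dark-to-bright).
#' @slot wOut outer-surface first-derivative weight (rewards bright-to-dark).
#' @slot w2In optional inner second-derivative weight (default 0).
#' @slot w2Out optional outer second-derivative weight (default 0).
#' @slot delta hard smoothness constraint: max index difference between
#'   neighbouring columns, per surface.
#' @slot p smoothness penalty per unit index difference between neighbours.
#' @slot q separation penalty per sample of wall thickness beyond \code{sPref}.
#' @slot sMin minimum inner/outer index separation (samples).
#' @slot sPref preferred separation (samples); thickness above it costs q/sample.
#' @slot lIn column length inward of the base (mm).
#' @slot lOut column length outward of the base (mm).
#' @slot step sample step along the column (mm).
#'
#' @aliases GraphCutParams-class
#' @export
setClass("GraphCutParams",
  representation(wIn = "numeric", wOut = "numeric", w2In = "numeric",
                 w2Out = "numeric", delta = "numeric", p = "numeric",
                 q = "numeric", sMin = "numeric", sPref = "numeric",
                 lIn = "numeric", lOut = "numeric", step = "numeric"),
  prototype(wIn = 1, wOut = 1, w2In = 0, w2Out = 0, delta = 2, p = 0.5,
            q = 0.5, sMin = 1, sPref = 4, lIn = 3, lOut = 5, step = 0.3))

setValidity("GraphCutParams", function(object) {
  msg <- character()
  if (object@delta < 0) msg <- c(msg, "delta must be >= 0")
  if (object@p < 0 || object@q < 0) msg <- c(msg, "p and q must be >= 0")
  if (object@step <= 0) msg <- c(msg, "step must be > 0")
  if (object@sMin < 0 || object@sMin > object@sPref)
    msg <- c(msg, "need 0 <= sMin <= sPref")
  if (object@lIn < 0 || object@lOut <= 0) msg <- c(msg, "bad column lengths")
  if (length(msg)) msg else TRUE
})

#' Column graph for coupled-surface segmentation
#'
#' One sampling column per mesh vertex: base point, outward direction, K
#' sample offsets, interpolated intensities, and the per-sample inner/outer
#' surface costs. Neighbour pairs come from the mesh edges.
#'
#' @slot base n x 3 matrix of column base points (mm).
#' @slot dir n x 3 matrix of unit outward directions.
#' @slot offsets numeric(K) of signed offsets (mm) along the direction.
#' @slot intensity n x K matrix of interpolated HU (NA outside the volume).
#' @slot costIn,costOut n x K matrices of finite surface costs.
#' @slot edges e x 2 integer matrix of neighbouring column pairs.
#' @slot step sample step (mm).
#'
#' @aliases ColumnGraph-class
#' @export
setClass("ColumnGraph",
  representation(base = "matrix", dir = "matrix", offsets = "numeric",
                 intensity = "matrix", costIn = "matrix", costOut = "matrix",
                 edges = "matrix", step = "numeric"))

setValidity("ColumnGraph", function(object) {
  msg <- character()
  K <- length(object@offsets)
  if (K < 2) msg <- c(msg, "need at least 2 samples per column")
  if (ncol(object@costIn) != K || ncol(object@costOut) != K)
    msg <- c(msg, "cost matrices must have K columns")
  if (any(!is.finite(object@costIn)) || any(!is.finite(object@costOut)))
    msg <- c(msg, "costs must be finite")
  if (length(msg)) msg else TRUE
})

#' Coupled surface solution
#'
#' Per-column inner (lumen) and outer (wall) surface sample indices returned
#' by the graph-cut solver, with the realised energy.
#'
#' @slot kIn,kOut integer vectors of 1-based sample indices per column.
#' @slot energy the minimised energy.
#' @slot graph the \linkS4class{ColumnGraph} the solution refers to.
#'
#' @aliases SurfacePair-class
#' @export
setClass("SurfacePair",
  representation(kIn = "integer", kOut = "integer", energy = "numeric",
                 graph = "ColumnGraph"))

setValidity("SurfacePair", function(object) {
  if (length(object@kIn) != length(object@kOut))
    "kIn and kOut must have equal length" else TRUE
})

#' Airway centreline tree
#'
#' Branches of an airway tree: per-branch metadata plus ordered centreline
#' points. Weibel convention: trachea is generation 0 and every branching
#' point increments the generation.
#'
#' @slot meta data.frame with columns id, parent (NA for the root),
#'   generation, length (mm), npoints.
#' @slot points named list (by id) of k x 3 matrices of centreline points (mm),
#'   ordered from the proximal end.
#'
#' @aliases CenterlineTree-class
#' @export
setClass("CenterlineTree",
  representation(meta = "data.frame", points = "list"))

setValidity("CenterlineTree", function(object) {
  m <- object@meta
  msg <- character()
  need <- c("id", "parent", "generation", "length")
  if (!all(need %in% names(m)))
    return("meta must have columns id, parent, generation, length")
  if (nrow(m)) {
    roots <- which(is.na(m$parent))
    if (length(roots) != 1L) msg <- c(msg, "tree must have exactly one root")
    known <- m$parent %in% m$id | is.na(m$parent)
    if (!all(known)) msg <- c(msg, "every non-root parent must exist")
    if (any(m$length < 0)) msg <- c(msg, "branch lengths must be >= 0")
    nonroot <- !is.na(m$parent)
    if (any(nonroot)) {
      pg <- m$generation[match(m$parent[nonroot], m$id)]
      if (any(m$generation[nonroot] != pg + 1L))
        msg <- c(msg, "generation(child) must equal generation(parent) + 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Tube specification for the synthetic phantom
#'
#' @slot lumenDiameter lumen (inner) diameter, mm.
#' @slot wallThickness wall thickness, mm.
#' @slot length tube length, mm.
#' @slot axis unit 3-vector, tube axis direction.
#' @slot center 3-vector, tube centre (mm).
#'
#' @aliases TubeSpec-class
#' @export
setClass("TubeSpec",
  representation(lumenDiameter = "numeric", wallThickness = "numeric",
                 length = "numeric", axis = "numeric", center = "numeric"))

setValidity("TubeSpec", function(object) {
  msg <- character()
  if (object@lumenDiameter <= 0) msg <- c(msg, "lumenDiameter must be > 0")
  if (object@wallThickness <= 0) msg <- c(msg, "wallThickness must be > 0")
  if (object@length <= 0) msg <- c(msg, "length must be > 0")
  if (length(object@axis) != 3 || sum(object@axis^2) == 0)
    msg <- c(msg, "axis must be a nonzero 3-vector")
  if (length(msg)) msg else TRUE
})

#' Phantom specification
#'
#' A set of airway-mimicking tubes embedded in foam, on a regular grid.
#' Default HU levels: air lumen -1000, foam background -850, tube wall -50,
#' matching air/parenchyma/soft-tissue contrast on inspiratory low-dose CT.
#'
#' @slot tubes list of \linkS4class{TubeSpec}.
#' @slot dim integer(3) grid shape.
#' @slot spacing numeric(3) voxel spacing (mm).
#' @slot huLumen,huWall,huBackground HU plateaus.
#'
#' @aliases PhantomSpec-class
#' @export
setClass("PhantomSpec",
  representation(tubes = "list", dim = "integer", spacing = "numeric",
                 huLumen = "numeric", huWall = "numeric",
                 huBackground = "numeric"),
  prototype(huLumen = -1000, huWall = -50, huBackground = -850))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@dim) != 3 || any(object@dim < 2))
    msg <- c(msg, "dim must be 3 integers >= 2")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers")
  if (!all(vapply(object@tubes, is, TRUE, "TubeSpec")))
    msg <- c(msg, "tubes must be TubeSpec objects")
  if (length(msg)) msg else TRUE
})

#' Bifurcating airway-tree specification
#'
#' Recursive symmetric bifurcation in the Weibel spirit: each child's lumen
#' diameter is the parent's times \code{diameterRatio}, its length is
#' \code{lengthDiameterRatio} times its own diameter, and the two children
#' leave the parent direction at \code{halfAngle} degrees in a branching plane
#' that rotates 90 degrees per generation. Wall thickness is
#' \code{wallFraction} times the local lumen radius.
#'
#' @slot rootDiameter root (trachea surrogate) lumen diameter, mm.
#' @slot wallFraction wall thickness as a fraction of lumen radius.
#' @slot diameterRatio child/parent lumen diameter ratio, in (0, 1].
#' @slot lengthDiameterRatio branch length / branch lumen diameter.
#' @slot halfAngle branching half-angle, degrees.
#' @slot maxGeneration deepest generation to grow (root = 0).
#' @slot minDiameter stop growing below this lumen diameter, mm.
#' @slot angleJitter,lengthJitter relative jitter magnitudes (0 = none).
#' @slot dim integer(3) grid shape.
#' @slot spacing numeric(3) voxel spacing, mm.
#' @slot huLumen,huWall,huBackground HU plateaus.
#'
#' @aliases TreeSpec-class
#' @export
setClass("TreeSpec",
  representation(rootDiameter = "numeric", wallFraction = "numeric",
                 diameterRatio = "numeric", lengthDiameterRatio = "numeric",
                 halfAngle = "numeric", maxGeneration = "integer",
                 minDiameter = "numeric", angleJitter = "numeric",
                 lengthJitter = "numeric", dim = "integer",
                 spacing = "numeric", huLumen = "numeric", huWall = "numeric",
                 huBackground = "numeric"),
  prototype(rootDiameter = 6, wallFraction = 0.4, diameterRatio = 0.78,
            lengthDiameterRatio = 3, halfAngle = 35, maxGeneration = 2L,
            minDiameter = 1, angleJitter = 0, lengthJitter = 0,
            huLumen = -1000, huWall = -50, huBackground = -850))

setValidity("TreeSpec", function(object) {
  msg <- character()
  if (object@diameterRatio <= 0 || object@diameterRatio > 1)
    msg <- c(msg, "diameterRatio must be in (0, 1]")
  if (object@maxGeneration < 0) msg <- c(msg, "maxGeneration must be >= 0")
  if (object@minDiameter <= 0) msg <- c(msg, "minDiameter must be > 0")
  if (length(object@dim) != 3 || any(object@dim < 2))
    msg <- c(msg, "dim must be 3 integers >= 2")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be positive")
  if (length(msg)) msg else TRUE
})

#' Low-dose scanner model
#'
#' Isotropic Gaussian point-spread blur followed by additive Gaussian noise,
#' a surrogate for a low-dose helical protocol of the "120 kVp, 20 mAs,
#' pitch 3.0" class.
#'
#' @slot fwhm PSF full width at half maximum, mm (>= 0; 0 disables blur).
#' @slot noiseSD additive noise standard deviation, HU (>= 0).
#' @slot noiseType noise family tag; only "gaussian".
#'
#' @aliases ScannerModel-class
#' @export
setClass("ScannerModel",
  representation(fwhm = "numeric", noiseSD = "numeric", noiseType = "character"),
  prototype(fwhm = 0.8, noiseSD = 25, noiseType = "gaussian"))

setValidity("ScannerModel", function(object) {
  msg <- character()
  if (object@fwhm < 0) msg <- c(msg, "fwhm must be >= 0")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (!identical(object@noiseType, "gaussian"))
    msg <- c(msg, "only gaussian noise is supported")
  if (length(msg)) msg else TRUE
})

#' Exact ground truth for a synthetic volume
#'
#' @slot lumenMask,wallMask disjoint \linkS4class{BinaryMask} objects.
#' @slot trees list of \linkS4class{CenterlineTree} (one per tube, or a single
#'   tree for an airway-tree volume).
#' @slot branches data.frame of true per-branch geometry: tree, id, generation,
#'   lumenDiameter (mm), totalDiameter (mm), length (mm).
#'
#' @aliases GroundTruth-class
#' @export
setClass("GroundTruth",
  representation(lumenMask = "BinaryMask", wallMask = "BinaryMask",
                 trees = "list", branches = "data.frame"))

setValidity("GroundTruth", function(object) {
  if (any(object@lumenMask@values * object@wallMask@values != 0))
    "lumen and wall masks must be disjoint" else TRUE
})

#' Per-scan bronchial parameter summary
#'
#' @slot genLA named numeric: mean luminal area (mm^2) per generation
#'   (names "0", "1", ...).
#' @slot genWAP named numeric: mean wall area percentage per generation.
#' @slot pi10 Pi10 (mm), NA when undefined.
#' @slot tac total airway count (measured branches).
#' @slot tlv total lung volume (litres), supplied externally.
#' @slot maxGeneration deepest measured generation.
#'
#' @aliases ScanSummary-class
#' @export
setClass("ScanSummary",
  representation(genLA = "numeric", genWAP = "numeric", pi10 = "numeric",
                 tac = "numeric", tlv = "numeric", maxGeneration = "numeric"))

setValidity("ScanSummary", function(object) {
  if (object@tac < 1) "TAC must be >= 1" else TRUE
})

#' Paired repeat-scan cohort
#'
#' @slot participants list; each element has fields id, scan1, scan2
#'   (\linkS4class{ScanSummary}) and daysBetween.
#'
#' @aliases PairedCohort-class
#' @export
setClass("PairedCohort", representation(participants = "list"))

setValidity("PairedCohort", function(object) {
  ok <- vapply(object@participants, function(p)
    is(p$scan1, "ScanSummary") && is(p$scan2, "ScanSummary") &&
      p$scan1@tlv > 0 && p$scan2@tlv > 0, TRUE)
  if (!all(ok)) "each participant needs two summaries with TLV > 0" else TRUE
})

#' Tuning parameter space
#'
#' Continuous search box per tuned graph-cut parameter plus fixed values for
#' the geometry parameters. Integer-valued parameters (delta, sPref) are
#' relaxed to continuous and rounded at evaluation.
#'
#' @slot bounds data.frame with columns name, lower, upper, log (logical),
#'   integer (logical).
#' @slot fixed named list of fixed parameter values (step, lIn, lOut, sMin, ...).
#'
#' @aliases ParamSpace-class
#' @export
setClass("ParamSpace",
  representation(bounds = "data.frame", fixed = "list"))

setValidity("ParamSpace", function(object) {
  b <- object@bounds
  need <- c("name", "lower", "upper", "log", "integer")
  if (!all(need %in% names(b)))
    return("bounds needs columns name, lower, upper, log, integer")
  if (any(b$lower >= b$upper)) return("each lower bound must be < upper")
  TRUE
})

#' Result of a tuning run
#'
#' @slot best named numeric vector of the best parameter values found.
#' @slot bestValue the best (minimum) objective value.
#' @slot history data.frame of all trials: trial index, one column per
#'   parameter, and the objective value.
#' @slot seed the RNG seed used.
#'
#' @aliases TuningResult-class
#' @export
setClass("TuningResult",
  representation(best = "numeric", bestValue = "numeric",
                 history = "data.frame", seed = "numeric"))

setValidity("TuningResult", function(object) {
  if (nrow(object@history) &&
      abs(min(object@history$value) - object@bestValue) > 1e-12)
    "bestValue must equal the minimum over the history" else TRUE
})
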