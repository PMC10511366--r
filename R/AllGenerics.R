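#' Accessors for image volumes and trees
#'
#' \code{voxelData} returns the raw 3D array; \code{voxelSpacing} and
#' \code{voxelOrigin} the grid geometry in mm; \code{nBranches},
#' \code{branchMeta} and \code{branchPoints} expose a
#' \linkS4class{CenterlineTree}.
#'
#' @param x an \linkS4class{ImageVolume} or \linkS4class{CenterlineTree}.
#' @param id a branch id.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setGeneric("nBranches", function(x) standardGeneric("nBranches"))
#' @rdname accessors
#' @export
setGeneric("branchMeta", function(x) standardGeneric("branchMeta"))
#' @rdname accessors
#' @export
setGeneric("branchPoints", function(x, id) standardGeneric("branchPoints"))

#' @rdname accessors
setMethod("voxelData", "ImageVolume", function(x) x@values)
#' @rdname accessors
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelOrigin", "ImageVolume", function(x) x@origin)
#' @rdname accessors
setMethod("nBranches", "CenterlineTree", function(x) nrow(x@meta))
#' @rdname accessors
setMethod("branchMeta", "CenterlineTree", function(x) x@meta)
#' @rdname accessors
setMethod("branchPoints", "CenterlineTree",
          function(x, id) x@points[[as.character(id)]])

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(class(object), sprintf("%d x %d x %d voxels", d[1], d[2], d[3]),
      sprintf("| spacing %.3g x %.3g x %.3g mm", object@spacing[1],
              object@spacing[2], object@spacing[3]), "\n")
  if (is(object, "BinaryMask"))
    cat("  foreground voxels:", sum(object@values), "\n")
  else
    cat(sprintf("  value range [%.4g, %.4g]\n", min(object@values),
                max(object@values)))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat("SurfaceMesh:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "faces\n")
})

setMethod("show", "CenterlineTree", function(object) {
  m <- object@meta
  cat("CenterlineTree:", nrow(m), "branches, max generation",
      if (nrow(m)) max(m$generation) else NA, "\n")
  if (nrow(m)) {
    tab <- table(m$generation)
    cat("  branches per generation:",
        paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
    cat(sprintf("  total centreline length %.1f mm\n", sum(m$length)))
  }
})

setMethod("show", "SurfacePair", function(object) {
  cat("SurfacePair:", length(object@kIn), "columns, energy",
      format(object@energy), "\n")
})

setMethod("show", "ScanSummary", function(object) {
  cat("ScanSummary: TAC", object@tac, "| max generation",
      object@maxGeneration, "| TLV", object@tlv, "L\n")
  cat("  Pi10:", if (is.na(object@pi10)) "undefined" else
    sprintf("%.3f mm", object@pi10), "\n")
  gens <- names(object@genLA)
  cat("  mean LA (mm^2):",
      paste(sprintf("g%s=%.2f", gens, object@genLA), collapse = " "), "\n")
})

setMethod("show", "TuningResult", function(object) {
  cat("TuningResult:", nrow(object@history), "trials, best objective",
      format(object@bestValue, digits = 4), "\n")
  cat("  best:", paste(sprintf("%s=%.4g", names(object@best), object@best),
                       collapse = " "), "\n")
})

setMethod("show", "GraphCutParams", function(object) {
  cat(sprintf(paste0("GraphCutParams: wIn=%.3g wOut=%.3g delta=%g p=%.3g ",
                     "q=%.3g sMin=%g sPref=%g | step=%g mm, L=[-%g, +%g] mm\n"),
              object@wIn, object@wOut, object@delta, object@p, object@q,
              object@sMin, object@sPref, object@step, object@lIn, object@lOut))
})
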