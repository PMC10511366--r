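# Result export: delimited branch table plus structured scan summary.

#' Export branch measurements and a scan summary
#'
#' Writes \code{branches.csv} (one row per measured branch, with a leading
#' comment line documenting the column units) and \code{summary.json}
#' (per-generation means, Pi10, TAC, TLV, max generation).
#'
#' @param measurements non-empty data.frame of branch measurements
#'   (\code{\link{measureTree}}), with parent ids if available.
#' @param summary a \linkS4class{ScanSummary}.
#' @param outDir output directory (created if missing).
#' @param tree optional \linkS4class{CenterlineTree} supplying parent ids.
#' @return Named character vector of the written paths, invisibly.
#' @export
exportResults <- function(measurements, summary, outDir, tree = NULL) {
  if (is.null(measurements) || nrow(measurements) == 0)
    stop("empty measurement list")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tab <- measurements
  tab$parent <- if (!is.null(tree))
    branchMeta(tree)$parent[match(tab$id, branchMeta(tree)$id)] else NA
  cols <- c("id", "parent", "generation", "length", "meanRIn", "meanROut",
            "LA", "WA", "WAP", "SRWA", "Pi", "nSections")
  tab <- tab[, cols]
  csvPath <- file.path(outDir, "branches.csv")
  units <- paste("# units: length/meanRIn/meanROut/SRWA/Pi mm;",
                 "LA/WA mm^2; WAP percent")
  con <- file(csvPath, "w")
  writeLines(units, con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  jsonPath <- file.path(outDir, "summary.json")
  jsonlite::write_json(list(
    genLA = as.list(summary@genLA), genWAP = as.list(summary@genWAP),
    pi10 = summary@pi10, tac = summary@tac, tlv = summary@tlv,
    maxGeneration = summary@maxGeneration),
    jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(branches = csvPath, summary = jsonPath))
}

#' Read back an exported branch table
#'
#' @param path path to a \code{branches.csv} written by
#'   \code{\link{exportResults}}.
#' @return data.frame of branch measurements.
#' @export
readBranchTable <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Read back an exported scan summary
#'
#' @param path path to a \code{summary.json}.
#' @return A \linkS4class{ScanSummary}.
#' @export
readScanSummary <- function(path) {
  j <- jsonlite::read_json(path)
  toNum <- function(x) stats::setNames(vapply(x, as.numeric, 0), names(x))
  scanSummary(genLA = toNum(j$genLA), genWAP = toNum(j$genWAP),
              pi10 = if (is.null(j$pi10)) NA_real_ else j$pi10,
              tac = j$tac,
              tlv = if (is.null(j$tlv)) NA_real_ else j$tlv)
}
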