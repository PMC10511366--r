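# MetaImage (.mha/.mhd) support. The format is a plain-text header followed
# by (or pointing to) a raw little-endian data block; only the axis-aligned
# 3D scalar subset needed here is implemented.

.metaTypes <- list(
  MET_UCHAR  = list(what = "integer", size = 1, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE))

readMetaImage <- function(path) {
  isMhd <- grepl("\\.mhd$", path, ignore.case = TRUE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) break
    kv <- regmatches(line, regexpr("=", line), invert = TRUE)[[1]]
    if (length(kv) != 2) stop("corrupt MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (is.null(hdr$NDims) || is.null(hdr$DimSize) ||
      is.null(hdr$ElementType) || is.null(hdr$ElementDataFile))
    stop("corrupt MetaImage header: missing required fields")
  ndims <- as.integer(hdr$NDims)
  if (ndims != 3L) stop("non-3D image (NDims = ", ndims, ")")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else rep(1, 3)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else rep(0, 3)
  if (!is.null(hdr$TransformMatrix)) {
    tm <- as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]])
    if (max(abs(tm - as.numeric(diag(3)))) > 1e-6)
      warning("non-identity orientation ignored; assuming axis-aligned")
  }
  type <- .metaTypes[[hdr$ElementType]]
  if (is.null(type)) stop("unsupported ElementType: ", hdr$ElementType)
  compressed <- identical(toupper(hdr$CompressedData %||% "FALSE"), "TRUE")
  n <- prod(dims)
  dataFile <- hdr$ElementDataFile
  readBlock <- function(c2) {
    readBin(c2, what = type$what, n = n, size = type$size,
            signed = type$signed, endian = "little")
  }
  if (identical(dataFile, "LOCAL")) {
    if (isMhd) stop(".mhd header cannot embed LOCAL data")
    raw <- if (compressed) {
      rest <- readBin(con, "raw", n = file.size(path))
      readBlock(rawConnection(memDecompress(rest, type = "gzip")))
    } else readBlock(con)
  } else {
    rawPath <- file.path(dirname(path), dataFile)
    if (!file.exists(rawPath)) stop("MetaImage data file not found: ", rawPath)
    c2 <- if (compressed) gzfile(rawPath, "rb") else file(rawPath, "rb")
    on.exit(close(c2), add = TRUE)
    raw <- readBlock(c2)
  }
  if (length(raw) != n) stop("corrupt MetaImage: short data block")
  imageVolume(array(as.numeric(raw), dim = dims), spacing, origin)
}

writeMetaImage <- function(vol, path) {
  v <- vol@values
  isInt <- all(v == round(v)) && max(abs(v)) < 2^31
  type <- if (isInt) "MET_INT" else "MET_DOUBLE"
  isMhd <- grepl("\\.mhd$", path, ignore.case = TRUE)
  dataRef <- if (isMhd) paste0(sub("\\.mhd$", "", basename(path),
                                   ignore.case = TRUE), ".raw") else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(vol@origin, digits = 15), collapse = " ")),
    paste("ElementSpacing =",
          paste(format(vol@spacing, digits = 15), collapse = " ")),
    paste("DimSize =", paste(dim(v), collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", dataRef))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  writeBlock <- function(c2) {
    if (isInt) writeBin(as.integer(v), c2, size = 4, endian = "little")
    else writeBin(as.numeric(v), c2, size = 8, endian = "little")
  }
  if (isMhd) {
    c2 <- file(file.path(dirname(path), dataRef), "wb")
    on.exit(close(c2), add = TRUE)
    writeBlock(c2)
  } else {
    writeBlock(con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
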