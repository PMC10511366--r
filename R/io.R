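#' Read a 3D medical image volume
#'
#' Reads NIfTI-1 (\code{.nii}, \code{.nii.gz}) or MetaImage (\code{.mha},
#' \code{.mhd}) files into an \linkS4class{ImageVolume}. Only axis-aligned
#' scans are supported; a non-identity orientation raises a warning and the
#' direction cosines are ignored.
#'
#' @param path file path with one of the supported extensions.
#' @return An \linkS4class{ImageVolume}.
#' @seealso \code{\link{writeVolume}}
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L) {
      if (length(d) == 4L && d[4] == 1L) {
        img <- array(as.numeric(img), dim = d[1:3])
        d <- d[1:3]
      } else stop("non-3D image (", length(d), " dimensions)")
    }
    pix <- RNifti::pixdim(img)[1:3]
    # origin from the sform/qform translation; direction cosines are not
    # resampled -- only axis-aligned scans are supported
    xf <- try(RNifti::xform(img), silent = TRUE)
    orig <- c(0, 0, 0)
    if (!inherits(xf, "try-error") && is.matrix(xf)) {
      rot <- xf[1:3, 1:3]
      offd <- abs(rot) - diag(abs(diag(rot)))
      if (max(abs(offd)) > 1e-4 * max(abs(rot)))
        warning("non-identity orientation ignored; assuming axis-aligned")
      orig <- as.numeric(xf[1:3, 4]) * sign(diag(rot))
      orig[!is.finite(orig)] <- 0
    }
    imageVolume(array(as.numeric(img), dim = d), pix, orig)
  } else if (grepl("\\.(mha|mhd)$", low)) {
    readMetaImage(path)
  } else {
    stop("unsupported extension (need .nii, .nii.gz, .mha or .mhd): ", path)
  }
}

#' Write a volume or mask to disk
#'
#' Writes NIfTI-1 or MetaImage according to the file extension. Integer-valued
#' volumes (masks) round-trip bitwise; floating HU volumes round-trip within
#' float precision for NIfTI and exactly for MetaImage (stored as doubles).
#'
#' @param vol an \linkS4class{ImageVolume} or \linkS4class{BinaryMask}.
#' @param path output path ending in .nii, .nii.gz, .mha or .mhd.
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ImageVolume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::asNifti(vol@values)
    RNifti::pixdim(img) <- vol@spacing
    mat <- diag(c(vol@spacing, 1))
    mat[1:3, 4] <- vol@origin
    RNifti::qform(img) <- structure(mat, code = 2L)
    RNifti::sform(img) <- structure(mat, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.(mha|mhd)$", low)) {
    writeMetaImage(vol, path)
  } else {
    stop("unsupported extension (need .nii, .nii.gz, .mha or .mhd): ", path)
  }
  invisible(path)
}

#' Read a mask file as a BinaryMask
#'
#' @inheritParams readVolume
#' @return A \linkS4class{BinaryMask}.
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  binaryMask(v@values != 0, v@spacing, v@origin)
}
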