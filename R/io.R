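#' Load a grayscale image as a unit-range intensity matrix
#'
#' PNG and TIFF images are read through their native readers (which scale
#' integer bit depths by the dtype maximum); multi-channel images are
#' collapsed to their channel mean. NIfTI volumes are read slice-wise:
#' \code{slice} selects an axial slice, and intensities above 1 are
#' rescaled by the volume maximum.
#'
#' @param path image file (.png, .tif/.tiff, .nii/.nii.gz).
#' @param slice axial slice index, required for NIfTI volumes.
#' @return numeric matrix with values in [0, 1].
#' @export
load_image <- function(path, slice = NULL) {
  if (!file.exists(path)) stop_input("cannot read image: %s", path)
  ext <- if (grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) ".nii.gz"
         else paste0(".", tolower(tools::file_ext(path)))
  img <- switch(ext,
    ".png" = png::readPNG(path),
    ".tif" = , ".tiff" = tiff::readTIFF(path),
    ".nii" = , ".nii.gz" = {
      vol <- RNifti::readNifti(path)
      if (length(dim(vol)) >= 3) {
        if (is.null(slice))
          stop_input("NIfTI volume %s requires a slice index", path)
        vol <- vol[, , slice]
      }
      vol <- as.matrix(vol)
      if (max(vol) > 1) vol <- vol / max(vol)
      vol
    },
    stop_input("unknown image format: %s", path))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  if (min(img) < 0) stop_input("negative intensities in %s", path)
  img
}

#' Save an intensity matrix as an 8-bit grayscale PNG
#'
#' Values are clipped to [0, 1] and quantized to 8 bits, so a round trip
#' agrees with the input to within 1/255.
#'
#' @param img numeric matrix.
#' @param path output .png path.
#' @export
save_image <- function(img, path) {
  png::writePNG(clip01(img), path)
  invisible(path)
}

#' Save / load a label map as an 8-bit PNG (labels stored verbatim)
#'
#' @param labels integer matrix with labels 0..c-1 (c <= 256).
#' @param path .png path.
#' @export
save_label_map <- function(labels, path) {
  if (max(labels) > 255) stop_input("label values exceed 8-bit range")
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname save_label_map
#' @export
load_label_map <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write a membership matrix as portable CSV text
#'
#' One row per cluster, one column per pixel (column-major pixel order of
#' the image matrix).
#'
#' @param U membership matrix.
#' @param path .csv path.
#' @export
save_memberships <- function(U, path) {
  utils::write.table(U, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname save_memberships
#' @export
load_memberships <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
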