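# Readers and writers for the image formats the pipeline touches:
# PNG and TIFF (8/16-bit grayscale) for slices and masks, NIfTI-1 for MR
# input. Intensities are min-max normalized to [0,1] at load so every
# downstream stage can rely on the GrayImage invariant.

#' Read a grayscale slice as a GrayImage
#'
#' Reads a PNG, TIFF, or NIfTI-1 image and min-max normalizes its
#' intensities to \[0, 1\] (a constant image maps to all zeros). Color
#' images are collapsed to the mean of their color channels (alpha
#' dropped). 3D NIfTI volumes are reduced to a single axial slice with a
#' warning; `slice = 1` (the first slice) is the default.
#'
#' @param path file path; format is taken from the extension
#'   (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param slice 1-based slice index used for 3D NIfTI volumes.
#' @return a [GrayImage-class].
#' @examples
#' p <- tempfile(fileext = ".png")
#' png::writePNG(matrix(seq(0, 1, length.out = 256), 16, 16), p)
#' readGrayImage(p)
#' @export
readGrayImage <- function(path, slice = 1L) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(sub(".*\\.(?=[^.]+$)", "", basename(path), perl = TRUE))
  if (grepl("\\.nii(\\.gz)?$", tolower(path))) ext <- "nii"
  m <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    nii = , gz = {
      vol <- RNifti::readNifti(path)
      a <- as.array(vol)
      if (length(dim(a)) > 2L) {
        a <- array(a, dim(a)[1:3])  # drop trailing singleton dims
        if (dim(a)[3] > 1L)
          warning("3D NIfTI volume: taking slice ", slice, " of ", dim(a)[3])
        a <- a[, , slice]
      }
      a
    },
    stop("unsupported image format: .", ext,
         " (supported: PNG, TIFF, NIfTI)")
  )
  if (length(dim(m)) == 3L) m <- apply(m[, , seq_len(min(3L, dim(m)[3])), drop = FALSE], c(1, 2), mean)
  GrayImage(minmax01(as.matrix(m)))
}

#' Read a binary mask
#'
#' Reads a PNG/TIFF mask; any pixel strictly above half intensity is
#' foreground.
#'
#' @param path file path to a PNG or TIFF mask.
#' @return a [BinaryMask-class].
#' @export
readMask <- function(path) {
  img <- readGrayImage(path)
  BinaryMask(img@.Data > 0.5)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground is written as 255, background as 0; the file round-trips
#' losslessly through [readMask()].
#'
#' @param mask a [BinaryMask-class] (or logical matrix).
#' @param path output path; the parent directory must exist.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  m <- asMaskMatrix(mask)
  if (!dir.exists(dirname(path)))
    stop("cannot write mask: no such directory: ", dirname(path))
  png::writePNG(array(as.numeric(m), dim(m)), path)
  invisible(path)
}

#' Write a GrayImage as a 16-bit TIFF
#'
#' 16-bit depth keeps the write/read round trip within 1/65535 per pixel.
#'
#' @param img a [GrayImage-class] (or numeric matrix in \[0,1\]).
#' @param path output path ending in `.tif`/`.tiff`.
#' @return the path, invisibly.
#' @export
writeGrayImage <- function(img, path) {
  m <- asImageMatrix(img)
  if (!dir.exists(dirname(path)))
    stop("cannot write image: no such directory: ", dirname(path))
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}
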