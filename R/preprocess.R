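# Stage 1: adaptive Wiener denoising, morphological skull stripping, and
# Gaussian-noise injection for the robustness experiments.
#
# Morphological primitives ride on EBImage's erode/dilate/fillHull with
# two local conventions: footprints are built here (exact x^2+y^2 <= r^2
# disks), and masks are padded with background before erosion/dilation so
# that out-of-image counts as background.

#' Build a structuring element
#'
#' @param radius integer >= 1, half-width in pixels.
#' @param shape `"disk"` (pixels with x^2 + y^2 <= radius^2) or
#'   `"square"` (full (2r+1) x (2r+1) block).
#' @return a [StructuringElement-class].
#' @examples
#' structuringElement(2)@footprint
#' @export
structuringElement <- function(radius, shape = c("disk", "square")) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1")
  s <- 2L * radius + 1L
  fp <- if (shape == "square") matrix(1, s, s) else {
    off <- seq(-radius, radius)
    1 * (outer(off^2, off^2, "+") <= radius^2)
  }
  new("StructuringElement", shape = shape, radius = radius, footprint = fp)
}

#' Add zero-mean Gaussian noise to an image
#'
#' Used to reproduce the noise-robustness protocol: noise of variance
#' 0.005, 0.01 or 0.02 (on the \[0,1\] intensity scale) is added to the
#' slice before preprocessing. The result is clipped back to \[0, 1\].
#' The draw is seeded, so a fixed seed gives a bit-identical image.
#'
#' @param img a [GrayImage-class].
#' @param variance noise variance >= 0 on the \[0,1\] scale.
#' @param seed integer seed for the noise draw.
#' @return a [GrayImage-class].
#' @export
addGaussianNoise <- function(img, variance, seed = 1L) {
  m <- asImageMatrix(img)
  if (variance < 0) stop("noise variance must be >= 0")
  if (variance == 0) return(GrayImage(m))
  noise <- withSeed(seed, matrix(rnorm(length(m), 0, sqrt(variance)), nrow(m)))
  GrayImage(clip01(m + noise))
}

#' Adaptive Wiener denoising
#'
#' Local-statistics (Lee-type) adaptive Wiener filter: with local mean
#' `mu` and local variance `s2` over a `window x window` neighbourhood,
#' each pixel is replaced by
#' `mu + max(0, s2 - nv) / max(s2, nv) * (x - mu)`
#' where `nv` is the noise variance, estimated as the mean of the local
#' variances when not supplied. Flat regions collapse to their local mean
#' while high-variance structure (edges) passes through nearly unchanged,
#' which is what makes the filter suitable for MR slices: it suppresses
#' Gaussian noise without destroying tissue boundaries.
#'
#' @param img a [GrayImage-class].
#' @param window odd window size >= 3, smaller than both image dimensions.
#' @param noiseVar known noise variance, or NULL to estimate.
#' @return the denoised [GrayImage-class] (clipped to \[0,1\]).
#' @export
wienerDenoise <- function(img, window = 3L, noiseVar = NULL) {
  m <- asImageMatrix(img)
  window <- oddWindowCheck(window)
  if (window >= min(dim(m)))
    stop("window must be smaller than both image dimensions")
  mu <- boxMean(m, window)
  s2 <- pmax(0, boxMean(m * m, window) - mu * mu)
  nv <- if (is.null(noiseVar)) mean(s2) else {
    if (noiseVar < 0) stop("noise variance must be >= 0")
    noiseVar
  }
  gain <- if (nv == 0) as.numeric(s2 > 0) else pmax(0, s2 - nv) / pmax(s2, nv)
  out <- mu + gain * (m - mu)
  GrayImage(clip01(out))
}

# pad-with-background wrappers around EBImage erosion/dilation
padCrop <- function(m, r, f) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L * r, nc + 2L * r)
  p[r + seq_len(nr), r + seq_len(nc)] <- m
  f(p)[r + seq_len(nr), r + seq_len(nc)]
}

erodeMask <- function(m, elem) {
  padCrop(m * 1, elem@radius, function(p) EBImage::erode(p, elem@footprint)) > 0.5
}

dilateMask <- function(m, elem) {
  padCrop(m * 1, elem@radius, function(p) EBImage::dilate(p, elem@footprint)) > 0.5
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with the same structuring element.
#' Opening is anti-extensive (the result is a subset of the input),
#' increasing, and idempotent; it removes structures smaller than the
#' element — here, the thin skull ring — while preserving larger shapes.
#'
#' @param mask a [BinaryMask-class] (or logical matrix).
#' @param elem a [StructuringElement-class].
#' @return the opened [BinaryMask-class].
#' @export
morphOpen <- function(mask, elem) {
  m <- asMaskMatrix(mask)
  BinaryMask(dilateMask(erodeMask(m, elem), elem))
}

#' Fill interior holes of a binary mask
#'
#' Every background region not connected to the image border becomes
#' foreground. Extensive (input is a subset of the output) and
#' idempotent.
#'
#' @param mask a [BinaryMask-class] (or logical matrix).
#' @return the filled [BinaryMask-class].
#' @export
fillHoles <- function(mask) {
  m <- asMaskMatrix(mask)
  BinaryMask(EBImage::fillHull(m * 1) > 0.5)
}

# 8-connected components: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass over the label graph.
label8 <- function(m) {
  lab <- EBImage::bwlabel(m * 1)
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal pairs
  pairs <- unique(rbind(
    cbind(a1[a1 > 0 & b1 > 0 & a1 != b1], b1[a1 > 0 & b1 > 0 & a1 != b1]),
    cbind(a2[a2 > 0 & b2 > 0 & a2 != b2], b2[a2 > 0 & b2 > 0 & a2 != b2])))
  if (nrow(pairs)) for (i in seq_len(nrow(pairs))) unite(pairs[i, 1], pairs[i, 2])
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

largestComponent <- function(m) {
  lab <- label8(m)
  if (max(lab) == 0L) return(m & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Morphological skull stripping
#'
#' Brain surface extraction on a denoised slice: (1) binarize at a head
#' threshold (Otsu by default), (2) morphological opening removes the
#' thin bright skull ring and other structures smaller than the element,
#' (3) keep the largest 8-connected component (the parenchyma), (4) fill
#' interior holes so dark structures inside the brain (ventricles) stay
#' in the mask. Returns the brain mask and the image with all non-brain
#' pixels set to 0.
#'
#' @param img the denoised [GrayImage-class].
#' @param elem a [StructuringElement-class]; NULL scales a disk with the
#'   image, radius `max(1, round(min(dim) / 51))` (5 at 256 x 256).
#' @param headThreshold `"otsu"` or a number in (0, 1).
#' @return list with elements `mask` ([BinaryMask-class]) and `image`
#'   (the masked [GrayImage-class]).
#' @export
skullStrip <- function(img, elem = NULL, headThreshold = "otsu") {
  m <- asImageMatrix(img)
  if (is.null(elem))
    elem <- structuringElement(max(1L, as.integer(round(min(dim(m)) / 51))))
  thr <- if (identical(headThreshold, "otsu")) {
    EBImage::otsu(EBImage::Image(m))
  } else {
    stopifnot(is.numeric(headThreshold), headThreshold > 0, headThreshold < 1)
    headThreshold
  }
  fg <- m > thr
  if (!any(fg)) stop("no head detected: empty foreground after thresholding")
  opened <- morphOpen(BinaryMask(fg), elem)@.Data
  if (!any(opened)) stop("no head detected: opening removed all foreground")
  brain <- fillHoles(BinaryMask(largestComponent(opened)))@.Data
  list(mask = BinaryMask(brain), image = GrayImage(m * brain))
}
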