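# Synthetic FLAIR-like brain phantom with exact ground truth.
#
# The phantom reproduces the structure the segmentation method assumes:
# dark background, a bright thin skull ring separated from the
# parenchyma by a dark subarachnoid gap (CSF is attenuated on FLAIR), an
# outer gray-matter band, white-matter interior, two dark ventricles,
# and one hyperintense tumor/edema blob placed in the white matter.
# Class mean intensities are ordered background < CSF < GM < WM < tumor
# with skull >= WM, and separations >= 0.2 so the classes stay several
# noise standard deviations apart at the highest studied variance.

PHANTOM_MEANS <- c(background = 0.02, csf = 0.25, gm = 0.45, wm = 0.65,
                   skull = 0.75, tumor = 0.90)
# tissue label codes used in the LabelMap
PHANTOM_CODES <- c(background = 0L, skull = 1L, csf = 2L, gm = 3L,
                   wm = 4L, tumor = 5L)

#' Generate a ground-truthed brain phantom
#'
#' Builds a `size x size` FLAIR-like slice (see the package vignette for
#' the geometry) with Gaussian noise of variance `noiseVar` added and
#' clipped to \[0, 1\]. Boundary irregularity and the tumor location are
#' drawn from the seeded RNG, so a fixed seed yields a bit-identical
#' phantom.
#'
#' @param size side length in pixels, >= 64.
#' @param noiseVar Gaussian noise variance on the \[0,1\] scale
#'   (the robustness protocol uses 0.005, 0.01, 0.02).
#' @param tumorRadiusFrac tumor semi-major axis as a fraction of `size`,
#'   in (0, 0.3\].
#' @param seed integer RNG seed.
#' @return a [BrainPhantom-class].
#' @examples
#' ph <- generatePhantom(128, noiseVar = 0.01, seed = 42)
#' ph
#' @export
generatePhantom <- function(size = 256L, noiseVar = 0, tumorRadiusFrac = 0.12,
                            seed = 1L) {
  size <- as.integer(size)
  if (size < 64L) stop("size must be >= 64")
  if (noiseVar < 0) stop("noise variance must be >= 0")
  if (tumorRadiusFrac <= 0 || tumorRadiusFrac > 0.3)
    stop("tumorRadiusFrac must lie in (0, 0.3]")

  cy <- cx <- (size + 1) / 2
  aR <- 0.43 * size  # head ellipse row semi-axis
  aC <- 0.36 * size  # head ellipse col semi-axis
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  dy <- (yy - cy) / aR
  dx <- (xx - cx) / aC
  rho <- sqrt(dy^2 + dx^2)
  theta <- atan2(yy - cy, xx - cx)

  e <- 1 / aC                                # ~1 px in normalized units
  tSkull <- max(2L, as.integer(round(3 * size / 256)))
  gap <- max(2L, as.integer(round(4 * size / 256)))
  skullIn <- 1 - tSkull * e
  brainOut <- skullIn - gap * e

  withSeed(seed, {
    # low-frequency boundary irregularity
    wob <- function(modes, amp) {
      a <- runif(length(modes), 0, amp)
      ph <- runif(length(modes), 0, 2 * pi)
      d <- 0
      for (i in seq_along(modes)) d <- d + a[i] * cos(modes[i] * theta + ph[i])
      d
    }
    rBrain <- brainOut * (1 + wob(c(3, 5), 0.008))
    gmIn <- 0.80 * rBrain * (1 + wob(2:4, 0.03))

    lab <- array(PHANTOM_CODES[["background"]], c(size, size))
    lab[rho <= 1 & rho > skullIn] <- PHANTOM_CODES[["skull"]]
    brain <- rho <= rBrain
    lab[brain] <- PHANTOM_CODES[["wm"]]
    lab[brain & rho > gmIn] <- PHANTOM_CODES[["gm"]]

    # lateral ventricles (CSF), elongated vertically, flanking the midline
    vOff <- 0.09 * size
    vR <- 0.13 * size; vC <- 0.045 * size
    vent <- (((yy - cy) / vR)^2 + ((xx - cx - vOff) / vC)^2 <= 1) |
            (((yy - cy) / vR)^2 + ((xx - cx + vOff) / vC)^2 <= 1)
    lab[vent & brain] <- PHANTOM_CODES[["csf"]]

    # tumor: rotated ellipse inside the white matter, clear of ventricles
    A <- tumorRadiusFrac * size
    B <- 0.8 * A
    placed <- FALSE
    for (try in 1:200) {
      ty <- cy + runif(1, -0.30, 0.30) * size
      tx <- cx + runif(1, -0.30, 0.30) * size
      ang <- runif(1, 0, pi)
      u <- (yy - ty) * cos(ang) + (xx - tx) * sin(ang)
      w <- -(yy - ty) * sin(ang) + (xx - tx) * cos(ang)
      tum <- (u / A)^2 + (w / B)^2 <= 1
      inside <- rho <= (rBrain - 2 * e)      # margin to the brain edge
      if (any(tum) && all(inside[tum]) && !any(vent[tum])) { placed <- TRUE; break }
    }
    if (!placed) stop("could not place a tumor of this size inside the phantom")
    lab[tum] <- PHANTOM_CODES[["tumor"]]

    img <- array(PHANTOM_MEANS[["background"]], c(size, size))
    for (cls in names(PHANTOM_CODES))
      img[lab == PHANTOM_CODES[[cls]]] <- PHANTOM_MEANS[[cls]]
    if (noiseVar > 0)
      img <- img + matrix(rnorm(size * size, 0, sqrt(noiseVar)), size)
    img <- clip01(img)
  })

  brainMask <- array(lab %in% PHANTOM_CODES[c("csf", "gm", "wm", "tumor")],
                     c(size, size))
  new("BrainPhantom",
      image = GrayImage(img),
      tissueLabels = LabelMap(lab),
      tumorMask = BinaryMask(array(lab == PHANTOM_CODES[["tumor"]], c(size, size))),
      brainMask = BinaryMask(brainMask),
      params = list(size = size, noiseVar = noiseVar,
                    tumorRadiusFrac = tumorRadiusFrac, seed = as.integer(seed),
                    classMeans = PHANTOM_MEANS, labelCodes = PHANTOM_CODES,
                    skullThickness = tSkull, gapWidth = gap))
}
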