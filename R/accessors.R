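# Constructors, accessors and show methods.

#' Construct a GrayImage
#'
#' @param pixels numeric matrix of intensities.
#' @param normalize if TRUE, min-max rescale to \[0, 1\] first (a constant
#'   matrix maps to all zeros); if FALSE the matrix must already satisfy
#'   the \[0, 1\] invariant.
#' @return a [GrayImage-class].
#' @examples
#' img <- GrayImage(matrix(seq(0, 1, length.out = 64), 8, 8))
#' range(img)
#' @export
GrayImage <- function(pixels, normalize = FALSE) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (normalize) pixels <- minmax01(pixels)
  new("GrayImage", pixels)
}

#' Construct a BinaryMask
#'
#' @param pixels logical (or coercible 0/1) matrix.
#' @return a [BinaryMask-class].
#' @export
BinaryMask <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) {
    stopifnot(all(pixels %in% c(0, 1)))
    pixels <- array(as.logical(pixels), dim(pixels))
  }
  new("BinaryMask", pixels)
}

#' Construct a LabelMap
#'
#' @param pixels integer matrix of cluster ids, -1 for outside-mask.
#' @return a [LabelMap-class].
#' @export
LabelMap <- function(pixels) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  new("LabelMap", pixels)
}

#' Pipeline configuration
#'
#' See [SegConfig-class] for the meaning and units of each parameter.
#'
#' @param k number of clusters (tissue classes inside the brain).
#' @param fuzzyIndex fuzzifier n > 1.
#' @param sigma2 Gaussian kernel width sigma^2 > 0 on \[0,1\] intensities.
#' @param epsilon convergence tolerance on the objective.
#' @param maxIter iteration cap.
#' @param wienerWindow odd Wiener filter window (pixels).
#' @param openRadius skull-strip structuring-element radius, NA = scaled
#'   with the image as `round(min(dim) / 51)`.
#' @param medianWindow odd postprocessing median window (pixels).
#' @param seed integer seed for all randomness in a run.
#' @return a validated [SegConfig-class].
#' @examples
#' segConfig(k = 4, sigma2 = 0.1)
#' @export
segConfig <- function(k = 4L, fuzzyIndex = 2, sigma2 = 0.1, epsilon = 1e-5,
                      maxIter = 100L, wienerWindow = 3L, openRadius = NA,
                      medianWindow = 3L, seed = 1L) {
  new("SegConfig", k = as.integer(k), fuzzyIndex = as.numeric(fuzzyIndex),
      sigma2 = as.numeric(sigma2), epsilon = as.numeric(epsilon),
      maxIter = as.integer(maxIter), wienerWindow = as.integer(wienerWindow),
      openRadius = as.numeric(openRadius),
      medianWindow = as.integer(medianWindow), seed = as.integer(seed))
}

#' @rdname ClusterResult-class
#' @export
setMethod("centroids", "ClusterResult", function(object) object@centroids)
#' @rdname ClusterResult-class
#' @export
setMethod("membership", "ClusterResult", function(object) object@membership)
#' @rdname ClusterResult-class
#' @export
setMethod("objectiveTrace", "ClusterResult", function(object) object@objective)
#' @rdname ClusterResult-class
#' @export
setMethod("nIter", "ClusterResult", function(object) object@nIter)
#' @rdname ClusterResult-class
#' @export
setMethod("converged", "ClusterResult", function(object) object@converged)
#' @rdname ClusterResult-class
#' @export
setMethod("labels", "ClusterResult", function(object) object@labels)

#' @rdname BrainPhantom-class
#' @export
setMethod("grayImage", "BrainPhantom", function(object) object@image)
#' @rdname BrainPhantom-class
#' @export
setMethod("tumorMask", "BrainPhantom", function(object) object@tumorMask)
#' @rdname BrainPhantom-class
#' @export
setMethod("brainMask", "BrainPhantom", function(object) object@brainMask)
#' @rdname BrainPhantom-class
#' @export
setMethod("labelMap", "BrainPhantom", function(object) object@tissueLabels)

#' @rdname SegRun-class
#' @param object a SegRun.
#' @export
setMethod("tumorMask", "SegRun", function(object) object@tumorMask)
#' @rdname SegRun-class
#' @export
setMethod("brainMask", "SegRun", function(object) object@brainMask)
#' @rdname SegRun-class
#' @export
setMethod("labelMap", "SegRun", function(object) object@labels)

#' @rdname MetricsReport-class
#' @export
setMethod("paperMetrics", "MetricsReport", function(object) object@paper)
#' @rdname MetricsReport-class
#' @export
setMethod("standardMetrics", "MetricsReport", function(object) object@standard)

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage %d x %d, intensity range [%.4f, %.4f]\n",
              nrow(object), ncol(object), min(object@.Data), max(object@.Data)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %d x %d, %d foreground pixels (%.1f%%)\n",
              nrow(object), ncol(object), sum(object@.Data),
              100 * mean(object@.Data)))
})

setMethod("show", "LabelMap", function(object) {
  tab <- table(object@.Data)
  cat(sprintf("LabelMap %d x %d, labels: %s\n", nrow(object), ncol(object),
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
})

setMethod("show", "SegConfig", function(object) {
  cat("SegConfig:\n")
  cat(sprintf("  k = %d, fuzzyIndex = %g, sigma2 = %g, epsilon = %g, maxIter = %d\n",
              object@k, object@fuzzyIndex, object@sigma2, object@epsilon,
              object@maxIter))
  cat(sprintf("  wienerWindow = %d, openRadius = %s, medianWindow = %d, seed = %d\n",
              object@wienerWindow,
              ifelse(is.na(object@openRadius), "auto",
                     format(object@openRadius)),
              object@medianWindow, object@seed))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult [%s]: %d pixels, %d clusters\n", object@method,
              nrow(object@membership), length(object@centroids)))
  cat("  centroids:", paste(sprintf("%.4f", object@centroids), collapse = " "), "\n")
  cat(sprintf("  %d iterations, converged: %s, final J = %.6g\n",
              object@nIter, object@converged,
              object@objective[length(object@objective)]))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP = %d, TN = %d, FP = %d, FN = %d\n",
              object@TP, object@TN, object@FP, object@FN))
})

setMethod("show", "MetricsReport", function(object) {
  m <- rbind(paper = object@paper, standard = object@standard)
  cat("MetricsReport (rows: printed formulas / standard definitions)\n")
  print(round(m, 4))
})

setMethod("show", "BrainPhantom", function(object) {
  p <- object@params
  cat(sprintf("BrainPhantom %d x %d, noise variance %g, seed %d\n",
              nrow(object@image), ncol(object@image), p$noiseVar, p$seed))
  cat(sprintf("  brain %d px, tumor %d px\n",
              sum(object@brainMask@.Data), sum(object@tumorMask@.Data)))
})

setMethod("show", "SegRun", function(object) {
  cat(sprintf("SegRun: tumor mask %d px, %d GKFCM iterations, seed %d\n",
              sum(object@tumorMask@.Data), object@clustering@nIter,
              object@config@seed))
  if (is(object@metrics, "MetricsReport")) {
    cat(sprintf("  standard Dice vs truth: %.4f\n",
                object@metrics@standard[["dice"]]))
  }
})
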