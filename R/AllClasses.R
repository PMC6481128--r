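#' @import methods
#' @importFrom stats rnorm sd var
NULL

#' GrayImage: a 2D intensity field on [0, 1]
#'
#' The unit every pipeline stage consumes and produces. A `GrayImage` is a
#' numeric matrix (rows = image rows, row-major pixel index j in raster
#' order) whose intensities are guaranteed to lie in \[0, 1\]; readers
#' min-max normalize at load time so this invariant holds from the moment
#' an image enters the package.
#'
#' @slot .Data numeric matrix of intensities in \[0, 1\], at least 8 x 8.
#' @seealso [readGrayImage()], [GrayImage()]
#' @export
setClass("GrayImage", contains = "matrix", validity = function(object) {
  m <- object@.Data
  if (!is.numeric(m) || length(dim(m)) != 2L)
    return("pixels must be a numeric matrix")
  if (nrow(m) < 8L || ncol(m) < 8L)
    return("image must be at least 8 x 8 pixels")
  if (anyNA(m) || any(!is.finite(m)))
    return("intensities must be finite and non-missing")
  if (min(m) < 0 || max(m) > 1)
    return("intensities must lie in [0, 1]")
  TRUE
})

#' BinaryMask: a per-pixel boolean region
#'
#' Logical matrix sharing the grid of the image it annotates (brain mask,
#' tumor mask, ground truth).
#'
#' @slot .Data logical matrix.
#' @seealso [BinaryMask()], [writeMask()]
#' @export
setClass("BinaryMask", contains = "matrix", validity = function(object) {
  m <- object@.Data
  if (!is.logical(m) || length(dim(m)) != 2L)
    return("mask must be a logical matrix")
  if (anyNA(m))
    return("mask must not contain NA")
  TRUE
})

#' LabelMap: hard cluster assignments on the image grid
#'
#' Integer matrix of cluster indices `0..k-1`, with `-1` marking pixels
#' outside the clustered region (outside the brain mask).
#'
#' @slot .Data integer matrix with values >= -1.
#' @export
setClass("LabelMap", contains = "matrix", validity = function(object) {
  m <- object@.Data
  if (!is.integer(m) || length(dim(m)) != 2L)
    return("labels must be an integer matrix")
  if (anyNA(m) || any(m < -1L))
    return("labels must be >= -1 with -1 meaning outside the mask")
  TRUE
})

#' SegConfig: pipeline parameters
#'
#' Holds every tunable of the segmentation pipeline. Defaults follow the
#' method's standard operating point on \[0, 1\] intensities: `k = 4`
#' tissue classes (CSF, gray matter, white matter, tumor/edema), fuzzy
#' index `n = 2`, Gaussian kernel width `sigma2 = 0.1`, objective
#' tolerance `epsilon = 1e-5`, and 3x3 windows for the Wiener and median
#' filters. `openRadius = NA` scales the skull-stripping disk with the
#' image: `round(min(height, width) / 51)`, i.e. radius 5 at 256 x 256.
#'
#' @slot k integer >= 2, number of clusters.
#' @slot fuzzyIndex numeric > 1, fuzzifier n of the membership weights.
#' @slot sigma2 positive numeric, Gaussian kernel width on the \[0,1\]
#'   intensity scale.
#' @slot epsilon positive numeric, stop when |J(i) - J(i-1)| <= epsilon.
#' @slot maxIter positive integer iteration cap.
#' @slot wienerWindow odd integer >= 3, adaptive Wiener filter window.
#' @slot openRadius structuring-element radius in pixels for skull
#'   stripping, or NA to scale with image size.
#' @slot medianWindow odd integer >= 3, postprocessing majority filter.
#' @slot seed integer RNG seed driving every random draw in a run.
#' @seealso [segConfig()]
#' @export
setClass("SegConfig", representation(
  k = "integer", fuzzyIndex = "numeric", sigma2 = "numeric",
  epsilon = "numeric", maxIter = "integer", wienerWindow = "integer",
  openRadius = "numeric", medianWindow = "integer", seed = "integer"
), validity = function(object) {
  if (object@k < 2L) return("k must be >= 2")
  if (object@fuzzyIndex <= 1) return("fuzzyIndex must be > 1")
  if (object@sigma2 <= 0) return("sigma2 must be > 0")
  if (object@epsilon <= 0) return("epsilon must be > 0")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  for (w in c(object@wienerWindow, object@medianWindow))
    if (w < 3L || w %% 2L == 0L) return("filter windows must be odd and >= 3")
  if (!is.na(object@openRadius) && object@openRadius < 1)
    return("openRadius must be >= 1 or NA for image-scaled")
  TRUE
})

#' StructuringElement: footprint for morphological operations
#'
#' A disk (`x^2 + y^2 <= r^2`) or square footprint, symmetric about its
#' center, built by [structuringElement()].
#'
#' @slot shape `"disk"` or `"square"`.
#' @slot radius integer >= 1, half-width in pixels.
#' @slot footprint 0/1 numeric matrix of odd side `2*radius + 1`.
#' @export
setClass("StructuringElement", representation(
  shape = "character", radius = "integer", footprint = "matrix"
), validity = function(object) {
  if (!object@shape %in% c("disk", "square"))
    return("shape must be 'disk' or 'square'")
  if (object@radius < 1L) return("radius must be >= 1")
  fp <- object@footprint
  if (any(dim(fp) != 2L * object@radius + 1L))
    return("footprint side must be 2*radius + 1")
  if (!isTRUE(all.equal(fp, fp[rev(seq_len(nrow(fp))), rev(seq_len(ncol(fp)))])))
    return("footprint must be symmetric about its center")
  TRUE
})

#' ClusterResult: output of a clustering run
#'
#' @slot centroids numeric vector of cluster centroid intensities (length k).
#' @slot membership N x k matrix of fuzzy memberships u_ij; each row sums
#'   to 1 (crisp 0/1 rows for hard K-means).
#' @slot labels integer vector, `labels[j] = argmax_i u_ij` (ties go to
#'   the lowest cluster index), 0-based cluster ids.
#' @slot objective numeric trace of the objective J per iteration
#'   (element 1 is J at initialization); nonincreasing.
#' @slot nIter number of update iterations performed.
#' @slot converged TRUE if the |dJ| <= epsilon stopping rule fired before
#'   the iteration cap.
#' @slot method `"kgkfcm"`, `"fcm"` or `"kmeans"`.
#' @seealso [gkfcmFit()], [fcmFit()], [kmeansFit()]
#' @export
setClass("ClusterResult", representation(
  centroids = "numeric", membership = "matrix", labels = "integer",
  objective = "numeric", nIter = "integer", converged = "logical",
  method = "character"
), validity = function(object) {
  u <- object@membership
  if (ncol(u) != length(object@centroids))
    return("membership columns must match centroid count")
  if (length(object@labels) != nrow(u))
    return("labels length must match membership rows")
  if (any(u < -1e-12) || any(u > 1 + 1e-12))
    return("memberships must lie in [0, 1]")
  if (max(abs(rowSums(u) - 1)) > 1e-9)
    return("membership rows must sum to 1 (within 1e-9)")
  J <- object@objective
  if (length(J) > 1L) {
    dJ <- diff(J)
    if (any(dJ > 1e-12 * pmax(abs(J[-length(J)]), 1)))
      return("objective trace must be nonincreasing")
  }
  TRUE
})

#' ConfusionCounts: pixelwise TP/TN/FP/FN tallies
#'
#' @slot TP,TN,FP,FN nonnegative pixel counts; their sum equals the number
#'   of evaluated pixels.
#' @seealso [confusionCounts()], [segMetrics()]
#' @export
setClass("ConfusionCounts", representation(
  TP = "numeric", TN = "numeric", FP = "numeric", FN = "numeric"
), validity = function(object) {
  v <- c(object@TP, object@TN, object@FP, object@FN)
  if (any(v < 0) || any(v != round(v))) return("counts must be nonnegative integers")
  TRUE
})

#' MetricsReport: overlap metrics under both formulations
#'
#' Dice, sensitivity, specificity and recall computed from a
#' [ConfusionCounts-class] under the method's printed formulas
#' (`paper`) and under the standard definitions (`standard`). Recall,
#' TP/(TP+FN), is identical in both. Undefined ratios (zero denominator)
#' are NaN.
#'
#' @slot paper named numeric: dice, sensitivity, specificity, recall as
#'   printed (dice = (TP+TN)/total, sensitivity = TP/(TP+FP),
#'   specificity = FN/(TN+FN)).
#' @slot standard named numeric: dice = 2TP/(2TP+FP+FN), sensitivity =
#'   TP/(TP+FN), specificity = TN/(TN+FP), recall = TP/(TP+FN).
#' @slot counts the [ConfusionCounts-class] the metrics came from.
#' @export
setClass("MetricsReport", representation(
  paper = "numeric", standard = "numeric", counts = "ConfusionCounts"
), validity = function(object) {
  nm <- c("dice", "sensitivity", "specificity", "recall")
  if (!identical(names(object@paper), nm) || !identical(names(object@standard), nm))
    return("metric vectors must be named dice, sensitivity, specificity, recall")
  ok <- function(x) all(is.nan(x) | (x >= 0 & x <= 1))
  if (!ok(object@paper) || !ok(object@standard))
    return("defined metrics must lie in [0, 1]")
  TRUE
})

#' BrainPhantom: a ground-truthed synthetic brain slice
#'
#' FLAIR-like phantom: dark background, bright skull ring separated from
#' the parenchyma by a dark subarachnoid gap, CSF/GM/WM tissue classes,
#' and one hyperintense tumor blob. Carries the exact tissue label map and
#' the masks the pipeline is supposed to recover.
#'
#' @slot image the noisy [GrayImage-class].
#' @slot tissueLabels [LabelMap-class] with codes 0 background, 1 skull,
#'   2 CSF, 3 gray matter, 4 white matter, 5 tumor.
#' @slot tumorMask,brainMask ground-truth [BinaryMask-class] objects;
#'   the tumor mask is a subset of the brain mask, skull pixels are not.
#' @slot params list of generation parameters (geometry, class means,
#'   noise variance, seed).
#' @seealso [generatePhantom()]
#' @export
setClass("BrainPhantom", representation(
  image = "GrayImage", tissueLabels = "LabelMap",
  tumorMask = "BinaryMask", brainMask = "BinaryMask", params = "list"
), validity = function(object) {
  d <- dim(object@image)
  if (!identical(d, dim(object@tissueLabels)) ||
      !identical(d, dim(object@tumorMask)) ||
      !identical(d, dim(object@brainMask)))
    return("image, labels and masks must share one grid")
  if (any(object@tumorMask@.Data & !object@brainMask@.Data))
    return("tumor mask must be contained in the brain mask")
  if (any(object@brainMask@.Data & object@tissueLabels@.Data == 1L))
    return("skull pixels must not be in the brain mask")
  TRUE
})

#' SegRun: manifest of one end-to-end pipeline run
#'
#' @slot config the [SegConfig-class] used.
#' @slot brainMask,tumorMaskRaw,tumorMask masks from skull stripping,
#'   extraction, and postprocessing.
#' @slot labels [LabelMap-class] over the full grid (-1 outside brain).
#' @slot clustering the [ClusterResult-class].
#' @slot metrics [MetricsReport-class] or NULL when no truth given.
#' @slot manifest list: config snapshot, input hashes, output paths,
#'   objective trace, seed, wall time.
#' @seealso [runPipeline()]
#' @export
setClass("SegRun", representation(
  config = "SegConfig", brainMask = "BinaryMask",
  tumorMaskRaw = "BinaryMask", tumorMask = "BinaryMask",
  labels = "LabelMap", clustering = "ClusterResult",
  metrics = "ANY", manifest = "list"
))
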