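# Stage 3: pick the tumor cluster out of the label map, then repair the
# binary tumor mask (fill holes, then binary median filtering).

#' Extract the tumor mask from a label map
#'
#' On FLAIR-like images the tumor/edema class is hyperintense, so by
#' default the cluster with the maximal centroid intensity is taken as
#' tumor. Alternatively an explicit intensity threshold selects every
#' cluster whose centroid exceeds it.
#'
#' @param labels a [LabelMap-class] (cluster ids, -1 outside the brain).
#' @param centroids numeric vector of cluster centroid intensities;
#'   `centroids[i + 1]` corresponds to label `i`.
#' @param threshold NULL for the maximal-centroid rule, or a number:
#'   clusters with centroid > threshold are tumor.
#' @return the tumor [BinaryMask-class] (always a subset of the in-brain
#'   pixels).
#' @export
extractTumor <- function(labels, centroids, threshold = NULL) {
  lab <- labels@.Data
  if (max(lab) >= length(centroids))
    stop("label range exceeds centroid count")
  if (length(unique(centroids)) == 1L)
    stop("ambiguous tumor cluster: all centroids are equal")
  tumorIds <- if (is.null(threshold)) which.max(centroids) - 1L
              else which(centroids > threshold) - 1L
  BinaryMask(array(lab %in% tumorIds, dim(lab)))
}

#' Postprocess a tumor mask
#'
#' Hole filling followed by a binary median (majority) filter: interior
#' holes left by fuzzy boundaries are filled, then each pixel takes the
#' majority vote of its `medianWindow x medianWindow` neighbourhood
#' (outside-image counts as background), which removes isolated
#' missegmented pixels and smooths ragged edges.
#'
#' @param mask the raw tumor [BinaryMask-class].
#' @param medianWindow odd window size >= 3.
#' @return the repaired [BinaryMask-class].
#' @export
postprocessMask <- function(mask, medianWindow = 3L) {
  w <- oddWindowCheck(medianWindow)
  filled <- fillHoles(mask)@.Data
  cnt <- boxSum0(filled * 1, w)
  BinaryMask(cnt > (w * w) / 2)
}
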