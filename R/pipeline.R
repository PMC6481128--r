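# End-to-end orchestration of the three pipeline stages:
# preprocess (Wiener denoise + skull strip) -> K++GKFCM clustering ->
# tumor extraction + postprocessing, with an optional evaluation against
# ground truth and a reproducibility manifest.

#' Run the full segmentation pipeline
#'
#' Executes denoising, skull stripping, K++GKFCM clustering of the
#' in-brain intensities, maximal-centroid tumor extraction, and mask
#' postprocessing. When `outDir` is given, every intermediate image is
#' written (noisy input, denoised, brain mask, label map, raw and final
#' tumor masks) together with a JSON manifest; identical config, input
#' and seed reproduce every output byte for byte.
#'
#' @param image a [GrayImage-class], or a file path readable by
#'   [readGrayImage()].
#' @param config a [SegConfig-class].
#' @param truth optional ground-truth tumor mask ([BinaryMask-class] or
#'   path) enabling metric computation.
#' @param noiseVar variance of Gaussian noise injected before
#'   preprocessing (0 = none); part of the noise-robustness protocol.
#' @param tumorThreshold NULL for the maximal-centroid rule, or an
#'   intensity threshold passed to [extractTumor()].
#' @param outDir optional output directory (created if missing).
#' @return a [SegRun-class].
#' @examples
#' ph <- generatePhantom(128, seed = 7)
#' run <- runPipeline(grayImage(ph), segConfig(seed = 7), truth = tumorMask(ph))
#' run
#' @export
runPipeline <- function(image, config = segConfig(), truth = NULL,
                        noiseVar = 0, tumorThreshold = NULL, outDir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  inputHash <- NA_character_
  if (is.character(image)) {
    inputHash <- unname(tools::md5sum(image))
    image <- readGrayImage(image)
  }
  if (is.character(truth)) truth <- readMask(truth)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  noisy <- stage("noise", {
    if (noiseVar > 0) addGaussianNoise(image, noiseVar, config@seed) else image
  })
  denoised <- stage("denoise", wienerDenoise(noisy, config@wienerWindow))
  stripped <- stage("skullstrip", {
    elem <- if (is.na(config@openRadius)) NULL
            else structuringElement(as.integer(config@openRadius))
    skullStrip(denoised, elem)
  })
  fit <- stage("cluster", gkfcmFit(stripped$image@.Data[stripped$mask@.Data],
                                   config))
  labels <- labelsToMap(fit, stripped$mask)
  tumorRaw <- stage("extract", extractTumor(labels, fit@centroids, tumorThreshold))
  tumor <- stage("postprocess", postprocessMask(tumorRaw, config@medianWindow))
  metrics <- if (!is.null(truth))
    stage("evaluate", segMetrics(tumor, truth)) else NULL

  outputs <- character(0)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    outputs <- c(
      noisy = writeGrayImage(noisy, file.path(outDir, "noisy.tif")),
      denoised = writeGrayImage(denoised, file.path(outDir, "denoised.tif")),
      brain_mask = writeMask(stripped$mask, file.path(outDir, "brain_mask.png")),
      labels = writeGrayImage(labelMapToImage(labels),
                              file.path(outDir, "labels.tif")),
      tumor_raw = writeMask(tumorRaw, file.path(outDir, "tumor_raw.png")),
      tumor = writeMask(tumor, file.path(outDir, "tumor_mask.png")))
  }

  manifest <- list(
    config = list(k = config@k, fuzzyIndex = config@fuzzyIndex,
                  sigma2 = config@sigma2, epsilon = config@epsilon,
                  maxIter = config@maxIter, wienerWindow = config@wienerWindow,
                  openRadius = config@openRadius,
                  medianWindow = config@medianWindow, seed = config@seed,
                  noiseVar = noiseVar),
    inputHash = inputHash,
    outputs = as.list(outputs),
    centroids = fit@centroids,
    objectiveTrace = fit@objective,
    nIter = fit@nIter,
    converged = fit@converged,
    metrics = if (is.null(metrics)) NULL else
      list(paper = as.list(metrics@paper), standard = as.list(metrics@standard)),
    seed = config@seed,
    wallTime = proc.time()[["elapsed"]] - t0)
  if (!is.null(outDir))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")

  new("SegRun", config = config, brainMask = stripped$mask,
      tumorMaskRaw = tumorRaw, tumorMask = tumor, labels = labels,
      clustering = fit, metrics = metrics, manifest = manifest)
}

#' Render a label map as a grayscale image
#'
#' Cluster ids are spread over distinct gray levels (outside-mask pixels
#' are black) for writing label maps to disk.
#'
#' @param labels a [LabelMap-class].
#' @return a [GrayImage-class].
#' @export
labelMapToImage <- function(labels) {
  lab <- labels@.Data
  mx <- max(lab)
  img <- array(0, dim(lab))
  if (mx >= 0) img[lab >= 0] <- (lab[lab >= 0] + 1) / (mx + 1)
  GrayImage(img)
}

#' Read a pipeline configuration from a flat key-value file
#'
#' The file is flat YAML, one `key: value` per line, with keys matching
#' the arguments of [segConfig()]; absent keys keep their defaults.
#'
#' @param path config file path.
#' @return a [SegConfig-class].
#' @export
readConfigFile <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(segConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(segConfig, vals)
}
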