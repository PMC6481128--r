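#' @rdname ClusterResult-class
#' @param object,x an object.
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname ClusterResult-class
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' @rdname ClusterResult-class
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))

#' @rdname ClusterResult-class
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))

#' @rdname ClusterResult-class
#' @export
setGeneric("nIter", function(object) standardGeneric("nIter"))

#' @rdname ClusterResult-class
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname BrainPhantom-class
#' @export
setGeneric("tumorMask", function(object) standardGeneric("tumorMask"))

#' @rdname BrainPhantom-class
#' @export
setGeneric("brainMask", function(object) standardGeneric("brainMask"))

#' @rdname BrainPhantom-class
#' @export
setGeneric("grayImage", function(object) standardGeneric("grayImage"))

#' @rdname MetricsReport-class
#' @export
setGeneric("paperMetrics", function(object) standardGeneric("paperMetrics"))

#' @rdname MetricsReport-class
#' @export
setGeneric("standardMetrics", function(object) standardGeneric("standardMetrics"))
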