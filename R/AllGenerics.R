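#' Bin centers of a processed object
#'
#' @param x a [BinMatrix-class], [OplsModel-class] or
#'   [CoefficientLoadings-class].
#' @return numeric vector of ppm bin centers.
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname binCenters
#' @export
setMethod("binCenters", "BinMatrix", function(x)
  SummarizedExperiment::rowData(x)$binCenter)

#' @rdname binCenters
#' @export
setMethod("binCenters", "OplsModel", function(x) x@binCenters)

#' @rdname binCenters
#' @export
setMethod("binCenters", "CoefficientLoadings", function(x) x@binCenters)

#' Samples x bins value matrix
#'
#' The chemometrics-oriented view of a [BinMatrix-class]: one row per
#' sample, one column per retained bin.
#'
#' @param x a [BinMatrix-class].
#' @return numeric matrix, samples x bins.
#' @export
binValues <- function(x) {
  stopifnot(is(x, "BinMatrix"))
  t(SummarizedExperiment::assay(x, "area"))
}

#' Sample metadata of a BinMatrix
#'
#' @param x a [BinMatrix-class].
#' @return data.frame with sampleId, group, timepoint.
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "BinMatrix"))
  as.data.frame(SummarizedExperiment::colData(x))
}

#' Model quality summaries
#'
#' Accessors for the cross-validated predictive fraction Q2, the fitted
#' class-variance fraction R2Y, and the CV-ANOVA p-value of an OPLS-DA
#' model.
#'
#' @param object an [OplsModel-class].
#' @return numeric(1).
#' @export
setGeneric("q2", function(object) standardGeneric("q2"))

#' @rdname q2
#' @export
setMethod("q2", "OplsModel", function(object) object@q2)

#' @rdname q2
#' @export
setGeneric("r2y", function(object) standardGeneric("r2y"))

#' @rdname q2
#' @export
setMethod("r2y", "OplsModel", function(object) object@r2y)

#' @rdname q2
#' @export
setGeneric("cvAnovaP", function(object) standardGeneric("cvAnovaP"))

#' @rdname q2
#' @export
setMethod("cvAnovaP", "OplsModel", function(object) object@cvAnovaP)

#' Predictive and orthogonal scores of an OPLS-DA model
#'
#' @param object an [OplsModel-class].
#' @return `predictiveScores()`: numeric per-sample scores;
#'   `orthoScores()`: matrix with one column per orthogonal component.
#' @export
predictiveScores <- function(object) {
  stopifnot(is(object, "OplsModel"))
  object@predictiveScores
}

#' @rdname predictiveScores
#' @export
orthoScores <- function(object) {
  stopifnot(is(object, "OplsModel"))
  object@orthoScores
}

#' Significant bins of coefficient loadings
#'
#' @param object a [CoefficientLoadings-class].
#' @return integer indices of bins with |r| above the critical value.
#' @export
significantBins <- function(object) {
  stopifnot(is(object, "CoefficientLoadings"))
  object@significantBins
}

#' Underlying igraph of a network object
#'
#' @param object an [Interactome-class] or [RegulationNetwork-class].
#' @return an igraph object.
#' @export
setGeneric("networkGraph", function(object) standardGeneric("networkGraph"))

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "Interactome", function(object) object@graph)

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "RegulationNetwork", function(object) object@graph)

#' Bridge paths and hubs of a regulation network
#'
#' @param object a [RegulationNetwork-class].
#' @return `bridgePaths()`: list of node-id sequences; `hubs()`: ranked
#'   data.frame of nodes by degree.
#' @export
bridgePaths <- function(object) {
  stopifnot(is(object, "RegulationNetwork"))
  object@bridgePaths
}

#' @rdname bridgePaths
#' @export
hubs <- function(object) {
  stopifnot(is(object, "RegulationNetwork"))
  object@hubs
}
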