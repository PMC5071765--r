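## Central S4 containers. BinMatrix rides on SummarizedExperiment (bins are
## rows/features, samples are columns, per Bioconductor convention even
## though chemometrics code works on the transposed samples x bins view).

#' Spectrum: a one-dimensional NMR spectrum
#'
#' A digitized 1-D spectrum on a strictly monotone chemical-shift (ppm)
#' axis, with sample metadata used downstream for class contrasts.
#'
#' @slot ppm numeric, strictly monotone chemical-shift axis (ppm).
#' @slot intensity numeric, nonnegative intensities, same length as `ppm`.
#' @slot sampleId character(1) sample identifier.
#' @slot group character(1) class label (e.g. `"control"`, `"exposed"`).
#' @slot timepoint character(1) exposure time label (e.g. `"24h"`).
#'
#' @export
setClass("Spectrum",
  slots = c(ppm = "numeric", intensity = "numeric", sampleId = "character",
            group = "character", timepoint = "character"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity must have equal length")
  d <- diff(object@ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    msg <- c(msg, "ppm axis must be strictly monotone")
  if (!all(is.finite(object@intensity)))
    msg <- c(msg, "intensities must be finite")
  if (any(object@intensity < 0))
    msg <- c(msg, "intensities must be nonnegative")
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param ppm numeric chemical-shift axis (ppm), strictly monotone.
#' @param intensity nonnegative numeric intensities of equal length.
#' @param sampleId sample identifier.
#' @param group class label.
#' @param timepoint time-point label.
#' @return A [Spectrum-class] object.
#' @examples
#' s <- Spectrum(seq(0, 10, 0.01), rep(1, 1001), "s1", group = "control")
#' @export
Spectrum <- function(ppm, intensity, sampleId, group = NA_character_,
                     timepoint = NA_character_) {
  if (length(ppm) > 1 && ppm[1] > ppm[length(ppm)]) {  # store ascending
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  new("Spectrum", ppm = as.numeric(ppm), intensity = as.numeric(intensity),
      sampleId = as.character(sampleId), group = as.character(group),
      timepoint = as.character(timepoint))
}

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum", object@sampleId,
      sprintf("(%d points, %.3f-%.3f ppm, group=%s, timepoint=%s)\n",
              length(object@ppm), min(object@ppm), max(object@ppm),
              object@group, object@timepoint))
})

#' BinMatrix: processed spectral bin areas
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay
#' (`"area"`) holding bins x samples values, `rowData$binCenter` giving
#' the ppm center of each retained bin, and `colData` carrying
#' `sampleId`, `group` and `timepoint`. Rows corresponding to excluded
#' windows (e.g. residual water) are absent entirely.
#'
#' @export
setClass("BinMatrix", contains = "SummarizedExperiment")

setValidity("BinMatrix", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  if (!"binCenter" %in% colnames(rd))
    msg <- c(msg, "rowData must contain binCenter")
  else if (any(!is.finite(rd$binCenter)))
    msg <- c(msg, "binCenter must be finite")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "timepoint") %in% colnames(cd)))
    msg <- c(msg, "colData must contain group and timepoint")
  if (length(msg)) msg else TRUE
})

#' Construct a BinMatrix
#'
#' @param values samples x bins numeric matrix (rows are samples, in the
#'   orientation produced by binning each spectrum).
#' @param binCenters numeric ppm center per bin (column of `values`).
#' @param sampleData data.frame with one row per sample, containing at
#'   least `group` and `timepoint`; rownames (or a `sampleId` column)
#'   give sample ids.
#' @return A [BinMatrix-class].
#' @export
BinMatrix <- function(values, binCenters, sampleData) {
  values <- as.matrix(values)
  if (ncol(values) != length(binCenters))
    stop("values must have one column per bin center")
  if (nrow(values) != nrow(sampleData))
    stop("sampleData must have one row per sample")
  if (is.null(sampleData$sampleId))
    sampleData$sampleId <- rownames(sampleData) %||% paste0("s", seq_len(nrow(sampleData)))
  a <- t(values)
  rownames(a) <- sprintf("bin_%.4f", binCenters)
  colnames(a) <- sampleData$sampleId
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(area = a),
    rowData = S4Vectors::DataFrame(binCenter = as.numeric(binCenters)),
    colData = S4Vectors::DataFrame(sampleData, row.names = sampleData$sampleId))
  new("BinMatrix", se)
}

setMethod("show", "BinMatrix", function(object) {
  cat(sprintf("BinMatrix: %d samples x %d bins\n", ncol(object), nrow(object)))
  cat("  groups:", paste(unique(object$group), collapse = ", "), "\n")
  cat("  bin centers:", sprintf("%.4f..%.4f ppm\n",
      min(binCenters(object)), max(binCenters(object))))
})

#' PlsModel: NIPALS partial least squares discriminant model
#'
#' @slot scores n x a matrix of component scores.
#' @slot weights p x a matrix of (unit-norm) weight vectors.
#' @slot loadings p x a matrix of X loadings.
#' @slot yLoadings numeric y loadings per component.
#' @slot xMeans,yMean centering constants.
#' @slot r2y numeric(1) fraction of class variance explained.
#' @slot y numeric class coding (+1/-1) used in the fit.
#' @export
setClass("PlsModel",
  slots = c(scores = "matrix", weights = "matrix", loadings = "matrix",
            yLoadings = "numeric", xMeans = "numeric", yMean = "numeric",
            r2y = "numeric", y = "numeric"))

setMethod("show", "PlsModel", function(object) {
  cat(sprintf("PlsModel: %d component(s), n = %d, R2Y = %.3f\n",
              ncol(object@scores), nrow(object@scores), object@r2y))
})

#' OplsModel: orthogonal projections to latent structures (OPLS-DA)
#'
#' One predictive component plus `nOrtho` orthogonal components removed
#' beforehand. Predictive and orthogonal scores are mutually orthogonal.
#' The predictive score sign is fixed so that the exposed (second) class
#' has positive mean score, making positive loadings correspond to
#' variables elevated under exposure.
#'
#' @slot predictiveScores numeric per-sample scores t.
#' @slot predictiveWeights,predictiveLoadings numeric per-bin w and p.
#' @slot yLoading numeric(1) regression of y on t.
#' @slot orthoScores,orthoWeights,orthoLoadings matrices, one column per
#'   orthogonal component (zero columns when `nOrtho = 0`).
#' @slot nOrtho integer(1) number of orthogonal components.
#' @slot q2 numeric(1) cross-validated predictive fraction (may be NA).
#' @slot r2y numeric(1) fitted class-variance fraction.
#' @slot cvAnovaP numeric(1) CV-ANOVA p-value (may be NA).
#' @slot xMeans,yMean centering constants.
#' @slot y numeric class coding used (+1 exposed, -1 control).
#' @slot groups character class labels in coding order (control, exposed).
#' @slot binCenters numeric ppm per variable (NA-free when known).
#' @export
setClass("OplsModel",
  slots = c(predictiveScores = "numeric", predictiveWeights = "numeric",
            predictiveLoadings = "numeric", yLoading = "numeric",
            orthoScores = "matrix", orthoWeights = "matrix",
            orthoLoadings = "matrix", nOrtho = "integer",
            q2 = "numeric", r2y = "numeric", cvAnovaP = "numeric",
            xMeans = "numeric", yMean = "numeric", y = "numeric",
            groups = "character", binCenters = "numeric"))

setValidity("OplsModel", function(object) {
  msg <- character()
  t <- object@predictiveScores
  To <- object@orthoScores
  if (ncol(To) != object@nOrtho)
    msg <- c(msg, "orthoScores must have nOrtho columns")
  if (object@nOrtho > 0 && sum(t^2) > 0) {
    for (j in seq_len(ncol(To))) {
      num <- abs(sum(t * To[, j]))
      den <- sqrt(sum(t^2) * sum(To[, j]^2))
      if (den > 0 && num / den > 1e-8)
        msg <- c(msg, "predictive and orthogonal scores must be orthogonal")
    }
  }
  if (!is.na(object@q2) && !is.na(object@r2y) &&
      object@q2 > object@r2y + 1e-8)
    msg <- c(msg, "q2 must not exceed r2y")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OplsModel", function(object) {
  cat(sprintf(
    "OplsModel: 1 predictive + %d orthogonal component(s), n = %d\n",
    object@nOrtho, length(object@predictiveScores)))
  cat(sprintf("  R2Y = %.3f, Q2 = %s, CV-ANOVA p = %s\n", object@r2y,
              formatC(object@q2, digits = 3, format = "f"),
              formatC(object@cvAnovaP, digits = 4, format = "g")))
  cat("  contrast:", paste(object@groups, collapse = " vs "), "\n")
})

#' CoefficientLoadings: correlation-coded loadings with significance
#'
#' Per-bin Pearson correlation `r` between each (processed) spectral
#' variable and the predictive score vector, with the critical value
#' `rCrit` at level `alpha` marking statistically significant bins.
#'
#' @slot r numeric per-bin correlation in \[-1, 1\] (0 for flat bins).
#' @slot rCrit numeric(1) critical |r|.
#' @slot alpha numeric(1) significance level.
#' @slot significantBins integer indices with |r| > rCrit.
#' @slot binCenters numeric ppm per bin.
#' @slot zeroVarianceBins integer indices of flat bins (r forced to 0).
#' @export
setClass("CoefficientLoadings",
  slots = c(r = "numeric", rCrit = "numeric", alpha = "numeric",
            significantBins = "integer", binCenters = "numeric",
            zeroVarianceBins = "integer"))

setValidity("CoefficientLoadings", function(object) {
  msg <- character()
  if (any(abs(object@r) > 1 + 1e-12)) msg <- c(msg, "|r| must be <= 1")
  expect <- which(abs(object@r) > object@rCrit)
  if (!identical(as.integer(expect), object@significantBins))
    msg <- c(msg, "significantBins must equal { bins with |r| > rCrit }")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoefficientLoadings", function(object) {
  cat(sprintf(
    "CoefficientLoadings: %d bins, |r| > %.3f (alpha = %g): %d significant\n",
    length(object@r), object@rCrit, object@alpha,
    length(object@significantBins)))
})

#' Interactome: scored undirected interaction graph
#'
#' Wraps an undirected simple igraph whose vertices carry a `type`
#' attribute (`"protein"`, `"pathway"` or `"metabolite"`) and whose
#' edges carry a `score` on the STRING 0-1000 combined-score convention.
#' Only edges at or above `scoreCutoff` are retained.
#'
#' @slot graph an igraph object.
#' @slot scoreCutoff numeric(1) combined-score cutoff applied at build time.
#' @export
setClass("Interactome", slots = c(graph = "ANY", scoreCutoff = "numeric"))

setValidity("Interactome", function(object) {
  g <- object@graph
  msg <- character()
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "graph must have no self-loops")
  if (any(igraph::which_multiple(g))) msg <- c(msg, "graph must be simple")
  if (igraph::ecount(g) > 0) {
    sc <- igraph::E(g)$score
    if (is.null(sc) || any(sc < 0 | sc > 1000))
      msg <- c(msg, "edge scores must lie in [0, 1000]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "Interactome", function(object) {
  g <- object@graph
  tt <- table(igraph::V(g)$type)
  cat(sprintf("Interactome: %d nodes (%s), %d edges (score >= %g)\n",
              igraph::vcount(g),
              paste(sprintf("%s: %d", names(tt), tt), collapse = ", "),
              igraph::ecount(g), object@scoreCutoff))
})

#' RegulationNetwork: core multi-omics regulation subnetwork
#'
#' The connected core of differentially expressed proteins plus the
#' "extended" (non-differential) nodes lying on retained bridge paths.
#' Edges are tagged `"direct"` (present in the interactome) or
#' `"indirect"` (inferred from a stored bridge path between two network
#' nodes). Hubs are ranked by degree.
#'
#' @slot graph igraph with vertex attributes `type`, `extended` and
#'   per-time-point fold changes, and edge attribute `interaction`.
#' @slot bridgePaths list of character vectors (node sequences).
#' @slot hubs data.frame (node, degree) ranked.
#' @slot componentSizes integer sizes of all candidate components.
#' @slot unplaced character ids of differential proteins without a node.
#' @export
setClass("RegulationNetwork",
  slots = c(graph = "ANY", bridgePaths = "list", hubs = "data.frame",
            componentSizes = "integer", unplaced = "character"))

setValidity("RegulationNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  msg <- character()
  nodes <- igraph::V(g)$name
  for (p in object@bridgePaths)
    if (length(p) && !all(p %in% nodes))
      msg <- c(msg, "bridge path references a node absent from the graph")
  if (igraph::ecount(g) > 0) {
    ind <- igraph::E(g)$interaction == "indirect"
    if (any(ind)) {
      ends <- igraph::ends(g, igraph::E(g)[ind])
      keyP <- vapply(object@bridgePaths, function(p)
        paste(sort(c(p[1], p[length(p)])), collapse = "|"), character(1))
      keyE <- apply(ends, 1, function(e) paste(sort(e), collapse = "|"))
      if (!all(keyE %in% keyP))
        msg <- c(msg, "every indirect edge must correspond to a stored bridge path")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegulationNetwork", function(object) {
  g <- object@graph
  cat(sprintf(
    "RegulationNetwork: %d nodes, %d edges (%d indirect), %d bridge path(s)\n",
    igraph::vcount(g), igraph::ecount(g),
    if (igraph::ecount(g)) sum(igraph::E(g)$interaction == "indirect") else 0L,
    length(object@bridgePaths)))
  if (nrow(object@hubs))
    cat("  top hubs:", paste(head(object@hubs$node, 3), collapse = ", "), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
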