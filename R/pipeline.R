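#' Pipeline run configuration
#'
#' Collects every stage's parameters. Inputs are either simulated from
#' a [SyntheticDesign-class] (the default) or read from files written
#' in the formats of [exportSyntheticData()] (`inputDir`).
#'
#' @param design a [SyntheticDesign-class] (used when `inputDir` is
#'   NULL).
#' @param inputDir directory of input files (spectra/, proteins.tsv,
#'   homology_hits.tsv, annotations.gmt, interactome_edges.tsv,
#'   interactome_nodes.tsv).
#' @param outDir optional output directory; when given, every stage
#'   writes its files there and the report goes to `report.json`.
#' @param processing a [processingParams()] object.
#' @param nOrtho orthogonal components for OPLS-DA.
#' @param nFolds cross-validation folds.
#' @param alpha significance level for coefficient loadings.
#' @param dep a [depCriteria()] object.
#' @param homology a [homologyCriteria()] object.
#' @param scoreCutoff interactome combined-score cutoff.
#' @param maxLen maximum bridge-path length in hops.
#' @param seed integer seed recorded in the report; overrides the
#'   design seed when given.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(design = syntheticDesign(), inputDir = NULL,
                      outDir = NULL, processing = processingParams(),
                      nOrtho = 1, nFolds = 5, alpha = 0.05,
                      dep = depCriteria(), homology = homologyCriteria(),
                      scoreCutoff = 400, maxLen = 4, seed = NULL) {
  if (!is.null(seed) && !is.null(design))
    design@seed <- as.integer(seed)
  if (!is.null(inputDir)) {
    need <- c("spectra", "proteins.tsv", "homology_hits.tsv",
              "annotations.gmt", "interactome_edges.tsv")
    missing <- need[!file.exists(file.path(inputDir, need))]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  structure(list(design = design, inputDir = inputDir, outDir = outDir,
                 processing = processing, nOrtho = nOrtho,
                 nFolds = nFolds, alpha = alpha, dep = dep,
                 homology = homology, scoreCutoff = scoreCutoff,
                 maxLen = maxLen,
                 seed = if (!is.null(design)) design@seed else seed),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Scalar fields of the YAML map onto the arguments of [runConfig()];
#' a `design:` block maps onto [syntheticDesign()] (with `effectMap` as
#' a named map of metabolite to signed effect size).
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  design <- if (!is.null(y$design)) {
    da <- y$design
    if (!is.null(da$effectMap))
      da$effectMap <- vapply(da$effectMap, as.numeric, numeric(1))
    do.call(syntheticDesign, da)
  } else syntheticDesign()
  args <- y[setdiff(names(y), "design")]
  if (!is.null(args$processing))
    args$processing <- do.call(processingParams, args$processing)
  if (!is.null(args$dep)) args$dep <- do.call(depCriteria, args$dep)
  if (!is.null(args$homology))
    args$homology <- do.call(homologyCriteria, args$homology)
  do.call(runConfig, c(list(design = design), args))
}

#' Export OPLS-DA model results to files
#'
#' Writes the model summary (JSON: q2, r2y, cvAnovaP, nOrtho), scores
#' TSV, loadings TSV (bin center, loading, r, significance flag) and
#' the metabolite-call TSV.
#'
#' @param model an [OplsModel-class].
#' @param loadings a [CoefficientLoadings-class].
#' @param calls metabolite-call data.frame.
#' @param dir output directory.
#' @return invisible character vector of paths.
#' @export
exportOplsResults <- function(model, loadings, calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summaryPath <- file.path(dir, "opls_summary.json")
  jsonlite::write_json(
    list(q2 = model@q2, r2y = model@r2y, cvAnovaP = model@cvAnovaP,
         nOrtho = model@nOrtho, contrast = model@groups),
    summaryPath, auto_unbox = TRUE, digits = NA, na = "null")
  scoresPath <- file.path(dir, "opls_scores.tsv")
  sc <- data.frame(predictive = model@predictiveScores)
  for (j in seq_len(model@nOrtho)) sc[[paste0("ortho", j)]] <- model@orthoScores[, j]
  write.table(sc, scoresPath, sep = "\t", row.names = FALSE, quote = FALSE)
  loadPath <- file.path(dir, "opls_loadings.tsv")
  write.table(data.frame(
    binCenter = loadings@binCenters, loading = model@predictiveLoadings,
    r = loadings@r,
    significant = seq_along(loadings@r) %in% loadings@significantBins),
    loadPath, sep = "\t", row.names = FALSE, quote = FALSE)
  callPath <- file.path(dir, "metabolite_calls.tsv")
  write.table(calls, callPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(summaryPath, scoresPath, loadPath, callPath))
}

#' Run the full multi-omics pipeline
#'
#' Stages, in order: spectral processing to a bin matrix; OPLS-DA with
#' venetian-blind Q2, CV-ANOVA and metabolite calling; iTRAQ
#' quantification filtering, fold changes and per-time-point
#' differential calls with their intersection; best-homolog mapping and
#' term enrichment (background: all mapped quantified proteins); and
#' interactome bridging to the core regulation network with ranked
#' hubs. Deterministic given the seed. Any stage failure aborts with
#' the stage name.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @return list with `report` (the run summary also written to
#'   `report.json` when `outDir` is set), `truth` (ground truth when
#'   inputs were simulated), and the main stage objects (`binMatrix`,
#'   `model`, `loadings`, `calls`, `deps`, `venn`, `mapping`,
#'   `enrichment`, `network`).
#' @examples
#' \donttest{
#' res <- runPipeline(runConfig(design = syntheticDesign(seed = 11)))
#' res$report$q2
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  simulated <- is.null(config$inputDir)
  truth <- list()

  ## inputs
  inputs <- stage("inputs", {
    if (simulated) {
      sp <- simulateSpectra(config$design)
      it <- simulateItraqTable(config$design)
      hits <- simulateHitTable(config$design)
      ann <- simulateAnnotations(config$design)
      net <- simulateInteractome(config$design, cutoff = config$scoreCutoff)
      truth <- list(effectMap = config$design@effectMap,
                     depIds = it$truth$depIds,
                     depDirection = it$truth$direction,
                     plantedPaths = net$plantedPaths,
                     hubs = net$truth$hubs, module = net$truth$module)
      list(spectra = sp, proteins = it$table, hits = hits, ann = ann,
           interactome = net$interactome)
    } else {
      d <- config$inputDir
      list(spectra = readSpectra(file.path(d, "spectra")),
           proteins = readProteinTable(file.path(d, "proteins.tsv")),
           hits = read.table(file.path(d, "homology_hits.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE),
           ann = readGmt(file.path(d, "annotations.gmt")),
           interactome = readEdgeList(
             file.path(d, "interactome_edges.tsv"),
             cutoff = config$scoreCutoff,
             nodeTypes = if (file.exists(file.path(d, "interactome_nodes.tsv")))
               read.table(file.path(d, "interactome_nodes.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE) else NULL))
    }
  })

  ## nmr -> chemometrics
  bm <- stage("nmr", buildBinMatrix(inputs$spectra, config$processing))
  model <- stage("chemometrics",
                 fitOplsda(bm, nOrtho = config$nOrtho, cv = TRUE,
                           nFolds = config$nFolds))
  loadings <- stage("chemometrics",
                    coefficientLoadings(model, bm, alpha = config$alpha))
  calls <- stage("chemometrics", callSignificantMetabolites(loadings))

  ## proteomics
  deps <- stage("proteomics", {
    filt <- quantFilter(inputs$proteins, config$dep)
    dep <- computeFoldChanges(filt, config$dep)
    filterDeps(dep, config$dep)
  })
  venn <- stage("proteomics", if (length(deps$sets) >= 2)
    intersectTimepoints(deps$sets) else
      list(common = unlist(deps$sets), regions = integer()))

  ## mapping & enrichment
  mapping <- stage("mapping", selectBestHomolog(inputs$hits, config$homology))
  allDeps <- unique(unlist(deps$sets))
  background <- unique(mapping$subject[!is.na(mapping$subject)])
  depHomologs <- unique(stats::na.omit(
    mapping$subject[match(allDeps, mapping$query)]))
  enrichment <- stage("enrichment", if (length(depHomologs))
    enrichTerms(depHomologs, inputs$ann, background) else
      enrichTerms(character(), inputs$ann, background))

  ## network
  network <- stage("network", {
    depTab <- deps$table[deps$table$is_dep, , drop = FALSE]
    md <- mapDeps(inputs$interactome, depTab, mapping)
    g <- md$interactome@graph
    depNodes <- igraph::V(g)$name[igraph::V(g)$dep]
    targets <- igraph::V(g)$name[igraph::V(g)$type %in%
                                   c("pathway", "metabolite")]
    bridges <- if (length(depNodes) && length(targets))
      shortestPathsBridge(md$interactome, depNodes, targets,
                          maxLen = config$maxLen) else NULL
    extractCoreSubnetwork(md$interactome, depNodes, bridges,
                          unplaced = md$unplaced)
  })

  hubTab <- hubs(network)
  report <- list(
    seed = config$seed,
    q2 = model@q2, r2y = model@r2y, cvAnovaP = model@cvAnovaP,
    nOrtho = model@nOrtho,
    metaboliteCalls = calls,
    depCounts = vapply(deps$sets, length, integer(1)),
    commonDeps = length(venn$common),
    topTerms = head(enrichment, 5),
    coreNetworkSize = as.integer(igraph::vcount(network@graph)),
    nBridgePaths = length(bridgePaths(network)),
    hubs = head(hubTab, 5))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    exportOplsResults(model, loadings, calls,
                      file.path(config$outDir, "chemometrics"))
    for (tp in names(deps$sets))
      writeLines(deps$sets[[tp]],
                 file.path(config$outDir, sprintf("deps_%s.txt", tp)))
    jsonlite::write_json(venn, file.path(config$outDir, "venn.json"),
                         auto_unbox = TRUE, digits = NA)
    write.table(enrichment, file.path(config$outDir, "enrichment.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    exportNetwork(network, config$outDir)
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows", pretty = TRUE)
  }
  list(report = report, truth = truth, binMatrix = bm, model = model,
       loadings = loadings, calls = calls, deps = deps, venn = venn,
       mapping = mapping, enrichment = enrichment, network = network)
}
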