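#' Write / read spectra as two-column CSV plus a sample sheet
#'
#' Each spectrum goes to `<sampleId>.csv` (columns ppm, intensity); the
#' sample sheet `samples.tsv` lists sample id, group and time point in
#' acquisition order (the order venetian-blind folds follow).
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param dir directory (created if needed).
#' @return invisible path of the sample sheet.
#' @export
writeSpectra <- function(spectra, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    sampleId = vapply(spectra, function(s) s@sampleId, character(1)),
    group = vapply(spectra, function(s) s@group, character(1)),
    timepoint = vapply(spectra, function(s) s@timepoint, character(1)))
  for (s in spectra)
    write.table(data.frame(ppm = s@ppm, intensity = s@intensity),
                file.path(dir, paste0(s@sampleId, ".csv")),
                sep = ",", row.names = FALSE, quote = FALSE)
  sheet <- file.path(dir, "samples.tsv")
  write.table(meta, sheet, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(sheet)
}

#' @rdname writeSpectra
#' @param dir directory containing `samples.tsv` and per-sample CSVs.
#' @return `readSpectra()`: named list of [Spectrum-class] objects in
#'   sample-sheet order.
#' @export
readSpectra <- function(dir) {
  sheet <- read.table(file.path(dir, "samples.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  spectra <- lapply(seq_len(nrow(sheet)), function(i) {
    tab <- read.table(file.path(dir, paste0(sheet$sampleId[i], ".csv")),
                      header = TRUE, sep = ",")
    Spectrum(tab$ppm, tab$intensity, sheet$sampleId[i],
             group = sheet$group[i], timepoint = sheet$timepoint[i])
  })
  names(spectra) <- sheet$sampleId
  spectra
}

#' Write / read a BinMatrix as TSV
#'
#' Layout: first columns sample id, group, timepoint, then one column
#' per bin named by its ppm center.
#'
#' @param bm a [BinMatrix-class].
#' @param path output file.
#' @export
writeBinMatrix <- function(bm, path) {
  stopifnot(is(bm, "BinMatrix"))
  vals <- binValues(bm)
  colnames(vals) <- sprintf("%.10g", binCenters(bm))
  out <- cbind(sampleInfo(bm)[, c("sampleId", "group", "timepoint")], vals)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBinMatrix
#' @return `readBinMatrix()`: a [BinMatrix-class].
#' @export
readBinMatrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  meta <- tab[, c("sampleId", "group", "timepoint")]
  vals <- as.matrix(tab[, -(1:3), drop = FALSE])
  BinMatrix(vals, as.numeric(colnames(vals)), meta)
}

#' Write / read an iTRAQ protein quantification table (TSV)
#'
#' @param tab protein quantification data.frame.
#' @param path file path.
#' @export
writeProteinTable <- function(tab, path) {
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeProteinTable
#' @export
readProteinTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Export a full synthetic data set to plain-text files
#'
#' Writes everything the pipeline consumes: per-sample spectra CSVs
#' with a sample sheet, the protein quantification TSV, the homology
#' hit TSV, annotations as GMT, the interactome as a 3-column edge TSV
#' with a node-type TSV, and the ground truth as JSON.
#'
#' @param design a [SyntheticDesign-class].
#' @param dir output directory.
#' @return invisible named character vector of paths.
#' @export
exportSyntheticData <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- simulateSpectra(design)
  writeSpectra(sp, file.path(dir, "spectra"))
  it <- simulateItraqTable(design)
  writeProteinTable(it$table, file.path(dir, "proteins.tsv"))
  hits <- simulateHitTable(design)
  write.table(hits, file.path(dir, "homology_hits.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  ann <- simulateAnnotations(design)
  writeGmt(ann, file.path(dir, "annotations.gmt"))
  net <- simulateInteractome(design)
  write.table(net$edges, file.path(dir, "interactome_edges.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(net$nodeTypes, file.path(dir, "interactome_nodes.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- list(
    seed = design@seed,
    effectMap = as.list(design@effectMap),
    depIds = it$truth$depIds,
    depDirection = as.list(it$truth$direction),
    plantedPaths = design@plantedPaths,
    plantedHubs = design@plantedHubs,
    plantedModule = design@plantedModule)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(spectra = file.path(dir, "spectra"),
              proteins = file.path(dir, "proteins.tsv"),
              hits = file.path(dir, "homology_hits.tsv"),
              annotations = file.path(dir, "annotations.gmt"),
              edges = file.path(dir, "interactome_edges.tsv"),
              nodes = file.path(dir, "interactome_nodes.tsv"),
              truth = file.path(dir, "ground_truth.json")))
}
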