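#' Differential-protein calling criteria
#'
#' Standard iTRAQ duplicate-design rules: fold change above 1.50 or
#' below 0.67 in any duplicate, at least two peptides, detection in
#' both replicates, and global FDR below 1%.
#'
#' @param upThreshold fold-change threshold for up-regulation (strict).
#' @param downThreshold fold-change threshold for down-regulation
#'   (strict).
#' @param minPeptides minimum peptide count for quantification.
#' @param requireBothReplicates require detection in both replicates.
#' @param fdrMax maximum global FDR.
#' @param replicateRule `"any"` (either replicate ratio suffices, the
#'   default reading of the duplicate design) or `"both"`.
#' @param foldChangeMean `"arithmetic"` (default; replicate ratios are
#'   averaged) or `"geometric"`.
#' @return list of class `DepCriteria`.
#' @export
depCriteria <- function(upThreshold = 1.50, downThreshold = 0.67,
                        minPeptides = 2, requireBothReplicates = TRUE,
                        fdrMax = 0.01, replicateRule = c("any", "both"),
                        foldChangeMean = c("arithmetic", "geometric")) {
  if (!(upThreshold > 1 && 1 > downThreshold && downThreshold > 0))
    stop("need upThreshold > 1 > downThreshold > 0")
  structure(list(upThreshold = upThreshold, downThreshold = downThreshold,
                 minPeptides = minPeptides,
                 requireBothReplicates = requireBothReplicates,
                 fdrMax = fdrMax, replicateRule = match.arg(replicateRule),
                 foldChangeMean = match.arg(foldChangeMean)),
            class = "DepCriteria")
}

ratioColumns <- function(tab) {
  cols <- grep("^ratio_.+_rep[0-9]+$", names(tab), value = TRUE)
  if (!length(cols)) stop("no ratio_<timepoint>_rep<k> columns found")
  tp <- sub("^ratio_(.+)_rep[0-9]+$", "\\1", cols)
  split(cols, factor(tp, levels = unique(tp)))
}

#' Quantification filter for an iTRAQ protein table
#'
#' Keeps proteins with at least `minPeptides` peptides, detected in
#' both replicates (when required), and with global FDR at or below
#' `fdrMax` where an `fdr` column is provided. Proteins with missing
#' peptide counts are excluded with a warning.
#'
#' @param tab protein quantification data.frame (columns `id`,
#'   `peptides`, `det_rep1`, `det_rep2`, optional `fdr`, and
#'   `ratio_<tp>_rep<k>` ratio columns).
#' @param criteria a [depCriteria()] object.
#' @return the filtered data.frame.
#' @examples
#' it <- simulateItraqTable(syntheticDesign(seed = 2))
#' nrow(quantFilter(it$table))
#' @export
quantFilter <- function(tab, criteria = depCriteria()) {
  if (!"peptides" %in% names(tab)) stop("table must contain peptides")
  missing <- is.na(tab$peptides)
  if (any(missing))
    warning(sum(missing), " protein(s) with missing peptide count excluded")
  keep <- !missing & tab$peptides >= criteria$minPeptides
  if (criteria$requireBothReplicates) {
    if (!all(c("det_rep1", "det_rep2") %in% names(tab)))
      stop("table must contain det_rep1 and det_rep2")
    keep <- keep & tab$det_rep1 & tab$det_rep2
  }
  if (!is.null(tab$fdr))
    keep <- keep & (is.na(tab$fdr) | tab$fdr <= criteria$fdrMax)
  tab[keep, , drop = FALSE]
}

#' Compute per-time-point fold changes from replicate ratios
#'
#' Fold change is the mean of the two replicate treated/control ratios
#' at each time point (arithmetic by default). When only one replicate
#' ratio is present the single ratio is used and flagged.
#'
#' @param tab filtered protein table with `ratio_<tp>_rep<k>` columns.
#' @param criteria a [depCriteria()] object (selects the mean type).
#' @return long-format data.frame (`DepTable`): id, timepoint, rep1,
#'   rep2, fold_change, direction, single_replicate.
#' @examples
#' tab <- data.frame(id = "p1", peptides = 3, det_rep1 = TRUE,
#'                   det_rep2 = TRUE, ratio_24h_rep1 = 2,
#'                   ratio_24h_rep2 = 3)
#' computeFoldChanges(tab)$fold_change  # 2.5
#' @export
computeFoldChanges <- function(tab, criteria = depCriteria()) {
  byTp <- ratioColumns(tab)
  out <- NULL
  for (tp in names(byTp)) {
    cols <- byTp[[tp]]
    r1 <- tab[[cols[1]]]
    r2 <- if (length(cols) > 1) tab[[cols[2]]] else rep(NA_real_, nrow(tab))
    bad <- which((!is.na(r1) & r1 <= 0) | (!is.na(r2) & r2 <= 0))
    if (length(bad))
      stop("nonpositive ratio for protein(s): ",
           paste(tab$id[bad], collapse = ", "))
    single <- is.na(r1) | is.na(r2)
    fc <- if (criteria$foldChangeMean == "arithmetic")
      rowMeans(cbind(r1, r2), na.rm = TRUE)
    else exp(rowMeans(log(cbind(r1, r2)), na.rm = TRUE))
    out <- rbind(out, data.frame(
      id = tab$id, timepoint = tp, rep1 = r1, rep2 = r2,
      fold_change = fc,
      direction = ifelse(fc > 1, "up", ifelse(fc < 1, "down", "unchanged")),
      single_replicate = single))
  }
  out[!is.na(out$fold_change), , drop = FALSE]
}

## significance of a single ratio against the thresholds: +1 up, -1 down,
## 0 neither, NA missing
ratioCall <- function(r, criteria) {
  ifelse(is.na(r), NA_real_,
         ifelse(r > criteria$upThreshold, 1,
                ifelse(r < criteria$downThreshold, -1, 0)))
}

#' Call differentially expressed proteins per time point
#'
#' Under the `"any"` replicate rule a protein is differential at a time
#' point when either replicate ratio exceeds the up threshold or falls
#' below the down threshold (strict inequalities); under `"both"`, both
#' replicates must. Proteins whose two replicates disagree in direction
#' (one up, one down) are excluded and logged as discordant. When a row
#' carries no replicate ratios (fixture tables with only mean fold
#' changes), the fold change itself is tested against the thresholds.
#'
#' @param dep a `DepTable` from [computeFoldChanges()] (or any
#'   data.frame with id, timepoint, fold_change and optionally
#'   rep1/rep2).
#' @param criteria a [depCriteria()] object.
#' @return list with `sets` (named list of DEP id vectors per time
#'   point), `table` (dep rows with is_dep and direction), and
#'   `discordant` (excluded ids per time point).
#' @export
filterDeps <- function(dep, criteria = depCriteria()) {
  stopifnot(all(c("id", "timepoint", "fold_change") %in% names(dep)))
  r1 <- if ("rep1" %in% names(dep)) dep$rep1 else rep(NA_real_, nrow(dep))
  r2 <- if ("rep2" %in% names(dep)) dep$rep2 else rep(NA_real_, nrow(dep))
  noReps <- is.na(r1) & is.na(r2)
  r1[noReps] <- dep$fold_change[noReps]
  c1 <- ratioCall(r1, criteria)
  c2 <- ratioCall(r2, criteria)
  discord <- !is.na(c1) & !is.na(c2) & c1 * c2 < 0
  hit <- switch(criteria$replicateRule,
    any = pmax(abs(c1), abs(c2), na.rm = TRUE) == 1,
    both = !is.na(c1) & !is.na(c2) & abs(c1) == 1 & abs(c2) == 1 &
      c1 == c2)
  isDep <- !is.na(hit) & hit & !discord
  tab <- dep
  tab$is_dep <- isDep
  tab$direction <- ifelse(dep$fold_change > 1, "up", "down")
  tps <- unique(dep$timepoint)
  sets <- lapply(setNames(tps, tps),
                 function(tp) dep$id[isDep & dep$timepoint == tp])
  disc <- lapply(setNames(tps, tps),
                 function(tp) dep$id[discord & dep$timepoint == tp])
  if (any(discord))
    message(sum(discord), " discordant replicate call(s) excluded")
  list(sets = sets, table = tab, discordant = disc)
}

#' Intersect per-time-point DEP sets
#'
#' Returns the k-way common set and the counts of every Venn region
#' (ids belonging to exactly a given combination of sets).
#'
#' @param sets named list (>= 2) of id vectors.
#' @return list with `common` (ids in all sets) and `regions` (named
#'   integer vector of exclusive Venn region counts, names like
#'   `"24h&48h"`).
#' @examples
#' intersectTimepoints(list(a = c("x", "y", "z"), b = c("y", "z"),
#'                          c = c("y", "z", "w")))
#' @export
intersectTimepoints <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  all <- unique(unlist(sets))
  member <- vapply(sets, function(s) all %in% s, logical(length(all)))
  if (length(all) == 1) member <- matrix(member, nrow = 1)
  combos <- apply(member, 1, function(m)
    paste(names(sets)[m], collapse = "&"))
  regions <- integer(0)
  # enumerate all nonempty combinations so absent regions count 0
  for (k in seq_along(sets)) {
    for (cmb in utils::combn(names(sets), k, simplify = FALSE)) {
      nm <- paste(cmb, collapse = "&")
      regions[nm] <- sum(combos == nm)
    }
  }
  list(common = Reduce(intersect, sets), regions = regions)
}

#' Persistent large-fold-change proteins of the cadmium gill study
#'
#' The summary table of stress-response, antioxidant, calcium-binding,
#' sulfur-metabolism, structural and metabolic proteins with large fold
#' changes at all three exposure time points, transcribed from the
#' published study and shipped as a plain-text fixture. Missing entries
#' are NA.
#'
#' @return data.frame: biological_function, description, evalue,
#'   accession, fc_24h, fc_48h, fc_96h.
#' @examples
#' head(cdFoldChangeTable())
#' @export
cdFoldChangeTable <- function() {
  path <- system.file("extdata", "table1_cd_foldchanges.tsv",
                      package = "cdomics")
  read.table(path, header = TRUE, sep = "\t", quote = "",
             na.strings = "NA", stringsAsFactors = FALSE)
}
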