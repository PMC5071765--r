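## Synthetic-data generators with known ground truth. These define the
## study conditions every downstream stage is validated against: a
## two-group NMR contrast with planted metabolite shifts, a duplicate
## replicate iTRAQ ratio table with planted differential proteins, and a
## scored interactome with planted bridge paths and a planted
## differential module.

#' Default planted metabolite effect map
#'
#' Signed effect sizes (in within-group standard-deviation units) for
#' the nine key gill biomarkers of cadmium exposure: elevated alanine,
#' glutamine, succinate, glutamate and glycogen; depleted leucine,
#' aspartate, proline and acetoacetate.
#'
#' @param effect absolute effect size in within-group SD units.
#' @return named numeric vector.
#' @export
defaultEffectMap <- function(effect = 2) {
  c(alanine = effect, glutamine = effect, succinate = effect,
    glutamate = effect, glycogen = effect,
    leucine = -effect, aspartate = -effect, proline = -effect,
    acetoacetate = -effect)
}

#' SyntheticDesign: ground-truth design for simulated data
#'
#' Collects every parameter of the synthetic study: sample sizes, the
#' planted metabolite effect map, noise levels, iTRAQ table dimensions
#' and planted fold changes, and interactome size with planted bridge
#' paths, hubs and differential module.
#'
#' @slot nPerGroup samples per group (control / exposed).
#' @slot effectMap named numeric, metabolite -> signed effect size in
#'   within-group SD units.
#' @slot noiseSd additive spectral noise SD (intensity units).
#' @slot concCv within-group coefficient of variation of (log-normal)
#'   metabolite concentrations.
#' @slot effectScale nominal log-scale within-group SD used to convert
#'   effect sizes to concentration shifts (fixed at the default
#'   `concCv` so that effects are in within-group SD units at the
#'   defaults and survive the noise-free case).
#' @slot baselineCv sample-to-sample coefficient of variation of the
#'   broad-baseline amplitude.
#' @slot seed integer RNG seed.
#' @slot timepoint exposure time label for the simulated contrast.
#' @slot nProteins number of quantified proteins.
#' @slot depFraction fraction of proteins with planted differential
#'   expression.
#' @slot plantedFcRange numeric(2), fold-change magnitude range (> 1).
#' @slot ratioNoiseSd log-scale SD of replicate ratio noise.
#' @slot nNodes,nEdges interactome size (random edges, before planted
#'   edges are added).
#' @slot plantedPaths list of node-id sequences inserted as high-score
#'   paths.
#' @slot plantedHubs node ids planted as hubs of the differential module.
#' @slot plantedModule node ids of the planted differential module.
#' @export
setClass("SyntheticDesign",
  slots = c(nPerGroup = "integer", effectMap = "numeric",
            noiseSd = "numeric", concCv = "numeric", effectScale = "numeric",
            baselineCv = "numeric",
            seed = "integer", timepoint = "character",
            nProteins = "integer", depFraction = "numeric",
            plantedFcRange = "numeric", ratioNoiseSd = "numeric",
            nNodes = "integer", nEdges = "integer",
            plantedPaths = "list", plantedHubs = "character",
            plantedModule = "character"))

setValidity("SyntheticDesign", function(object) {
  msg <- character()
  if (object@nPerGroup < 3L) msg <- c(msg, "nPerGroup must be >= 3")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (object@concCv < 0) msg <- c(msg, "concCv must be nonnegative")
  if (object@baselineCv < 0) msg <- c(msg, "baselineCv must be nonnegative")
  if (object@depFraction < 0 || object@depFraction > 1)
    msg <- c(msg, "depFraction must lie in [0, 1]")
  if (length(object@plantedFcRange) != 2 || any(object@plantedFcRange <= 1))
    msg <- c(msg, "planted fold-change magnitudes must be > 1")
  maxE <- object@nNodes * (object@nNodes - 1) / 2
  if (object@nEdges > maxE)
    msg <- c(msg, "nEdges must not exceed nNodes*(nNodes-1)/2")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic study design
#'
#' Defaults emulate the study conditions the pipeline targets: two
#' groups of 10 samples, the nine-biomarker effect map at |effect| = 2
#' within-group SD, duplicate-replicate iTRAQ ratios for 100 proteins
#' of which 10% carry planted fold changes in \[2, 5\], and a 60-node
#' interactome with a planted differential module (two hubs) and two
#' planted protein-to-pathway bridge paths.
#'
#' @param nPerGroup samples per group.
#' @param effectMap named numeric effect map (metabolite -> signed
#'   effect in within-group SD units).
#' @param noiseSd additive spectral noise SD.
#' @param concCv within-group concentration CV (log scale).
#' @param baselineCv baseline-amplitude CV across samples.
#' @param seed integer RNG seed.
#' @param timepoint time-point label of the simulated contrast.
#' @param nProteins number of quantified proteins.
#' @param depFraction fraction of proteins with planted effects.
#' @param plantedFcRange fold-change magnitude range (low, high), > 1.
#' @param ratioNoiseSd log-scale SD of replicate ratio noise.
#' @param nNodes,nEdges interactome node and random-edge counts.
#' @param plantedPaths list of node-id sequences to insert as
#'   high-score paths; `NULL` plants two protein-to-pathway bridges
#'   through extended nodes.
#' @param plantedHubs,plantedModule planted hub / differential-module
#'   node ids; `NULL` derives them from `nProteins * depFraction`.
#' @return A [SyntheticDesign-class].
#' @examples
#' d <- syntheticDesign(seed = 7)
#' @export
syntheticDesign <- function(nPerGroup = 10, effectMap = defaultEffectMap(),
                            noiseSd = 0.002, concCv = 0.15,
                            baselineCv = 0.05, seed = 1,
                            timepoint = "24h",
                            nProteins = 100, depFraction = 0.1,
                            plantedFcRange = c(2, 5), ratioNoiseSd = 0.05,
                            nNodes = 60, nEdges = 150,
                            plantedPaths = NULL, plantedHubs = NULL,
                            plantedModule = NULL) {
  nDep <- round(nProteins * depFraction)
  np <- nProteinNodes(nNodes)
  if (is.null(plantedModule))
    plantedModule <- if (nDep > 0) paste0("P", seq_len(min(nDep, np))) else character()
  if (is.null(plantedHubs))
    plantedHubs <- head(plantedModule, 2)
  if (is.null(plantedPaths)) {
    plantedPaths <- list()
    if (length(plantedModule) >= 2 && np >= 4)
      plantedPaths <- list(c(plantedModule[1], paste0("P", np - 1), "PW1"),
                           c(plantedModule[2], paste0("P", np), "PW2"))
  }
  if (is.null(effectMap)) effectMap <- setNames(numeric(0), character(0))
  new("SyntheticDesign", nPerGroup = as.integer(nPerGroup),
      effectMap = effectMap, noiseSd = noiseSd, concCv = concCv,
      baselineCv = baselineCv, effectScale = 0.15,
      seed = as.integer(seed), timepoint = timepoint,
      nProteins = as.integer(nProteins), depFraction = depFraction,
      plantedFcRange = as.numeric(plantedFcRange),
      ratioNoiseSd = ratioNoiseSd, nNodes = as.integer(nNodes),
      nEdges = as.integer(nEdges), plantedPaths = plantedPaths,
      plantedHubs = as.character(plantedHubs),
      plantedModule = as.character(plantedModule))
}

setMethod("show", "SyntheticDesign", function(object) {
  cat(sprintf(
    "SyntheticDesign: %d/group, %d perturbed metabolites, %d proteins (%d planted DEPs),\n  %d-node interactome, %d planted path(s), seed %d\n",
    object@nPerGroup, sum(object@effectMap != 0), object@nProteins,
    round(object@nProteins * object@depFraction), object@nNodes,
    length(object@plantedPaths), object@seed))
})

## node-type partition used by the interactome generator
nProteinNodes <- function(nNodes) {
  nNodes - 2 * nAnchorNodes(nNodes)
}
nAnchorNodes <- function(nNodes) max(2L, round(0.1 * nNodes))

#' Simulate two-group 1H-NMR spectra with planted metabolite shifts
#'
#' Each spectrum is a sum of Lorentzian peaks (one set per metabolite
#' template) plus a broad macromolecular baseline, on a shared ppm axis
#' over `range`. Metabolite concentrations are log-normal: metabolite m
#' in sample i has
#' `conc = baseLevel * exp(effectScale * delta_m * [exposed]) * exp(concCv * z_mi)`
#' with `z ~ N(0,1)` drawn independently per sample and metabolite, so a
#' planted effect `delta_m` shifts the exposed-group mean by exactly
#' `delta_m` within-group standard deviations on the log scale when
#' `concCv` equals the nominal `effectScale` — symmetrically for up- and
#' down-regulation under the downstream log-type variance
#' stabilization. The baseline amplitude varies across samples with CV
#' `baselineCv` (class-unrelated structured variation, the kind OPLS
#' orthogonal components remove). Additive Gaussian noise of SD
#' `noiseSd` is clipped at zero (spectra are nonnegative intensities).
#'
#' @param design a [SyntheticDesign-class].
#' @param library metabolite template library
#'   (default [defaultMetaboliteLibrary()]).
#' @param baseline broad-baseline profile data.frame (center,
#'   halfWidth, amplitude); `NULL` for none.
#' @param ppmStep axis step in ppm.
#' @param range ppm axis range.
#' @return named list of [Spectrum-class] objects (controls first), with
#'   the design attached as attribute `"design"`.
#' @examples
#' sp <- simulateSpectra(syntheticDesign(nPerGroup = 3, seed = 1))
#' sp[[1]]
#' @export
simulateSpectra <- function(design, library = defaultMetaboliteLibrary(),
                            baseline = defaultBaselineProfile(),
                            ppmStep = 2.5e-4, range = c(0.2, 9.1)) {
  stopifnot(is(design, "SyntheticDesign"))
  validateMetaboliteLibrary(library)
  unknown <- setdiff(names(design@effectMap), library$metabolite)
  if (length(unknown))
    stop("effect map names metabolites absent from the library: ",
         paste(unknown, collapse = ", "))
  mets <- unique(library$metabolite)
  ppm <- seq(range[1], range[2], by = ppmStep)
  n <- design@nPerGroup
  groups <- rep(c("control", "exposed"), each = n)
  ids <- sprintf("%s_%02d", groups, c(seq_len(n), seq_len(n)))
  base <- setNames(library$baseLevel[!duplicated(library$metabolite)], mets)
  delta <- setNames(rep(0, length(mets)), mets)
  delta[names(design@effectMap)] <- design@effectMap

  withr::with_seed(design@seed, {
    # per-sample, per-metabolite concentrations
    z <- matrix(if (design@concCv > 0) rnorm(2 * n * length(mets)) else 0,
                nrow = 2 * n, ncol = length(mets),
                dimnames = list(ids, mets))
    expo <- rep(c(0, 1), each = n)
    shift <- exp(design@effectScale * outer(expo, delta))
    conc <- sweep(shift * exp(design@concCv * z), 2, base, "*")
    dimnames(conc) <- dimnames(z)

    blShape <- numeric(length(ppm))
    if (!is.null(baseline))
      for (j in seq_len(nrow(baseline)))
        blShape <- blShape + baseline$amplitude[j] * baseline$halfWidth[j]^2 /
          ((ppm - baseline$center[j])^2 + baseline$halfWidth[j]^2)
    blScale <- if (design@baselineCv > 0)
      pmax(0, 1 + design@baselineCv * rnorm(2 * n)) else rep(1, 2 * n)

    spectra <- vector("list", 2 * n)
    for (i in seq_len(2 * n)) {
      y <- blScale[i] * blShape
      for (k in seq_len(nrow(library))) {
        hw <- library$halfWidth[k]
        amp <- conc[i, library$metabolite[k]] * library$relIntensity[k]
        y <- y + amp * hw^2 / ((ppm - library$center[k])^2 + hw^2)
      }
      if (design@noiseSd > 0)
        y <- pmax(0, y + rnorm(length(ppm), sd = design@noiseSd))
      spectra[[i]] <- Spectrum(ppm, y, ids[i], group = groups[i],
                               timepoint = design@timepoint)
    }
  })
  names(spectra) <- ids
  attr(spectra, "design") <- design
  spectra
}

#' Simulate a duplicate-replicate iTRAQ protein quantification table
#'
#' Emulates an 8-plex design quantified as two replicate
#' treated/control ratios per time point (24, 48, 96 h). Proteins
#' without planted effects have ratios log-normally distributed around
#' 1; planted differential proteins have ratios around a fold change
#' drawn from `plantedFcRange` (or its reciprocal for down-regulation),
#' redrawn per time point. Planted proteins always satisfy the
#' quantification filters (>= 2 peptides, detected in both replicates,
#' FDR below 1%), so that recovery failures reflect the calling rules,
#' not an unquantifiable plant.
#'
#' @param design a [SyntheticDesign-class].
#' @param timepoints time-point labels.
#' @return list with `table` (the quantification data.frame: id,
#'   description, peptides, det_rep1, det_rep2, fdr, and
#'   `ratio_<tp>_rep<k>` columns) and `truth` (planted ids, per-id
#'   direction, and the per-(id, timepoint) true ratios).
#' @examples
#' it <- simulateItraqTable(syntheticDesign(seed = 3))
#' head(it$table[, 1:6]); it$truth$depIds
#' @export
simulateItraqTable <- function(design, timepoints = c("24h", "48h", "96h")) {
  stopifnot(is(design, "SyntheticDesign"))
  np <- design@nProteins
  nDep <- round(np * design@depFraction)
  if (design@depFraction > 0 && nDep < 1)
    stop("depFraction * nProteins must be >= 1 when depFraction > 0")
  withr::with_seed(design@seed + 1L, {
    ids <- sprintf("prot%04d", seq_len(np))
    tab <- data.frame(
      id = ids,
      description = sprintf("synthetic protein %d", seq_len(np)),
      peptides = 1L + rpois(np, 3),
      det_rep1 = runif(np) < 0.97,
      det_rep2 = runif(np) < 0.97,
      fdr = runif(np, 0, 0.009))
    depIds <- ids[seq_len(nDep)]
    if (nDep > 0) {  # plants must be quantifiable
      tab$peptides[seq_len(nDep)] <- pmax(2L, tab$peptides[seq_len(nDep)])
      tab$det_rep1[seq_len(nDep)] <- TRUE
      tab$det_rep2[seq_len(nDep)] <- TRUE
    }
    dirUp <- runif(nDep) < 0.5
    truthRatios <- NULL
    for (tp in timepoints) {
      true <- rep(1, np)
      if (nDep > 0) {
        fc <- runif(nDep, design@plantedFcRange[1], design@plantedFcRange[2])
        true[seq_len(nDep)] <- ifelse(dirUp, fc, 1 / fc)
      }
      for (rep in 1:2) {
        noise <- if (design@ratioNoiseSd > 0)
          exp(rnorm(np, sd = design@ratioNoiseSd)) else 1
        tab[[sprintf("ratio_%s_rep%d", tp, rep)]] <- true * noise
      }
      truthRatios <- rbind(truthRatios,
        data.frame(id = ids, timepoint = tp, trueRatio = true))
    }
  })
  list(table = tab,
       truth = list(depIds = depIds,
                    direction = setNames(ifelse(dirUp, "up", "down"), depIds),
                    ratios = truthRatios))
}

#' Simulate a scored interactome with planted structure
#'
#' Generates a random undirected graph over protein, pathway and
#' metabolite-anchor nodes with combined scores drawn uniformly on
#' \[150, 999\] (STRING 0-1000 convention), then inserts planted
#' structure as high-score edges: the planted differential module (a
#' two-hub double star over `plantedModule`), the planted bridge paths,
#' and metabolite-to-pathway anchor edges. Random edges that would
#' directly connect the endpoints of a planted path are resampled so
#' that each planted path remains among the shortest paths between its
#' endpoints. Duplicate edges keep the maximum score.
#'
#' @param design a [SyntheticDesign-class].
#' @param cutoff combined-score cutoff passed to [buildGraph()].
#' @return list with `interactome` (an [Interactome-class]), `edges`
#'   (the full pre-cutoff edge data.frame), `nodeTypes` (data.frame id,
#'   type), `plantedPaths`, and `truth` (hubs, module).
#' @examples
#' net <- simulateInteractome(syntheticDesign(seed = 5))
#' net$interactome
#' @export
simulateInteractome <- function(design, cutoff = 400) {
  stopifnot(is(design, "SyntheticDesign"))
  nN <- design@nNodes
  nA <- nAnchorNodes(nN)
  np <- nProteinNodes(nN)
  nodes <- c(paste0("P", seq_len(np)), paste0("PW", seq_len(nA)),
             paste0("M", seq_len(nA)))
  types <- rep(c("protein", "pathway", "metabolite"), c(np, nA, nA))
  for (p in design@plantedPaths)
    if (!all(p %in% nodes))
      stop("planted path references nodes absent from the graph: ",
           paste(setdiff(p, nodes), collapse = ", "))
  if (!all(design@plantedModule %in% nodes))
    stop("planted module references nodes absent from the graph")

  planted <- data.frame(from = character(), to = character(),
                        score = numeric())
  addEdge <- function(e, a, b, s) rbind(e, data.frame(from = a, to = b, score = s))
  # differential module: double star around the two planted hubs
  mod <- design@plantedModule
  if (length(mod) >= 2) {
    h <- design@plantedHubs
    planted <- addEdge(planted, h[1], h[2], 900)
    rest <- setdiff(mod, h)
    if (length(rest)) {
      half <- ceiling(length(rest) / 2)
      for (v in rest[seq_len(half)]) planted <- addEdge(planted, h[1], v, 900)
      for (v in setdiff(rest, rest[seq_len(half)]))
        planted <- addEdge(planted, h[2], v, 900)
    }
  }
  # bridge paths
  for (p in design@plantedPaths)
    for (k in seq_len(length(p) - 1))
      planted <- addEdge(planted, p[k], p[k + 1], 950)
  # metabolite anchors hang off pathways
  for (i in seq_len(nA))
    planted <- addEdge(planted, paste0("M", i), paste0("PW", i), 900)

  # random-edge pairs, excluding pairs that would shortcut a planted path
  forbid <- character()
  for (p in design@plantedPaths) {
    cmb <- utils::combn(p, 2)
    adj <- cbind(p[-length(p)], p[-1])
    keyAll <- apply(cmb, 2, function(e) paste(sort(e), collapse = "|"))
    keyAdj <- apply(adj, 1, function(e) paste(sort(e), collapse = "|"))
    forbid <- c(forbid, setdiff(keyAll, keyAdj))
  }
  withr::with_seed(design@seed + 2L, {
    idx <- which(upper.tri(matrix(0, nN, nN)), arr.ind = TRUE)
    key <- paste(pmin(nodes[idx[, 1]], nodes[idx[, 2]]),
                 pmax(nodes[idx[, 1]], nodes[idx[, 2]]), sep = "|")
    ok <- which(!key %in% forbid)
    pick <- sample(ok, min(design@nEdges, length(ok)))
    rnd <- data.frame(from = nodes[idx[pick, 1]], to = nodes[idx[pick, 2]],
                      score = round(runif(length(pick), 150, 999)))
  })
  edges <- rbind(planted, rnd)
  nodeTypes <- data.frame(id = nodes, type = types)
  g <- buildGraph(edges, cutoff = cutoff, nodeTypes = nodeTypes)
  list(interactome = g, edges = edges, nodeTypes = nodeTypes,
       plantedPaths = design@plantedPaths,
       truth = list(hubs = design@plantedHubs, module = mod))
}

#' Simulate a homology hit table
#'
#' Produces per-query alignment hits such that quantified protein
#' `prot000i` has its genuine homolog at interactome node `Pi` (best
#' identity among qualifying hits), plus lower-identity decoy hits.
#' Queries beyond the number of protein nodes receive only hits above
#' the e-value cutoff and therefore stay unmapped.
#'
#' @param design a [SyntheticDesign-class].
#' @return data.frame with columns query, subject, pident, evalue, rank.
#' @export
simulateHitTable <- function(design) {
  stopifnot(is(design, "SyntheticDesign"))
  np <- nProteinNodes(design@nNodes)
  withr::with_seed(design@seed + 3L, {
    rows <- list()
    for (i in seq_len(design@nProteins)) {
      q <- sprintf("prot%04d", i)
      if (i <= np) {
        decoy <- paste0("P", sample(setdiff(seq_len(np), i), 2))
        rows[[i]] <- data.frame(
          query = q,
          subject = c(paste0("P", i), decoy),
          pident = c(runif(1, 75, 95), runif(2, 40, 65)),
          evalue = c(10^-runif(1, 40, 80), 10^-runif(1, 12, 25),
                     10^-runif(1, 2, 8)),
          rank = 1:3)
      } else {
        rows[[i]] <- data.frame(query = q,
                                subject = paste0("P", sample(np, 1)),
                                pident = runif(1, 60, 80),
                                evalue = 10^-runif(1, 1, 9), rank = 1L)
      }
    }
  })
  do.call(rbind, rows)
}

#' Simulate annotation sets (GMT-style)
#'
#' Builds a collection of gene sets over the interactome protein nodes:
#' one planted term containing the planted differential module (so term
#' enrichment can be validated against ground truth) plus random terms.
#'
#' @param design a [SyntheticDesign-class].
#' @param nRandomTerms number of random terms.
#' @param termSize size of each random term.
#' @return named list of member-id vectors with a `descriptions`
#'   attribute, as returned by [readGmt()].
#' @export
simulateAnnotations <- function(design, nRandomTerms = 5, termSize = 8) {
  stopifnot(is(design, "SyntheticDesign"))
  np <- nProteinNodes(design@nNodes)
  prots <- paste0("P", seq_len(np))
  withr::with_seed(design@seed + 4L, {
    sets <- list(PLANTED_MODULE = unique(c(design@plantedModule,
                                           sample(prots, 2))))
    for (k in seq_len(nRandomTerms))
      sets[[sprintf("RANDOM_TERM_%d", k)]] <- sample(prots, termSize)
  })
  attr(sets, "descriptions") <- setNames(
    c("planted differential module",
      rep("random background term", nRandomTerms)), names(sets))
  sets
}
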