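#' Build a scored interaction graph
#'
#' Keeps edges with combined score at or above `cutoff` (400 by
#' default, the conventional medium-confidence setting on the 0-1000
#' combined-score scale), merges duplicate edges by maximum score,
#' drops self-loops, and preserves all nodes — including those whose
#' every edge falls below the cutoff. Malformed rows (missing ids or
#' non-finite scores) are skipped with a message.
#'
#' @param edges data.frame with columns from, to, score (0-1000).
#' @param cutoff combined-score cutoff.
#' @param nodeTypes optional data.frame (id, type) tagging nodes as
#'   protein / pathway / metabolite; untagged nodes default to
#'   `"protein"`.
#' @return an [Interactome-class].
#' @examples
#' e <- data.frame(from = c("a", "b"), to = c("b", "a"),
#'                 score = c(500, 700))
#' buildGraph(e)   # single a-b edge, score 700
#' @export
buildGraph <- function(edges, cutoff = 400, nodeTypes = NULL) {
  stopifnot(all(c("from", "to", "score") %in% names(edges)))
  bad <- is.na(edges$from) | is.na(edges$to) | !is.finite(edges$score) |
    edges$from == "" | edges$to == ""
  if (any(bad)) {
    message(sum(bad), " malformed edge row(s) skipped")
    edges <- edges[!bad, , drop = FALSE]
  }
  if (any(edges$score < 0 | edges$score > 1000))
    stop("edge scores must lie in [0, 1000]")
  loops <- edges$from == edges$to
  if (any(loops)) {
    message(sum(loops), " self-loop(s) skipped")
    edges <- edges[!loops, , drop = FALSE]
  }
  nodes <- unique(c(edges$from, edges$to,
                    if (!is.null(nodeTypes)) nodeTypes$id))
  if (nrow(edges)) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    merged <- aggregate(score ~ a + b,
                        data = data.frame(a = a, b = b, score = edges$score),
                        FUN = max)
    merged <- merged[merged$score >= cutoff, , drop = FALSE]
  } else {
    merged <- data.frame(a = character(), b = character(), score = numeric())
  }
  vdf <- data.frame(name = nodes,
                    type = rep("protein", length(nodes)))
  if (!is.null(nodeTypes))
    vdf$type[match(nodeTypes$id, vdf$name)] <- nodeTypes$type
  g <- igraph::graph_from_data_frame(
    data.frame(from = merged$a, to = merged$b, score = merged$score),
    directed = FALSE, vertices = vdf)
  new("Interactome", graph = g, scoreCutoff = cutoff)
}

#' Read a 3-column interactome edge list
#'
#' @param path TSV with columns from, to, score (header optional,
#'   detected).
#' @param ... passed to [buildGraph()].
#' @return an [Interactome-class].
#' @export
readEdgeList <- function(path, ...) {
  first <- readLines(path, n = 1)
  hasHeader <- grepl("score", first, ignore.case = TRUE)
  tab <- read.table(path, sep = "\t", header = hasHeader,
                    stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("from", "to", "score")
  buildGraph(tab, ...)
}

#' Annotate interactome nodes with differential-protein fold changes
#'
#' Maps differential proteins onto graph nodes through a homolog
#' mapping and stores per-time-point fold changes as vertex attributes
#' (`fc_<tp>`). When several proteins hit the same node, the node
#' keeps the fold change of largest magnitude on the log scale, all
#' values are retained in `fc_all`, and the collision is flagged
#' (`multiMapped`). Differential proteins whose homolog is absent from
#' the graph are listed as unplaced.
#'
#' @param interactome an [Interactome-class].
#' @param dep a `DepTable` (id, timepoint, fold_change) restricted to
#'   differential rows, e.g. `filterDeps(...)$table` rows with
#'   `is_dep`.
#' @param mapping data.frame (query, subject) from
#'   [selectBestHomolog()].
#' @return list with `interactome` (annotated) and `unplaced`
#'   (character ids).
#' @export
mapDeps <- function(interactome, dep, mapping) {
  stopifnot(is(interactome, "Interactome"))
  g <- interactome@graph
  map <- mapping[!is.na(mapping$subject), c("query", "subject")]
  dep$node <- map$subject[match(dep$id, map$query)]
  present <- !is.na(dep$node) & dep$node %in% igraph::V(g)$name
  unplaced <- unique(dep$id[!present])
  dep <- dep[present, , drop = FALSE]
  igraph::V(g)$dep <- igraph::V(g)$name %in% dep$node
  for (tp in unique(dep$timepoint)) {
    d <- dep[dep$timepoint == tp, , drop = FALSE]
    # strongest |log fc| wins on collision; all values kept in fc_all
    o <- order(-abs(log(d$fold_change)))
    d <- d[o, , drop = FALSE]
    att <- rep(NA_real_, igraph::vcount(g))
    idx <- match(d$node[!duplicated(d$node)], igraph::V(g)$name)
    att[idx] <- d$fold_change[!duplicated(d$node)]
    g <- igraph::set_vertex_attr(g, paste0("fc_", tp), value = att)
  }
  multi <- unique(dep$node[duplicated(paste(dep$node, dep$timepoint))])
  igraph::V(g)$multiMapped <- igraph::V(g)$name %in% multi
  all <- vapply(igraph::V(g)$name, function(v) {
    rows <- dep[dep$node == v, , drop = FALSE]
    if (!nrow(rows)) "" else
      paste(sprintf("%s:%s=%.4g", rows$id, rows$timepoint,
                    rows$fold_change), collapse = ";")
  }, character(1))
  igraph::V(g)$fc_all <- unname(all)
  out <- interactome
  out@graph <- g
  list(interactome = out, unplaced = unplaced)
}

#' Shortest bridge paths from proteins to pathway/metabolite nodes
#'
#' For every (source, target) pair, finds all unweighted (hop-count)
#' shortest paths of length at most `maxLen` by breadth-first search.
#' Intermediate nodes outside the source set are tagged "extended" —
#' the connector proteins pulled in from the database. Disconnected
#' pairs are recorded as unreachable, not an error; a source equal to a
#' target yields the length-0 path.
#'
#' @param interactome an [Interactome-class].
#' @param sources character, source node ids (e.g. differential
#'   proteins).
#' @param targets character, target node ids (pathway / metabolite
#'   anchors).
#' @param maxLen maximum path length in hops.
#' @return list with `paths` (list of node-id vectors), `pairs`
#'   (data.frame source, target, length, reachable) and `extended`
#'   (character ids of non-source intermediate nodes).
#' @export
shortestPathsBridge <- function(interactome, sources, targets, maxLen = 4) {
  stopifnot(is(interactome, "Interactome"))
  g <- interactome@graph
  nodes <- igraph::V(g)$name
  if (!all(c(sources, targets) %in% nodes))
    stop("sources and targets must be nodes of the graph")
  paths <- list(); pairs <- NULL; extended <- character()
  for (s in sources) {
    d <- drop(igraph::distances(g, v = s, to = targets))
    for (j in seq_along(targets)) {
      t <- targets[j]
      if (s == t) {
        paths[[length(paths) + 1L]] <- s
        pairs <- rbind(pairs, data.frame(source = s, target = t,
                                         length = 0, reachable = TRUE))
        next
      }
      if (!is.finite(d[j]) || d[j] > maxLen) {
        pairs <- rbind(pairs, data.frame(
          source = s, target = t,
          length = if (is.finite(d[j])) d[j] else NA_real_,
          reachable = FALSE))
        next
      }
      sp <- igraph::all_shortest_paths(g, from = s, to = t)$vpaths
      for (p in sp) {
        pv <- igraph::as_ids(p)
        paths[[length(paths) + 1L]] <- pv
        extended <- union(extended, setdiff(pv[-c(1, length(pv))], sources))
      }
      pairs <- rbind(pairs, data.frame(source = s, target = t,
                                       length = d[j], reachable = TRUE))
    }
  }
  list(paths = paths, pairs = pairs, extended = extended)
}

#' Extract the core regulation subnetwork
#'
#' Induces the subgraph on differential nodes plus any extended nodes
#' lying on the retained bridge paths, and keeps its largest connected
#' component. Direct edges come from the interactome; for each stored
#' bridge path whose nodes survive, an indirect edge joins its
#' endpoints (unless a direct edge already does). Hubs are ranked by
#' [rankHubs()].
#'
#' @param interactome a DEP-annotated [Interactome-class] (from
#'   [mapDeps()]).
#' @param depNodes character ids of differential nodes.
#' @param bridges optional result of [shortestPathsBridge()]; its paths
#'   contribute extended nodes and indirect edges.
#' @param unplaced character ids carried into the result for reporting.
#' @return a [RegulationNetwork-class] (empty, with a warning, when
#'   there are no differential nodes).
#' @export
extractCoreSubnetwork <- function(interactome, depNodes, bridges = NULL,
                                  unplaced = character()) {
  stopifnot(is(interactome, "Interactome"))
  g <- interactome@graph
  depNodes <- intersect(depNodes, igraph::V(g)$name)
  bridgePaths <- if (is.null(bridges)) list() else bridges$paths
  extended <- if (is.null(bridges)) character() else bridges$extended
  if (!length(depNodes)) {
    warning("no differential nodes in the graph: empty network")
    eg <- igraph::make_empty_graph(0, directed = FALSE)
    return(new("RegulationNetwork", graph = eg, bridgePaths = list(),
               hubs = data.frame(node = character(), degree = integer()),
               componentSizes = integer(), unplaced = unplaced))
  }
  keep <- union(depNodes, unlist(bridgePaths))
  sub <- igraph::induced_subgraph(g, intersect(keep, igraph::V(g)$name))
  comp <- igraph::components(sub)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  coreMembers <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  core <- igraph::induced_subgraph(sub, coreMembers)
  if (igraph::ecount(core) > 0)
    igraph::E(core)$interaction <- "direct"
  igraph::V(core)$extended <- !(igraph::V(core)$name %in% depNodes)
  # indirect edges for bridge paths retained in the core
  kept <- list()
  for (p in bridgePaths) {
    if (!all(p %in% igraph::V(core)$name)) next
    kept[[length(kept) + 1L]] <- p
    if (length(p) > 2) {
      ends <- c(p[1], p[length(p)])
      if (!igraph::are_adjacent(core, ends[1], ends[2]))
        core <- igraph::add_edges(core, ends,
                                  attr = list(interaction = "indirect",
                                              score = NA_real_))
    }
  }
  net <- new("RegulationNetwork", graph = core, bridgePaths = kept,
             hubs = data.frame(node = character(), degree = integer()),
             componentSizes = sizes, unplaced = unplaced)
  net@hubs <- rankHubs(net, igraph::vcount(core))
  net
}

#' Rank hub nodes by degree
#'
#' Nodes are ranked by degree within the core network; ties are broken
#' by the total |log fold change| across time points (larger first),
#' then by node id.
#'
#' @param network a [RegulationNetwork-class].
#' @param k number of top nodes to return (all, when larger than the
#'   node count).
#' @return data.frame: node, degree, totalAbsLogFc.
#' @export
rankHubs <- function(network, k = 10) {
  stopifnot(is(network, "RegulationNetwork"))
  g <- network@graph
  if (igraph::vcount(g) == 0)
    return(data.frame(node = character(), degree = integer(),
                      totalAbsLogFc = numeric()))
  deg <- igraph::degree(g)
  fcAttrs <- grep("^fc_", igraph::vertex_attr_names(g), value = TRUE)
  fcAttrs <- setdiff(fcAttrs, "fc_all")
  totFc <- rep(0, igraph::vcount(g))
  for (a in fcAttrs) {
    v <- igraph::vertex_attr(g, a)
    totFc <- totFc + ifelse(is.na(v), 0, abs(log(v)))
  }
  out <- data.frame(node = igraph::V(g)$name, degree = as.integer(deg),
                    totalAbsLogFc = totFc)
  out <- out[order(-out$degree, -out$totalAbsLogFc, out$node), , drop = FALSE]
  rownames(out) <- NULL
  head(out, min(k, nrow(out)))
}

#' Export a regulation network to Cytoscape-compatible files
#'
#' Writes a SIF edge file (`node  direct|indirect  node`), a
#' node-attribute TSV (type, extended flag, per-time-point fold
#' changes) and a GraphML file carrying all attributes plus the bridge
#' paths (as a JSON graph attribute) so that [importNetwork()] can
#' rebuild the object losslessly.
#'
#' @param network a [RegulationNetwork-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisible character vector of the files written.
#' @export
exportNetwork <- function(network, dir, prefix = "regulation_network") {
  stopifnot(is(network, "RegulationNetwork"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- network@graph
  sif <- file.path(dir, paste0(prefix, ".sif"))
  attrTsv <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  gml <- file.path(dir, paste0(prefix, ".graphml"))
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g))
    writeLines(paste(ends[, 1], igraph::E(g)$interaction, ends[, 2],
                     sep = "\t"), sif)
  } else writeLines(character(), sif)
  av <- igraph::vertex_attr_names(g)
  nodeTab <- data.frame(node = if (igraph::vcount(g)) igraph::V(g)$name
                        else character())
  for (a in setdiff(av, "name"))
    nodeTab[[a]] <- if (igraph::vcount(g)) igraph::vertex_attr(g, a)
                    else vector(mode = "character", length = 0)
  write.table(nodeTab, attrTsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  gExp <- igraph::set_graph_attr(g, "bridgePaths",
    as.character(jsonlite::toJSON(network@bridgePaths)))
  gExp <- igraph::set_graph_attr(gExp, "unplaced",
    as.character(jsonlite::toJSON(network@unplaced)))
  gExp <- igraph::set_graph_attr(gExp, "componentSizes",
    as.character(jsonlite::toJSON(network@componentSizes)))
  # GraphML cannot hold logical/NA attributes portably
  for (a in setdiff(igraph::vertex_attr_names(gExp), "name")) {
    v <- igraph::vertex_attr(gExp, a)
    if (is.logical(v))
      gExp <- igraph::set_vertex_attr(gExp, a, value = as.integer(v))
  }
  igraph::write_graph(gExp, gml, format = "graphml")
  invisible(c(sif = sif, nodes = attrTsv, graphml = gml))
}

#' Re-import a regulation network from GraphML
#'
#' @param path a GraphML file written by [exportNetwork()].
#' @return a [RegulationNetwork-class].
#' @export
importNetwork <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  bp <- igraph::graph_attr(g, "bridgePaths")
  up <- igraph::graph_attr(g, "unplaced")
  cs <- igraph::graph_attr(g, "componentSizes")
  g <- igraph::delete_graph_attr(g, "bridgePaths")
  g <- igraph::delete_graph_attr(g, "unplaced")
  g <- igraph::delete_graph_attr(g, "componentSizes")
  if ("id" %in% igraph::vertex_attr_names(g))
    g <- igraph::delete_vertex_attr(g, "id")
  if ("score" %in% igraph::edge_attr_names(g)) {
    sc <- igraph::edge_attr(g, "score")
    sc[is.nan(sc)] <- NA_real_
    g <- igraph::set_edge_attr(g, "score", value = sc)
  }
  for (a in igraph::vertex_attr_names(g)) {   # GraphML writes NA as NaN
    v <- igraph::vertex_attr(g, a)
    if (is.numeric(v) && any(is.nan(v))) {
      v[is.nan(v)] <- NA_real_
      g <- igraph::set_vertex_attr(g, a, value = v)
    }
  }
  if ("extended" %in% igraph::vertex_attr_names(g))
    g <- igraph::set_vertex_attr(g, "extended",
      value = as.logical(igraph::vertex_attr(g, "extended")))
  if ("dep" %in% igraph::vertex_attr_names(g))
    g <- igraph::set_vertex_attr(g, "dep",
      value = as.logical(igraph::vertex_attr(g, "dep")))
  if ("multiMapped" %in% igraph::vertex_attr_names(g))
    g <- igraph::set_vertex_attr(g, "multiMapped",
      value = as.logical(igraph::vertex_attr(g, "multiMapped")))
  paths <- lapply(jsonlite::fromJSON(bp, simplifyVector = FALSE),
                  function(p) unlist(p))
  net <- new("RegulationNetwork", graph = g, bridgePaths = paths,
             hubs = data.frame(node = character(), degree = integer()),
             componentSizes = as.integer(jsonlite::fromJSON(cs)),
             unplaced = as.character(jsonlite::fromJSON(up)))
  net@hubs <- rankHubs(net, igraph::vcount(g))
  net
}
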