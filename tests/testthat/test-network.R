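test_that("graph building merges duplicates, drops loops, keeps nodes", {
  e <- data.frame(from = c("a", "b", "c", "c"),
                  to = c("b", "a", "c", "d"),
                  score = c(500, 700, 900, 100))
  expect_message(g <- buildGraph(e, cutoff = 400), "self-loop")
  gr <- networkGraph(g)
  expect_equal(igraph::ecount(gr), 1)           # a-b merged, c-d cut
  expect_identical(igraph::E(gr)$score, 700)         # max of duplicates
  expect_setequal(igraph::V(gr)$name, c("a", "b", "c", "d"))
  # all edges below cutoff: empty edge set, nodes preserved
  gLow <- buildGraph(data.frame(from = "a", to = "b", score = 100))
  expect_equal(igraph::ecount(networkGraph(gLow)), 0)
  expect_setequal(igraph::V(networkGraph(gLow))$name, c("a", "b"))
  expect_error(buildGraph(data.frame(from = "a", to = "b", score = 2000)),
               "\\[0, 1000\\]")
})

test_that("bridge search: trivial paths and unreachable pairs", {
  e <- data.frame(from = c("a", "b"), to = c("b", "c"),
                  score = c(900, 900))
  g <- buildGraph(e, nodeTypes = data.frame(id = c("a", "b", "c", "z"),
                                            type = c("protein", "protein",
                                                     "pathway", "pathway")))
  br <- shortestPathsBridge(g, "a", "c")
  expect_identical(br$paths[[1]], c("a", "b", "c"))
  expect_identical(br$extended, "b")
  same <- shortestPathsBridge(g, "a", "a")
  expect_identical(same$paths[[1]], "a")
  expect_identical(same$pairs$length, 0)
  disc <- shortestPathsBridge(g, "a", "z")
  expect_false(disc$pairs$reachable)
  # paths beyond maxLen are not returned
  far <- shortestPathsBridge(g, "a", "c", maxLen = 1)
  expect_length(far$paths, 0)
  expect_false(far$pairs$reachable)
})

test_that("BFS path lengths match the Floyd-Warshall oracle on random graphs", {
  set.seed(31)
  for (trial in 1:30) {
    n <- sample(8:50, 1)
    m <- sample(n:(2 * n), 1)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- idx[sample(nrow(idx), min(m, nrow(idx))), , drop = FALSE]
    nodes <- paste0("v", seq_len(n))
    e <- data.frame(from = nodes[pick[, 1]], to = nodes[pick[, 2]],
                    score = 900)
    g <- buildGraph(e, cutoff = 400,
                    nodeTypes = data.frame(id = nodes, type = "protein"))
    adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
    adj[cbind(pick[, 1], pick[, 2])] <- 1
    adj <- adj + t(adj)
    D <- floydWarshall(adj)
    ig <- igraph::distances(networkGraph(g))
    ig <- ig[nodes, nodes]
    expect_equal(unname(ig), unname(D))
    # spot-check the bridge search agrees on a random source/target
    s <- sample(nodes, 1); t <- sample(nodes, 1)
    br <- shortestPathsBridge(g, s, t, maxLen = n)
    if (is.finite(D[s, t])) {
      expect_true(br$pairs$reachable)
      expect_identical(br$pairs$length, D[s, t])
      for (p in br$paths) expect_length(p, D[s, t] + 1)
    } else {
      expect_false(br$pairs$reachable)
    }
  }
})

test_that("raising the score cutoff never shortens paths or adds bridges", {
  d <- syntheticDesign(seed = 33)
  sim <- simulateInteractome(d, cutoff = 400)
  gHi <- buildGraph(sim$edges, cutoff = 700, nodeTypes = sim$nodeTypes)
  targets <- sim$nodeTypes$id[sim$nodeTypes$type == "pathway"]
  loP <- shortestPathsBridge(sim$interactome, d@plantedModule, targets)
  hiP <- shortestPathsBridge(gHi, d@plantedModule, targets)
  key <- function(p) paste(p$source, p$target)
  common <- intersect(key(loP$pairs), key(hiP$pairs))
  lo <- loP$pairs[match(common, key(loP$pairs)), ]
  hi <- hiP$pairs[match(common, key(hiP$pairs)), ]
  reach <- !is.na(lo$length) & !is.na(hi$length)
  expect_true(all(hi$length[reach] >= lo$length[reach]))
  expect_true(all(!hi$reachable | lo$reachable))
})

test_that("DEP mapping annotates nodes, reports unplaced, round-trips values", {
  e <- data.frame(from = c("N1", "N2"), to = c("N2", "N3"),
                  score = c(900, 900))
  g <- buildGraph(e)
  dep <- data.frame(id = c("p1", "p2", "p3"), timepoint = "24h",
                    fold_change = c(2.5, 0.4, 9.9))
  mapping <- data.frame(query = c("p1", "p2", "p3"),
                        subject = c("N1", "N2", "ABSENT"))
  md <- mapDeps(g, dep, mapping)
  gr <- networkGraph(md$interactome)
  expect_identical(md$unplaced, "p3")
  expect_equal(igraph::vertex_attr(gr, "fc_24h",
                                   igraph::V(gr)["N1"]), 2.5)
  expect_equal(igraph::vertex_attr(gr, "fc_24h",
                                   igraph::V(gr)["N2"]), 0.4)
  # empty DEP set annotates nothing
  md0 <- mapDeps(g, dep[0, ], mapping)
  expect_false(any(igraph::V(networkGraph(md0$interactome))$dep))
  # collision: two proteins on one node is flagged, both values kept
  dep2 <- data.frame(id = c("p1", "p4"), timepoint = "24h",
                     fold_change = c(2.5, 0.2))
  map2 <- data.frame(query = c("p1", "p4"), subject = c("N1", "N1"))
  md2 <- mapDeps(g, dep2, map2)
  v <- igraph::V(networkGraph(md2$interactome))["N1"]
  expect_true(igraph::vertex_attr(networkGraph(md2$interactome),
                                  "multiMapped", v))
  expect_match(igraph::vertex_attr(networkGraph(md2$interactome),
                                   "fc_all", v), "p1.*p4|p4.*p1")
})

test_that("core extraction keeps the largest component plus bridge nodes", {
  # two DEP components of sizes 5 (a1..a5 path) and 3 (b1..b3 path)
  e <- data.frame(from = c("a1", "a2", "a3", "a4", "b1", "b2"),
                  to = c("a2", "a3", "a4", "a5", "b2", "b3"),
                  score = 900)
  g <- buildGraph(e)
  deps <- c(paste0("a", 1:5), paste0("b", 1:3))
  net <- extractCoreSubnetwork(g, deps)
  expect_equal(igraph::vcount(networkGraph(net)), 5)
  expect_identical(net@componentSizes, c(5L, 3L))
  expect_setequal(igraph::V(networkGraph(net))$name, paste0("a", 1:5))
  # fully connected DEP set -> the whole set
  e2 <- data.frame(from = c("x", "x", "y"), to = c("y", "z", "z"),
                   score = 900)
  net2 <- extractCoreSubnetwork(buildGraph(e2), c("x", "y", "z"))
  expect_equal(igraph::vcount(networkGraph(net2)), 3)
  # no DEP nodes -> empty network with a warning
  expect_warning(net0 <- extractCoreSubnetwork(g, character()), "empty")
  expect_equal(igraph::vcount(networkGraph(net0)), 0)
})

test_that("extended bridge nodes join the core and indirect edges are tagged", {
  e <- data.frame(from = c("d1", "x", "d1"), to = c("x", "d2", "d3"),
                  score = 900)
  g <- buildGraph(e, nodeTypes = data.frame(
    id = c("d1", "d2", "d3", "x"), type = c("protein", "pathway",
                                            "protein", "protein")))
  br <- shortestPathsBridge(g, c("d1", "d3"), "d2")
  net <- extractCoreSubnetwork(g, c("d1", "d3"), br)
  gr <- networkGraph(net)
  expect_true("x" %in% igraph::V(gr)$name)
  expect_true(igraph::vertex_attr(gr, "extended", igraph::V(gr)["x"]))
  ind <- igraph::E(gr)[igraph::E(gr)$interaction == "indirect"]
  expect_gte(length(ind), 1L)
  # every indirect edge corresponds to a stored bridge path
  ends <- igraph::ends(gr, ind)
  keys <- apply(ends, 1, function(x) paste(sort(x), collapse = "|"))
  bkeys <- vapply(bridgePaths(net), function(p)
    paste(sort(c(p[1], p[length(p)])), collapse = "|"), character(1))
  expect_true(all(keys %in% bkeys))
  # every extended node lies on at least one stored bridge path
  extn <- igraph::V(gr)$name[igraph::V(gr)$extended]
  expect_true(all(extn %in% unlist(bridgePaths(net))))
})

test_that("hub ranking: star center first, ties broken by fold change then id", {
  e <- data.frame(from = rep("hub", 5), to = paste0("leaf", 1:5),
                  score = 900)
  net <- extractCoreSubnetwork(buildGraph(e), c("hub", paste0("leaf", 1:5)))
  expect_identical(hubs(net)$node[1], "hub")
  # 4-cycle is degree-regular; fold-change magnitude then id decides
  e2 <- data.frame(from = c("a", "b", "c", "d"), to = c("b", "c", "d", "a"),
                   score = 900)
  g2 <- buildGraph(e2)
  dep <- data.frame(id = paste0("p", 1:4), timepoint = "24h",
                    fold_change = c(2, 8, 2, 2))
  md <- mapDeps(g2, dep, data.frame(query = paste0("p", 1:4),
                                    subject = c("a", "b", "c", "d")))
  net2 <- extractCoreSubnetwork(md$interactome, c("a", "b", "c", "d"))
  h <- hubs(net2)
  expect_identical(h$node[1], "b")       # |log 8| dominates
  expect_identical(h$node[2:4], c("a", "c", "d"))  # then id
  # k larger than the node count returns everything
  expect_identical(nrow(rankHubs(net2, 99)), 4L)
})

test_that("network export round-trips through GraphML and writes SIF", {
  d <- syntheticDesign(seed = 35)
  res <- runPipeline(runConfig(design = d))
  net <- res$network
  dir <- withr::local_tempdir()
  files <- exportNetwork(net, dir)
  expect_true(all(file.exists(files)))
  sif <- read.table(files[["sif"]], sep = "\t")
  expect_true(all(sif$V2 %in% c("direct", "indirect")))
  gr <- networkGraph(net)
  expect_equal(nrow(sif), igraph::ecount(gr))
  back <- importNetwork(files[["graphml"]])
  bg <- networkGraph(back)
  expect_setequal(igraph::V(bg)$name, igraph::V(gr)$name)
  expect_equal(igraph::ecount(bg), igraph::ecount(gr))
  expect_setequal(vapply(bridgePaths(back), paste, character(1),
                         collapse = ">"),
                  vapply(bridgePaths(net), paste, character(1),
                         collapse = ">"))
  expect_identical(back@componentSizes, net@componentSizes)
  expect_equal(hubs(back), hubs(net))
  # node attributes survive
  for (a in c("type", "extended", "fc_24h"))
    expect_equal(igraph::vertex_attr(bg, a)[match(igraph::V(gr)$name,
                                                  igraph::V(bg)$name)],
                 igraph::vertex_attr(gr, a))
  # empty network still exports valid files
  ee <- suppressWarnings(extractCoreSubnetwork(buildGraph(
    data.frame(from = "a", to = "b", score = 900)), character()))
  f0 <- exportNetwork(ee, dir, prefix = "empty")
  expect_true(file.exists(f0[["sif"]]))
  expect_identical(length(readLines(f0[["sif"]])), 0L)
})
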