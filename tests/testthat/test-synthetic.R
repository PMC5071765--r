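test_that("null design yields identical control and exposed spectra", {
  d <- nullNoiseDesign(effectMap = defaultEffectMap(0))
  sp <- simulateSpectra(d)
  n <- d@nPerGroup
  for (i in seq_len(n))
    expect_identical(sp[[i]]@intensity, sp[[n + i]]@intensity)
})

test_that("a single one-peak template puts the spectrum maximum at the peak", {
  lib <- data.frame(metabolite = "probe", center = 2.0, relIntensity = 1,
                    halfWidth = 0.002, baseLevel = 1)
  d <- nullNoiseDesign(effectMap = c(probe = 0))
  sp <- simulateSpectra(d, library = lib, baseline = NULL)
  s <- sp[[1]]
  expect_equal(s@ppm[which.max(s@intensity)], 2.0, tolerance = 1e-3)
})

test_that("unknown metabolite in the effect map is a named error", {
  d <- nullNoiseDesign(effectMap = c(unobtainium = 2))
  expect_error(simulateSpectra(d), "unobtainium")
})

test_that("generators are bit-reproducible under a fixed seed", {
  d <- mimicDesign(seed = 42)
  expect_identical(simulateSpectra(d)[[5]]@intensity,
                   simulateSpectra(d)[[5]]@intensity)
  expect_identical(simulateItraqTable(d), simulateItraqTable(d))
  expect_identical(igraph::as_data_frame(
                     networkGraph(simulateInteractome(d)$interactome)),
                   igraph::as_data_frame(
                     networkGraph(simulateInteractome(d)$interactome)))
})

test_that("noise-free group mean spectra differ only at perturbed peaks", {
  d <- nullNoiseDesign()   # 9 planted effects, zero stochastic terms
  sp <- simulateSpectra(d)
  n <- d@nPerGroup
  ctrl <- rowMeans(sapply(sp[seq_len(n)], function(s) s@intensity))
  expo <- rowMeans(sapply(sp[n + seq_len(n)], function(s) s@intensity))
  dif <- expo - ctrl
  lib <- defaultMetaboliteLibrary()
  perturbed <- lib[lib$metabolite %in% names(defaultEffectMap()), ]
  ppm <- sp[[1]]@ppm
  # within a perturbed peak core the difference is material ...
  core <- rep(FALSE, length(ppm))
  for (k in seq_len(nrow(perturbed)))
    core <- core | abs(ppm - perturbed$center[k]) < perturbed$halfWidth[k]
  expect_gt(min(abs(dif[core])), 1e-4)
  # ... and far from every perturbed peak it is Lorentzian-tail small
  far <- rep(TRUE, length(ppm))
  for (k in seq_len(nrow(perturbed)))
    far <- far & abs(ppm - perturbed$center[k]) > 0.25
  expect_lt(max(abs(dif[far])), 1e-3)
  expect_lt(max(abs(dif[far])), 0.01 * max(abs(dif[core])))
})

test_that("null iTRAQ design gives unit ratios and no differential calls", {
  d <- syntheticDesign(depFraction = 0, ratioNoiseSd = 0, seed = 3)
  it <- simulateItraqTable(d)
  rcols <- grep("^ratio_", names(it$table), value = TRUE)
  for (cc in rcols) expect_true(all(it$table[[cc]] == 1))
  expect_length(it$truth$depIds, 0)
  fd <- filterDeps(computeFoldChanges(quantFilter(it$table)))
  expect_true(all(lengths(fd$sets) == 0))
})

test_that("a large planted fold change passes the threshold rule everywhere", {
  # plant a single protein at the 17.39-scale fold change reported for
  # the universal stress protein and check it is called at every time point
  d <- syntheticDesign(nProteins = 20, depFraction = 1 / 20,
                       plantedFcRange = c(17.39, 17.39), ratioNoiseSd = 0,
                       seed = 5)
  it <- simulateItraqTable(d)
  fd <- filterDeps(computeFoldChanges(quantFilter(it$table)))
  planted <- it$truth$depIds
  for (tp in names(fd$sets)) expect_true(planted %in% fd$sets[[tp]])
})

test_that("differential calling recovers exactly the planted set at low noise", {
  d <- syntheticDesign(nProteins = 100, depFraction = 0.1,
                       plantedFcRange = c(3, 5), ratioNoiseSd = 0.02,
                       seed = 7)
  it <- simulateItraqTable(d)
  fd <- filterDeps(computeFoldChanges(quantFilter(it$table)))
  for (tp in names(fd$sets))
    expect_setequal(fd$sets[[tp]], it$truth$depIds)
})

test_that("interactome planting: isolated planted path is the bridge", {
  d <- syntheticDesign(nNodes = 10, nEdges = 0, nProteins = 10,
                       depFraction = 0.2,
                       plantedPaths = list(c("P1", "P2", "PW1")),
                       plantedModule = c("P1", "P3"),
                       plantedHubs = c("P1", "P3"), seed = 1)
  net <- simulateInteractome(d)
  br <- shortestPathsBridge(net$interactome, "P1", "PW1")
  expect_true(any(vapply(br$paths, identical, logical(1),
                         c("P1", "P2", "PW1"))))
})

test_that("an edgeless interactome reports every bridge query unreachable", {
  d <- syntheticDesign(nNodes = 10, nEdges = 0, nProteins = 10,
                       plantedPaths = list(), plantedModule = character(),
                       plantedHubs = character(), seed = 2)
  net <- simulateInteractome(d)
  br <- shortestPathsBridge(net$interactome, "P1", c("PW1", "M1"))
  expect_true(all(!br$pairs$reachable))
  expect_length(br$paths, 0)
})

test_that("planted paths must reference existing nodes", {
  d <- syntheticDesign(plantedPaths = list(c("P1", "NOSUCH", "PW1")))
  expect_error(simulateInteractome(d), "NOSUCH")
})

test_that("synthetic data export writes the full plain-text bundle", {
  dir <- withr::local_tempdir()
  d <- syntheticDesign(nPerGroup = 3, seed = 9)
  paths <- exportSyntheticData(d, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_identical(unlist(truth$plantedHubs), c("P1", "P2"))
  sp <- readSpectra(paths[["spectra"]])
  expect_length(sp, 6)
  expect_identical(sp[[1]]@group, "control")
})
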