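# shared factories for small, fast synthetic designs

# fully deterministic design: no spectral noise, no concentration or
# baseline scatter; planted effects remain exact
nullNoiseDesign <- function(seed = 1, effectMap = defaultEffectMap(), ...) {
  syntheticDesign(nPerGroup = 3, effectMap = effectMap, noiseSd = 0,
                  concCv = 0, baselineCv = 0, seed = seed, ...)
}

# the two-group biomarker-recovery study at its default conditions
mimicDesign <- function(seed = 1, ...) syntheticDesign(seed = seed, ...)

# small spectrum on a coarse axis for fast binning tests
flatSpectrum <- function(value = 2, from = 0, to = 10, by = 0.001,
                         id = "s1", group = "control") {
  ppm <- seq(from, to, by = by)
  Spectrum(ppm, rep(value, length(ppm)), id, group = group,
           timepoint = "24h")
}

# vectorized Floyd-Warshall all-pairs shortest hop counts (oracle)
floydWarshall <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n, dimnames = dimnames(adj))
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# hypergeometric upper-tail p by full enumeration of the pmf (oracle)
enumHyperP <- function(overlap, termSize, querySize, backgroundSize) {
  ks <- 0:min(termSize, querySize)
  pmf <- choose(termSize, ks) *
    choose(backgroundSize - termSize, querySize - ks) /
    choose(backgroundSize, querySize)
  sum(pmf[ks >= overlap])
}
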