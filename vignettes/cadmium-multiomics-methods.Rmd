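---
title: "Methods: multi-omics inference of a cadmium-response regulation network"
author: "cdomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics inference of a cadmium-response regulation network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`cdomics` implements the inference chain used to characterize heavy-metal
stress responses in bivalve gill tissue from paired ^1^H-NMR metabolomics
and iTRAQ proteomics:

1. **Spectral processing** — binning, water exclusion, total-area
   normalization, generalized-log transform (`buildBinMatrix()`).
2. **Chemometrics** — OPLS-DA with venetian-blind cross-validated Q²,
   CV-ANOVA, and biomarker calling by correlation-coded loadings
   (`fitOplsda()`, `coefficientLoadings()`,
   `callSignificantMetabolites()`).
3. **Proteomics** — replicate-ratio fold changes and differential calls
   (`quantFilter()`, `computeFoldChanges()`, `filterDeps()`,
   `intersectTimepoints()`).
4. **Mapping and enrichment** — best-homolog selection and
   hypergeometric term over-representation (`selectBestHomolog()`,
   `enrichTerms()`).
5. **Network integration** — scored-interactome construction,
   shortest-path bridging of differential proteins to pathway and
   metabolite nodes, core-subnetwork extraction and hub ranking
   (`buildGraph()`, `shortestPathsBridge()`, `extractCoreSubnetwork()`,
   `rankHubs()`).

A synthetic-data module (`syntheticDesign()`, `simulateSpectra()`,
`simulateItraqTable()`, `simulateInteractome()`) plants known effects at
every layer so that the whole chain is testable by parameter recovery
without access to raw instrument data.

```{r}
library(cdomics)
res <- runPipeline(runConfig(design = syntheticDesign(seed = 1)))
res$report$q2
```

# Spectral processing

Spectra arrive as two-column (ppm, intensity) series. Processing follows
the standard workflow for 500-MHz extract spectra:

* **Binning.** Left-closed right-open bins of width 0.005 ppm anchored
  at 0.2 ppm, covering 0.2–9.1 ppm. Each bin value is the exact
  integral of the piecewise-linear interpolant of the digitized
  spectrum (trapezoidal rule with interpolated bin-edge ordinates), so
  binning is exact for the data as digitized and invariant to the
  point density of the axis. Bins with no interior data points fall
  back to the same integral, which is then pure linear interpolation; a
  warning is raised.
* **Water exclusion.** Bins intersecting the open window 4.72–4.96 ppm
  are dropped entirely *before* normalization: the 0.005 grid aligns
  both window edges exactly, removing 48 of 1780 bins (1732 retained),
  and residual water area must not distort the total-area denominator.
  Dropping after normalization would leak water area into every other
  bin; a regression test asserts the implemented order.
* **Normalization.** Each row is divided by its total integrated area
  (dilution correction); rows then sum to one.
* **Variance stabilization.** The generalized logarithm
  `g(x) = log(x + sqrt(x^2 + lambda))`, which is defined at zero and
  tends to `log(2x)` as `lambda` tends to 0. The default `lambda` is
  1e-8 times the squared median of the normalized matrix — effectively
  a pure log for well-measured bins — chosen so that low-intensity
  peaks gain weight relative to the dominant resonances.

The processed object is a `BinMatrix`, a `SummarizedExperiment` with
bins as rows (`rowData$binCenter`) and samples as columns (`colData`:
sample id, group, time point). Column count depends only on the
processing parameters, never on the data.

# OPLS-DA and significance

The class contrast (exposed vs control, coded +1/−1) is modelled with
NIPALS partial least squares. `fitOplsda()` first removes `nOrtho`
(default 1) *orthogonal* components — directions of structured variation
uncorrelated with the class — by deflating `X` with components built
from `p − (wᵀp / wᵀw)·w`, then fits a single predictive component. The
predictive and orthogonal score vectors are mutually orthogonal by
construction (enforced by the class validity at 1e-8). The predictive
score sign is fixed so the exposed-group mean is positive, which makes
positive loadings correspond to metabolites elevated under exposure.

**Cross-validation.** Q² = 1 − PRESS/SSY with five-way *venetian-blind*
folds: sample *i* (in sample-sheet order) belongs to fold
`(i − 1) mod 5 + 1`. The fold assignment is deterministic and seedless;
if a training split would contain one class, folds are reassigned
round-robin within each class with a warning. Q² above 0.08 indicates a
model better than chance; values between 0.7 and 1.0 indicate a highly
robust model. Fitted models cap Q² at R²Y (cross-validated prediction
cannot beat the fit).

**CV-ANOVA.** Significance of the cross-validated model is assessed by
`F = ((SSY − PRESS)/d₁) / (PRESS/d₂)` with `d₁` the number of fitted
components (`nOrtho + 1` by default, configurable, since the reference
method is cited by name only) and `d₂ = n − d₁ − 1`; `p = 1` whenever
PRESS ≥ SSY.

**Biomarker calling.** For each bin, `r` is the Pearson correlation
between the processed bin values and the predictive scores (the
standard coefficient-coded loadings display). The significance cutoff
is the exact two-tailed critical value of the correlation coefficient,
`r_crit = sqrt(t*² / (t*² + n − 2))`; at α = 0.05 and n = 11 this is
the conventional 0.602. `criticalR()` always takes `n` explicitly —
the cutoff is a function of the sample count, not a constant. A
metabolite is called when any bin inside one of its assignment regions
(peak centers ± 0.0125 ppm) is significant; its direction is the sign
of `r` at its strongest significant bin; significant bins outside all
regions are reported as unassigned. `r` is computed against the
predictive scores rather than the raw class vector: with two balanced
classes the two are monotonically related, and scores are the standard
choice for coefficient plots.

# Proteomics

iTRAQ quantification arrives as two replicate treated/control ratios
per time point (the 8-plex 113–121 labelling quantified as channel
ratios). Rules:

* **Quantification filter** — at least 2 peptides, detected in both
  replicates, global FDR below 1% where provided.
* **Fold change** — the arithmetic mean of the two replicate ratios
  ("average ratio"; a geometric option is exposed in
  `depCriteria(foldChangeMean=)`).
* **Differential call** — fold change above 1.50 or below 0.67 *in any
  duplicate* (strict inequalities). "Any duplicate" is read literally:
  either replicate suffices; replicates that disagree in direction
  (one above 1.50, the other below 0.67) are excluded and logged as
  discordant rather than called both ways. The "corrected" fold change
  is taken as the bias-corrected ratio emitted upstream; no further
  correction is applied here.
* **Intersection** — `intersectTimepoints()` returns the k-way common
  set and all exclusive Venn region counts.

The package ships (as a plain-text fixture) the published table of
persistent large-fold-change proteins; every non-missing value in it
satisfies the 1.50/0.67 rule, while the table's own stricter caption
(">2 or <0.5 at all time points") is contradicted by one histone entry
at 0.53 and two missing 24-h values — the fixture preserves the table
as printed and a test documents the inconsistency without resolving it.

# Homolog mapping and enrichment

Proteins are mapped to a model-organism proteome by the rule: among the
10 best-ranked hits with e-value strictly below 1e-10, take the hit
with the highest percent identity; break ties by smaller e-value, then
lexicographic subject id; queries with no qualifying hit stay unmapped.
Hit rank defaults to e-value order when absent (the ordering of the
"best 10" is not fully specified upstream; bit-score ordering is
available via `homologyCriteria(rankBy=)`).

Term over-representation uses the one-sided hypergeometric tail
(Fisher's exact test, greater): enrichment is the scientific question,
and a two-sided option is exposed. P-values are Benjamini–Hochberg
adjusted — a deliberate substitution for the web-service EASE
correction, recorded here because the web service is out of scope. The
background universe is all quantified proteins that mapped to a
homolog, the standard choice when the source is silent.

# Network integration

Interactome edges carry combined scores on the 0–1000 convention; the
"default score setting" is concretized as combined score ≥ 400 (the
conventional medium-confidence default). Duplicate edges keep the
maximum score; self-loops are dropped; nodes are typed protein /
pathway / metabolite, with metabolites attached through pathway anchor
nodes (proteins connect to metabolism through pathways; metabolites
hang off them).

Bridging uses **unweighted** (hop-count) breadth-first shortest paths —
the upstream method names only "a shortest-path algorithm", so scores
enter solely through the edge cutoff. All shortest paths of length at
most `maxLen = 4` hops between each differential protein and each
pathway/metabolite node are retained (observed bridges in this class of
model span at most 4 edges; configurable). Non-differential
intermediates are tagged *extended* — the connector proteins pulled in
from the database.

The core regulation network is the largest connected component of the
subgraph induced by differential nodes plus extended nodes on retained
bridge paths. Edges present in the interactome are tagged `direct`; for
every stored bridge path whose endpoints lack a direct edge an
`indirect` edge is added (every indirect edge therefore corresponds to
a stored path — a class invariant). Hubs are ranked by degree, ties
broken by total |log fold change| across time points, then node id.
Export produces SIF, a node-attribute TSV and GraphML (bridging paths
embedded as a JSON graph attribute), and `importNetwork()` rebuilds the
object losslessly.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, not tuning knobs.

**Spectra.** Each sample is a sum of Lorentzian resonances from a
16-metabolite, 47-resonance template library (approximate literature
chemical shifts, half-width 0.002 ppm, broad glycogen anomerics),
plus a broad macromolecular baseline (12 humps, amplitudes 1.5–6% of
the unit peak scale) and additive Gaussian noise (SD 0.002, clipped at
zero since intensities are nonnegative). Metabolite concentrations are
log-normal — `base * exp(0.15 * delta * [exposed]) * exp(concCv * z)` —
so a planted effect `delta` shifts the exposed group by exactly `delta`
within-group standard deviations on the log scale, symmetrically for
up- and down-regulation under the pipeline's log-type transform (a
linear shift would be direction-asymmetric after the glog). The
default effect map plants the nine biomarkers of the cadmium-exposure
contrast: alanine, glutamine, succinate, glutamate and glycogen up;
leucine, aspartate, proline and acetoacetate down; |effect| = 2.

The within-group concentration CV (0.15), baseline-amplitude CV
(0.05, a single per-sample scale — extract-amount variation, the
classic rank-1 class-orthogonal structure an OPLS orthogonal component
removes), noise level, and library density were chosen once so that
the simulation reproduces the reference chemometric behaviour
(two groups of 10 separate with venetian-blind Q² above 0.8); they are
recorded in the design object, not asserted as measured values. Two
features of real spectra are deliberately *not* emulated: chemical-
shift drift between samples (upstream calibration is out of scope) and
peak-shape distortions from imperfect phasing — so passing tests
validate the inference chain, not robustness to misreferenced spectra.

**iTRAQ tables.** 100 proteins, 10% planted differential at fold
changes drawn from [2, 5] (direction random, redrawn per time point),
log-normal replicate noise (SD 0.05), Poisson peptide counts, 97%
replicate detection. Planted proteins always satisfy the
quantification filters, so recovery failures reflect the calling
rules, not an unquantifiable plant.

**Interactome.** 60 nodes (48 proteins, 6 pathway anchors, 6
metabolites), 150 random edges with scores uniform on [150, 999];
planted structure inserted as high-score edges: a two-hub double star
over the planted differential module, two planted protein–extended–
pathway bridge paths, and metabolite–pathway anchors. Random edges
that would directly shortcut a planted path's endpoints are resampled,
which guarantees the planted length-2 paths remain among the shortest
paths regardless of graph density; longer planted paths are supported
but can legitimately be bypassed in dense graphs.

# Numerical choices and degenerate inputs

* Bin-edge exclusion uses strict inequalities with a 1e-9 ppm guard
  against floating-point edge alignment.
* NIPALS stops (with a warning) when the weight norm collapses, i.e.
  beyond the rank of `X`; an all-flat matrix yields a degenerate model
  with zero scores, Q² = NA and CV-ANOVA p = 1 rather than an error,
  so null designs flow through the pipeline.
* Zero-variance bins get `r = 0` and are flagged, never NA.
* All-zero spectra are an error at normalization ("empty spectrum").
* Generators draw from seed offsets (seed, +1, +2, +3, +4 for spectra,
  iTRAQ, interactome, hits, annotations) so each data type is
  individually reproducible; everything downstream of generation is
  deterministic.
* Problem sizes used throughout validation (20 samples x 1732 bins,
  100 proteins, 60-node graphs, 20-seed recovery batteries) were
  chosen as the smallest sizes at which the statistical claims are
  meaningful at desk scale.

# Known limitations

* Numerical equivalence with commercial chemometrics suites is not a
  goal; conventions (component scaling, CV-ANOVA degrees of freedom)
  differ between implementations, and `d₁` is configurable for that
  reason.
* Whether the upstream PLS-DA acceptance thresholds (0.08; 0.7–1.0)
  also governed OPLS-DA model acceptance is not stated in the source
  method; this package computes and reports both Q² and CV-ANOVA p and
  leaves acceptance to the analyst.
* Reported sample counts upstream are ambiguous (the 0.602 cutoff
  implies n = 11 while the design names five biological replicates);
  `criticalR(alpha, n)` therefore never hard-codes a cutoff.
* Enrichment does not propagate annotations over an ontology graph;
  terms are flat sets.
* GO/KEGG term content, interactome content and the published
  dataset-dependent counts depend on external database versions and
  unreleased raw data, and are out of scope; the network logic is
  validated on planted synthetic structure instead.
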