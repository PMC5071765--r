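#' Default metabolite template library
#'
#' A small library of metabolite spectral templates for simulating gill
#' tissue extract spectra. One row per Lorentzian peak: `metabolite`,
#' `center` (ppm), `relIntensity` (relative peak amplitude),
#' `halfWidth` (half-width at half-maximum, ppm) and `baseLevel`
#' (baseline concentration in arbitrary units, repeated per peak).
#'
#' Chemical shifts are approximate literature positions for the major
#' resonances of common tissue-extract metabolites (amino acids, TCA
#' intermediates, osmolytes, energy-storage compounds), chosen so that
#' metabolites that may shift in opposite directions keep at least one
#' well-resolved peak. The library covers the nine key biomarkers of
#' Cd-exposure studies in bivalve gill (leucine, alanine, proline,
#' glutamate, glutamine, acetoacetate, succinate, aspartate, glycogen)
#' plus several typically unperturbed metabolites.
#'
#' @param halfWidth default peak half-width in ppm.
#' @return data.frame of peak templates.
#' @examples
#' lib <- defaultMetaboliteLibrary()
#' unique(lib$metabolite)
#' @export
defaultMetaboliteLibrary <- function(halfWidth = 0.002) {
  pk <- function(met, centers, rel, base) {
    data.frame(metabolite = met, center = centers, relIntensity = rel,
               halfWidth = halfWidth, baseLevel = base)
  }
  lib <- rbind(
    pk("leucine",   c(0.950, 0.960, 0.970, 1.700, 1.715),
                    c(0.6, 1.0, 0.6, 0.35, 0.35), 1.2),
    pk("alanine",   c(1.470, 1.485, 3.770), c(1.0, 1.0, 0.3), 1.5),
    pk("proline",   c(1.990, 2.005, 3.330, 3.340, 4.130),
                    c(0.5, 0.5, 0.4, 0.4, 0.35), 1.0),
    pk("glutamate", c(2.060, 2.080, 2.340, 2.355),
                    c(0.5, 0.5, 0.6, 0.6), 1.3),
    pk("glutamine", c(2.130, 2.145, 2.440, 2.455),
                    c(0.5, 0.5, 0.55, 0.55), 1.1),
    pk("acetoacetate", c(2.270, 2.280), c(0.9, 0.5), 0.6),
    pk("succinate", c(2.405, 2.415), c(0.8, 0.8), 0.9),
    pk("aspartate", c(2.660, 2.680, 2.790, 2.810),
                    c(0.5, 0.5, 0.5, 0.5), 0.8),
    pk("glycogen",  c(3.610, 3.650, 3.830, 5.400, 5.420),
                    c(0.4, 0.35, 0.3, 0.5, 0.4), 1.4),
    pk("lactate",   c(1.320, 1.335, 4.110), c(1.0, 1.0, 0.3), 1.0),
    pk("betaine",   c(3.260, 3.900), c(1.0, 0.25), 1.6),
    pk("taurine",   c(3.250, 3.420, 3.430), c(0.6, 0.6, 0.6), 1.4),
    pk("glycine",   c(3.550), c(1.0), 1.0),
    pk("hypotaurine", c(2.640, 3.350), c(0.7, 0.6), 0.7),
    pk("glucose",   c(3.400, 3.460, 3.530, 3.720, 3.890, 5.230),
                    c(0.3, 0.3, 0.3, 0.35, 0.3, 0.4), 1.1),
    pk("adenine",   c(8.200, 8.220, 8.510), c(0.4, 0.4, 0.4), 0.5))
  # glycogen anomeric resonances are broad
  lib$halfWidth[lib$metabolite == "glycogen" & lib$center > 5] <- 4 * halfWidth
  rownames(lib) <- NULL
  validateMetaboliteLibrary(lib)
  lib
}

validateMetaboliteLibrary <- function(library) {
  need <- c("metabolite", "center", "relIntensity", "halfWidth", "baseLevel")
  if (!all(need %in% names(library)))
    stop("metabolite library must have columns: ", paste(need, collapse = ", "))
  if (any(library$center < 0.2 | library$center > 9.1))
    stop("all peak centers must lie within [0.2, 9.1] ppm")
  if (any(library$halfWidth <= 0)) stop("half-widths must be > 0")
  if (any(library$relIntensity <= 0)) stop("relative intensities must be > 0")
  if (any(library$baseLevel < 0)) stop("base levels must be nonnegative")
  invisible(library)
}

#' Default broad-baseline profile
#'
#' Broad Lorentzian humps emulating the macromolecular and residual
#' lipid/protein envelope of tissue-extract spectra, which keeps every
#' spectral bin above the noise floor (as in real spectra). One row per
#' hump: `center`, `halfWidth`, `amplitude` (all relative to the
#' metabolite peak scale).
#'
#' @return data.frame of baseline humps.
#' @export
defaultBaselineProfile <- function() {
  data.frame(
    center    = c(0.9, 1.3, 2.0, 2.7, 3.2, 3.7, 4.2, 5.3, 6.5, 7.3, 8.2, 8.9),
    halfWidth = c(0.3, 0.4, 0.5, 0.4, 0.5, 0.4, 0.4, 0.6, 0.7, 0.6, 0.5, 0.4),
    amplitude = c(0.04, 0.06, 0.05, 0.04, 0.06, 0.05, 0.03, 0.03, 0.02,
                  0.025, 0.02, 0.015))
}

#' Assignment regions for metabolite calling
#'
#' Maps each metabolite to the ppm regions covered by its peaks
#' (center +/- `pad`), used to assign significant spectral bins to
#' metabolites.
#'
#' @param library a metabolite template library
#'   (see [defaultMetaboliteLibrary()]).
#' @param pad half-width of the assignment window around each peak
#'   center, in ppm. The default (0.0125) spans +/- 2.5 bins at the
#'   standard 0.005-ppm bin width.
#' @return data.frame with columns metabolite, low, high.
#' @export
metaboliteRegions <- function(library, pad = 0.0125) {
  validateMetaboliteLibrary(library)
  data.frame(metabolite = library$metabolite,
             low = library$center - pad,
             high = library$center + pad)
}
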