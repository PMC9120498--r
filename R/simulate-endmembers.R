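# Endmember spectra are built from a smooth vegetation template whose shape
# parameters evolve by Brownian motion along the phylogeny, so evolutionary
# divergence translates into spectral divergence in expectation.

# Template parameters: base value, Brownian sd per unit branch length, and
# the hard range the evolved value is clamped to. Ranges keep the rendered
# scenes vegetation-like (dark red band, bright NIR plateau) so NDVI and
# shade masks behave as they do on real canopies.
.endmemberParams <- data.frame(
  param = c("visBase", "greenAmp", "nirA", "edgePos", "waterDepth1",
            "waterDepth2", "swirDecay"),
  base  = c(0.045,     0.05,       0.45,   715,       0.70,
            0.85,       0.9),
  sd    = c(0.012,     0.02,       0.07,   8,         0.10,
            0.06,       0.25),
  lo    = c(0.015,     0.01,       0.25,   695,       0.40,
            0.60,       0.3),
  hi    = c(0.10,      0.12,       0.62,   735,       0.92,
            0.97,       1.8)
)

# Smooth vegetation-like reflectance on the wavelength grid (nm):
# low visible reflectance with a green-peak bump, a logistic red edge
# rising to a NIR plateau that decays into the SWIR, and Gaussian water
# absorption dips at ~980/1200/1450/1940 nm.
vegetationTemplate <- function(wavelengths, params) {
  wl <- wavelengths
  vis <- params[["visBase"]] +
    params[["greenAmp"]] * exp(-(wl - 550)^2 / (2 * 45^2))
  edge <- 1 / (1 + exp(-(wl - params[["edgePos"]]) / 12))
  decay <- exp(-params[["swirDecay"]] * pmax(wl - 1300, 0) / 1000)
  dips <- 1 -
    0.12 * exp(-(wl - 980)^2  / (2 * 40^2)) -
    0.18 * exp(-(wl - 1200)^2 / (2 * 45^2)) -
    params[["waterDepth1"]] * exp(-(wl - 1450)^2 / (2 * 55^2)) -
    params[["waterDepth2"]] * exp(-(wl - 1940)^2 / (2 * 75^2))
  spec <- vis * (1 - edge) + params[["nirA"]] * edge * decay * pmax(dips, 0.02)
  pmin(pmax(spec, 0), 1)
}

#' Fixed bare-soil endmember
#'
#' A smooth reflectance spectrum increasing from the visible into the SWIR
#' (bright soil, no red edge, no chlorophyll absorption), used by the scene
#' renderer for bare-ground pixels. Its NDVI is low (~0.1), so NDVI masking
#' can separate it from any vegetation mixture.
#'
#' @param wavelengths numeric, nm.
#' @return numeric reflectance in \[0, 1\].
#' @examples
#' s <- soilSpectrum(seq(400, 2400, by = 10))
#' range(s)
#' @export
soilSpectrum <- function(wavelengths) {
  wl <- wavelengths
  s <- 0.08 + 0.22 * (wl - 380) / (2510 - 380) +
    0.03 * exp(-(wl - 1700)^2 / (2 * 300^2)) -
    0.05 * exp(-(wl - 1940)^2 / (2 * 80^2)) -
    0.03 * exp(-(wl - 1450)^2 / (2 * 60^2))
  pmin(pmax(s, 0), 1)
}

#' Simulate species endmember spectra along a phylogeny
#'
#' Each species' endmember is a smooth vegetation template whose shape
#' parameters (visible baseline, green-peak amplitude, NIR plateau, red-edge
#' position, water-absorption depths, SWIR decay) evolve by Brownian motion
#' along the tree and are then clamped to fixed physiological ranges, so
#' closely related species have smaller spectral Euclidean distances in
#' expectation. Growth forms (`tree` vs `herb`) and crown-diameter/height
#' ranges are drawn per species for the scene renderer.
#'
#' @param phylogeny an ultrametric [ape::phylo], e.g. from
#'   [simulatePhylogeny()].
#' @param wavelengths working wavelength grid (nm), default the 426-band
#'   5 nm grid from 380 nm.
#' @param seed integer seed.
#' @param bmSd non-negative multiplier on the Brownian standard deviations;
#'   0 makes all species spectra identical to the template.
#' @param treeProb probability that a species is a canopy tree (at least one
#'   tree and, when `>= 2` species, one herb are enforced).
#' @return a [SpeciesLibrary-class].
#' @examples
#' tr <- simulatePhylogeny(6, seed = 1)
#' lib <- simulateEndmembers(tr, seq(400, 2400, by = 20), seed = 2)
#' range(reflectance(lib))
#' @export
simulateEndmembers <- function(phylogeny,
                               wavelengths = seq(380, 2505, by = 5),
                               seed = NULL, bmSd = 1, treeProb = 0.5) {
  stopIfNot(inherits(phylogeny, "phylo"), "'phylogeny' must be an ape phylo")
  stopIfNot(length(bmSd) == 1L && bmSd >= 0, "'bmSd' must be >= 0")
  n <- length(phylogeny$tip.label)
  withSeed(seed, {
    pars <- .endmemberParams
    traits <- matrix(NA_real_, n, nrow(pars),
                     dimnames = list(phylogeny$tip.label, pars$param))
    for (j in seq_len(nrow(pars))) {
      sig <- bmSd * pars$sd[j]
      tr <- if (sig > 0)
        ape::rTraitCont(phylogeny, model = "BM", sigma = sig,
                        root.value = pars$base[j])
      else
        stats::setNames(rep(pars$base[j], n), phylogeny$tip.label)
      traits[, j] <- pmin(pmax(tr[phylogeny$tip.label], pars$lo[j]),
                          pars$hi[j])
    }
    spectra <- t(apply(traits, 1L, function(p)
      vegetationTemplate(wavelengths, as.list(p))))
    colnames(spectra) <- NULL

    form <- ifelse(stats::runif(n) < treeProb, "tree", "herb")
    if (!any(form == "tree")) form[sample.int(n, 1L)] <- "tree"
    if (n >= 2L && !any(form == "herb"))
      form[sample.int(n, 1L)] <- "herb"

    crownMid <- ifelse(form == "tree", stats::runif(n, 2.5, 6), 0.3)
    crownRange <- cbind(min = crownMid * 0.7, max = crownMid * 1.3)
    heightMid <- ifelse(form == "tree", stats::runif(n, 8, 22),
                        stats::runif(n, 0.2, 1.5))
    heightRange <- cbind(min = heightMid * 0.8, max = heightMid * 1.2)
    rownames(crownRange) <- rownames(heightRange) <- phylogeny$tip.label

    new("SpeciesLibrary", spectra = spectra,
        wavelengths = as.numeric(wavelengths),
        growthForm = form, crownRange = crownRange,
        heightRange = heightRange)
  })
}
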