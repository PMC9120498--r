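# Fixture builders shared across tests. Everything is generated in code;
# the coarse 101-band grid keeps module tests fast while spanning the full
# 400-2400 nm working range (NDVI, shade and water windows all populated).

wlCoarse <- seq(400, 2400, by = 20)

# A small species library on an arbitrary grid.
makeTestLibrary <- function(nSpecies = 6, wl = wlCoarse, seed = 1,
                            treeProb = 0.5) {
  tr <- simulatePhylogeny(max(nSpecies, 2), seed = seed)
  lib <- simulateEndmembers(tr, wl, seed = seed + 1, treeProb = treeProb)
  list(tree = tr, lib = lib)
}

# Manual single-species library (the simulator enforces >= 2 tips).
monocultureLibrary <- function(wl = wlCoarse, form = "tree") {
  spectra <- matrix(specDiv:::vegetationTemplate(wl, as.list(setNames(
    specDiv:::.endmemberParams$base, specDiv:::.endmemberParams$param))),
    nrow = 1, dimnames = list("sp01", NULL))
  new("SpeciesLibrary", spectra = spectra, wavelengths = wl,
      growthForm = form,
      crownRange = matrix(c(3, 5), 1, 2, dimnames = list("sp01", NULL)),
      heightRange = matrix(c(8, 12), 1, 2, dimnames = list("sp01", NULL)))
}

# A rendered small scene plus its simulation inputs.
makeTestScene <- function(nPlots = 6, nSpecies = 6, seed = 1,
                          gradientStrength = 1, noiseSd = 0.005,
                          shadeFraction = 0.1, soilFraction = 0.05,
                          wl = wlCoarse, plotSide = 20) {
  fix <- makeTestLibrary(nSpecies, wl, seed)
  cm <- simulateCommunities(nPlots, fix$lib, gradientStrength,
                            seed = seed + 10)
  cfg <- sceneConfig(nPlots = nPlots, plotSide = plotSide, wavelengths = wl,
                     gradientStrength = gradientStrength, noiseSd = noiseSd,
                     shadeFraction = shadeFraction,
                     soilFraction = soilFraction)
  scene <- renderScene(cm, fix$lib, cfg, seed = seed + 20)
  c(fix, list(cm = cm, cfg = cfg, scene = scene))
}

# Star phylogeny with k tips, depth 1.
starTree <- function(k) {
  ape::read.tree(text = paste0("(", paste0(sprintf("sp%02d:1", seq_len(k)),
                                           collapse = ","), ");"))
}

# Random stem map on a plot.
randomStemMap <- function(nTrees, plotSide = 20, dRange = c(2, 6),
                          hRange = c(5, 25)) {
  data.frame(species = sample(sprintf("sp%02d", 1:3), nTrees, replace = TRUE),
             x_m = runif(nTrees, 0, plotSide),
             y_m = runif(nTrees, 0, plotSide),
             crown_diameter_m = runif(nTrees, dRange[1], dRange[2]),
             height_m = runif(nTrees, hRange[1], hRange[2]))
}
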