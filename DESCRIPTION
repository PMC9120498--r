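Package: specDiv
Title: Spectral Alpha- and Beta-Diversity of Plant Communities from
    Imaging Spectroscopy
Version: 0.99.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes spectral diversity from hyperspectral surface
    reflectance imagery and relates it to plant taxonomic and phylogenetic
    diversity. Implements water-band and spectrum-tail masking, NDVI and
    near-infrared shade masks with a minimum valid-pixel plot rule,
    brightness normalization, pooled principal component analysis with
    distance-preserving (type I) scaling, per-plot spectral variance
    (spectral alpha-diversity), Euclidean distances among plot mean
    spectra (spectral beta-diversity), top-of-canopy cover from
    stem-mapped trees with height-ranked crown occlusion, understory
    rescaling, species richness, Shannon index, phylogenetic species
    evenness, Hellinger beta-diversity, distance-distance regressions,
    co-inertia analysis with a Monte-Carlo permutation test, and
    regressions stratified by leaf area index. A synthetic-scene
    generator produces georeferenced reflectance cubes, stem maps,
    percent-cover inventories, phylogenies and leaf area index with
    known ground truth so every stage can be verified end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
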