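---
title: "Spectral alpha- and beta-diversity of plant communities: methods and design"
author: "specDiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral alpha- and beta-diversity of plant communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specDiv)
```

## The problem

Imaging spectrometers measure surface reflectance in hundreds of narrow
bands. Because plant species differ in leaf chemistry, structure and
phenology, spatial variation in canopy reflectance carries information
about the variation in species composition on the ground. `specDiv`
implements a pipeline that quantifies this link at two scales:

* **alpha (within plot)** — the spectral variance among the 1 m pixels of a
  20 m × 20 m vegetation plot (`SD_alpha`) against plot-level species
  richness, Shannon index and phylogenetic species evenness (PSE);
* **beta (among plots)** — Euclidean distances among plot mean spectra
  against Hellinger distances among plot species compositions, compared by
  distance–distance regression and by co-inertia analysis with a
  Monte-Carlo permutation test.

Real campaigns of this kind consume multi-gigabyte airborne mosaics. To
make every stage verifiable on a desk, the package ships a synthetic-scene
generator that emulates the four field inputs — a georeferenced reflectance
cube, stem-mapped tree tables, understory percent-cover inventories and
per-plot leaf area index (LAI) — with fully known ground truth and
controllable compositional turnover.

## The spectral workflow

**Masking.** Bands at ≤ 400 nm and ≥ 2400 nm and inside the atmospheric
water-vapour windows 1340–1445 nm and 1790–1955 nm are removed
(`dropBadBands()`). Non-vegetated pixels are excluded with an NDVI mask and
shaded pixels with a near-infrared shade mask, the mean reflectance over
752–1048 nm (`computeNDVI()`, `computeNIRShadeIndex()`). Thresholds are
inclusive (`≥`), site-specific for NDVI (0.2 for sparse to 0.8 for dense
vegetation) and vegetation-type-specific for shade (forest 0.18, shrubland
0.20, grassland 0.22). A plot enters the analysis only if at least 50% of
its pixels pass both masks — read inclusively, so exactly 200 of 400
passing pixels keeps the plot. The NDVI band windows are not fixed by
convention at 5 nm resolution; the defaults (red 650–680 nm, NIR
780–800 nm) are a standard broadband choice and are configurable. Masks are
evaluated on the original reflectance before band exclusion; both index
windows survive the exclusion, so the order only matters if a user narrows
the retained range.

**Normalization.** Each retained pixel spectrum is divided by its Euclidean
norm (`brightnessNormalize()`). This removes overall illumination
differences — a shaded spectrum and its unshaded original become identical —
and is idempotent.

**PCA with distance-preserving scaling.** One PCA is fitted per site on the
pooled pixels of all retained plots (`fitPooledPCA()`): distances among
plots must live in a single feature space, so fitting per plot would be
incoherent. "Type I" scaling is operationalized as: centre the band
columns on the pooled mean, do not standardize, and score pixels by
projection onto unit eigenvectors, which preserves Euclidean distances.
Components are retained until more than 95% of total variance is
explained. The eigendecomposition uses the band covariance matrix when
bands ≤ pixels and the pixel Gram matrix otherwise; both routes agree to
numerical tolerance and are cross-checked in the tests.

**Diversity metrics.** `SD_alpha` is the mean squared deviation of pixel
scores from their plot mean, summed over retained components — equivalently
the sum of the biased per-component variances. It is rotation-invariant and
obeys the law of total variance: the pooled site variance equals the
pixel-weighted mean of within-plot `SD_alpha` plus the among-plot centroid
term. Spectral beta-diversity is the Euclidean distance among plot mean
spectra (`plotMeanSpectra()`, `spectralBetaDistances()`). Mean spectra are
computed from the brightness-normalized reflectance in band space — the
same input as the PCA; computing them in retained PC space would give the
same distances up to the discarded < 5% of variance.

## The plant-diversity workflow

**Top-of-canopy cover.** Field inventories report understory cover
(plants < 3 m) per plot and stem-mapped trees (location, crown diameter,
height). To compare with imagery, which sees the canopy from above, tree
crowns are modelled as flat discs and rasterized on a sub-pixel grid
(default 0.1 m) with height-ranked occlusion: every cell belongs to the
tallest crown covering it (`visibleCrownCover()`). Ties in height are
broken by record order — the ranking variable is height alone, so ties are
arbitrary and the rule just makes them deterministic. Understory
percentages are then rescaled to the open fraction `1 - f` and added
(`combineCover()`). Rasterization rather than exact circular-arrangement
geometry keeps the computation robust; it converges to the exact
polygon-clipping solution as the resolution shrinks, which the test suite
verifies against an independent exact oracle.

**Metrics.** Richness counts species with positive cover; the Shannon
index is `−Σ p log p` in nats. PSE uses the phylogenetic correlation
matrix `C` of a depth-normalized ultrametric tree (`phyloCovariance()`,
computed by direct traversal):

`PSE = (M Σ mᵢCᵢᵢ − mᵀCm) / (M² − Σ mᵢ²)`, `M = Σ mᵢ`.

This denominator makes PSE exactly 1 on a star phylogeny for *any*
abundances and reduces exactly to PSV under equal abundances. A widely
used implementation divides by `M² − M·mean(m)` instead; the two coincide
for equal abundances (where we cross-check against it) but only the form
above has both closed-form limits, so it is the one implemented.
Replicated-phylogeny averaging is supported by passing a list of trees.
Taxonomic beta-diversity is the Hellinger distance: Euclidean distance
among rows of `sqrt(cover / rowSum)`, bounded by `√2` and invariant to row
totals.

## Statistics

`distanceRegression()` fits OLS of spectral on taxonomic distance over
unordered plot pairs (or over per-plot mean distances). Inference is the
standard two-sided slope t-test applied to the pairs as if independent —
the field's practice, kept for fidelity even though pairs sharing a plot
are dependent; a Mantel-style permutation option (`mantel = TRUE`) is
provided off by default for users who want dependence-respecting
inference. `pooledDistanceRegression()` pools pairs across sites.

`coinertia()` measures two-table concordance: with both tables
column-centred under uniform row weights, the co-inertia eigenvalues are
the squared singular values of the cross-covariance `t(Y)X/n`, the total
co-inertia their sum, and RV the total normalized by the Frobenius norms
of the self-covariances. `coinertiaTest()` permutes the rows of Y (999
permutations by default) and reports `p = (1 + #{perm ≥ obs})/(nPerm+1)`;
the permutation statistic reduces to the squared Frobenius norm of the
permuted cross-covariance, so no decomposition is needed inside the loop.

How much "variation in the inventories is explained by the spectra" has no
canonical co-inertia operationalization. `varianceExplained()` implements
one plausible, explicitly non-canonical choice: a redundancy-style
statistic — regress Y on the plot scores of X along the first k co-inertia
axes and report explained over total sum of squares. It is 1 for `Y = X`
with all axes, 0 for orthogonal tables, and non-decreasing in k. With few
plots it saturates (k ≥ n−1 spans the whole row space), so the pipeline
reports the 2-axis version, the plane an ordination plot would show.

`laiClassRegressions()` stratifies plots into LAI classes — default bounds
`[0.13, 0.634], (0.634, 1.183], (1.183, 1.84], (1.84, 3.80]`, the first
class closed on the left — and fits per class and metric an OLS of the
plant metric on `SD_alpha`.

## The synthetic-scene generator

The generator is first-class, tested code, and its defaults define the
study conditions used throughout the tests: 20 plots of 20 m × 20 m at
1 m pixels, 426 bands from 380 nm at 5 nm spacing, additive sensor noise
sd 0.005 reflectance, 10% shaded pixels (multiplicative factor 0.1), 5%
bare-soil pixels, total plant cover 90%.

* `simulatePhylogeny()` draws a coalescent tree (pairwise joining,
  exponential waiting times) rescaled to depth 1.
* `simulateEndmembers()` builds each species' reflectance from a smooth
  vegetation template — low visible reflectance with a green-peak bump, a
  logistic red edge rising to a NIR plateau, water-absorption dips, SWIR
  decay — whose parameters evolve by Brownian motion along the tree and are
  clamped to physiological ranges. Related species therefore have similar
  spectra in expectation, echoing the observation that spectral
  dissimilarity tracks evolutionary divergence. No field-spectra statistics
  constrain these shapes; the generator's claims are limited to its tested
  invariants (range, smoothness, phylogenetic signal), not radiometric
  realism — no radiative transfer, atmosphere, BRDF or topography.
* `simulateCommunities()` places plots evenly on a 1-d gradient; species
  respond with Gaussian niches (random optima and widths) raised to the
  `gradientStrength` power, times log-normal baselines and per-plot noise.
  `gradientStrength = 0` removes the niche term entirely, making
  communities exchangeable; 1 is the default strong-turnover setting.
* `renderScene()` realizes tree cover as randomly placed circular crowns
  (clipped to the plot; placement never fails, overlap is allowed),
  rasterizes height-ranked ownership on a 4× sub-pixel grid, fills the open
  area of each pixel with the plot's understory mixture, draws whole-pixel
  bare-soil and shade indicators as independent Bernoulli flags, and adds
  truncated Gaussian noise. Per-plot LAI increases deterministically (up to
  small noise) with vegetation and crown fraction, spanning roughly
  0.13–3.8. The soil endmember is a fixed bright, increasing spectrum so
  NDVI separates it cleanly from any vegetation mixture; the whole-pixel
  soil/shade design makes mask recovery exactly testable.

What the generator deliberately does **not** emulate: sub-pixel soil
mixtures, within-species spectral variability, vertical canopy structure,
sensor PSF and georeferencing error, understory growing under crowns being
partially visible through gaps. Passing tests therefore demonstrate the
correctness and calibration of the *computations*, not that real airborne
imagery would yield the same effect sizes.

## Null models and calibration

In any generative model where the image is rendered from the same
communities that feed the inventory, spectral and taxonomic distances are
positively coupled at *any* gradient strength — pixels are mixtures of
species endmembers, so compositional noise alone creates association. A
"no-gradient" run is therefore not a null for the spectral–taxonomic
relationship. The calibration tests instead pair tables from
*independently simulated* datasets (both at `gradientStrength = 0`): the
co-inertia permutation test then rejects at the nominal 5% rate, and the
distance regression's Mantel permutation option does the same. The naive
t-test on distance pairs, by contrast, is *anticonservative* under this
matrix-structured null (it claims one degree of freedom per pair while the
effective information is roughly one per plot); the acceptance script
reports its realized null rejection rate alongside the calibrated ones
rather than hiding it, and the calibration assertions in the test suite
are made on the permutation tests, which are exact by construction. On coupled data the question is effect size, not
existence — which is what the naive fit is reported for.

## Numerical choices and edge cases

* Determinism: every stochastic operation takes an explicit seed and
  restores the caller's RNG state; the pipeline derives per-stage seeds
  from one root seed, and equal config + seed yields bit-identical output
  manifests.
* Zero-norm pixels are dropped with a warning before normalization;
  all-zero cover rows are excluded from the Hellinger transform; PSE and
  Shannon are reported missing for communities below 2 (respectively 1)
  species; a zero-variance regressor yields a missing slope, not an error.
* Plot membership uses pixel-centre containment with half-open cells, so
  every pixel belongs to at most one plot.
* Water windows and index windows are closed intervals; thresholds are
  inclusive.
* PCA eigenvalues are clipped at 0 to absorb negative round-off;
  `varianceTarget = 1` retains all components above `1e-12` of the largest.
* Problem sizes in the tests are chosen to keep the full suite and the
  acceptance script inside a few minutes: sites of 5–20 plots, libraries
  of 6–12 species, coarse 101-band grids for module tests and the full
  426-band grid for end-to-end replicate studies (100 seeds).

## Worked example

```{r example, eval = FALSE}
tr  <- simulatePhylogeny(10, seed = 1)
lib <- simulateEndmembers(tr, seed = 2)
cm  <- simulateCommunities(20, lib, gradientStrength = 1, seed = 3)
sc  <- renderScene(cm, lib, sceneConfig(), seed = 4)

ext <- extractSitePixels(sceneCube(sc), maskConfig(), "forest",
                         ndviThreshold = 0.3)
pix <- lapply(ext$pixels, brightnessNormalize)
pca <- fitPooledPCA(pix, 0.95)
spectralAlpha(pca)

beta <- spectralBetaDistances(plotMeanSpectra(pix))
taxb <- taxonomicBetaDistances(sceneCover(sc)[rownames(beta), ])
distanceRegression(beta, taxb)
coinertiaTest(plotMeanSpectra(pix),
              hellingerTransform(sceneCover(sc)[rownames(beta), ]),
              nPerm = 999, seed = 5)
```

## Known limitations

* The naive OLS inference on distance pairs inherits the field's
  anticonservatism under dependence; use `mantel = TRUE` when inference
  matters.
* `varianceExplained()` is one of several defensible operationalizations
  and is labelled as such.
* Crown geometry is two-dimensional; no account of crown transparency or
  vertical overlap order beyond total height.
* The generator's endmember spectra are caricatures; absolute values of
  spectral diversity are not comparable with real sensors.
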