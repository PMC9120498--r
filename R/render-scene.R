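#' Scene configuration
#'
#' Validated parameter set for the synthetic scene renderer. Defaults follow
#' the survey design the package emulates: 20 m x 20 m plots sampled at 1 m
#' pixels, and a 426-band wavelength grid from 380 nm at 5 nm spacing.
#'
#' @param nPlots number of plots in the scene.
#' @param plotSide plot edge length in metres; must be an integer multiple
#'   of `pixelSize`.
#' @param pixelSize pixel edge length in metres.
#' @param wavelengths working wavelength grid (nm).
#' @param gradientStrength non-negative compositional-turnover strength
#'   passed to [simulateCommunities()].
#' @param noiseSd standard deviation of additive Gaussian sensor noise on
#'   reflectance (default 0.005).
#' @param shadeFraction fraction of pixels flagged as shaded (spectrum
#'   multiplied by `shadeFactor`).
#' @param soilFraction fraction of pixels rendered as pure bare soil.
#' @param shadeFactor multiplicative factor applied to shaded pixels
#'   (default 0.1).
#' @param subsample integer crown-rasterization supersampling factor per
#'   pixel edge (default 4, i.e. 16 subcells per 1 m pixel).
#' @param totalCover per-plot total percent cover target for
#'   [simulateCommunities()].
#' @param seed default seed used by [renderScene()] when none is given.
#' @return a validated list of class `SceneConfig`.
#' @examples
#' cfg <- sceneConfig(nPlots = 4, wavelengths = seq(400, 2400, by = 20))
#' @export
sceneConfig <- function(nPlots = 20L, plotSide = 20, pixelSize = 1,
                        wavelengths = seq(380, 2505, by = 5),
                        gradientStrength = 1, noiseSd = 0.005,
                        shadeFraction = 0.10, soilFraction = 0.05,
                        shadeFactor = 0.1, subsample = 4L,
                        totalCover = 90, seed = NULL) {
  nPlots <- checkCount(nPlots, "nPlots")
  stopIfNot(plotSide > 0 && pixelSize > 0 &&
              abs(plotSide / pixelSize - round(plotSide / pixelSize)) < 1e-9,
            "'plotSide' must be a positive multiple of 'pixelSize'")
  stopIfNot(!is.unsorted(wavelengths, strictly = TRUE),
            "'wavelengths' must be strictly increasing")
  for (f in c(shadeFraction, soilFraction, shadeFactor))
    stopIfNot(f >= 0 && f <= 1, "fractions must lie in [0, 1]")
  stopIfNot(gradientStrength >= 0, "'gradientStrength' must be >= 0")
  stopIfNot(noiseSd >= 0, "'noiseSd' must be >= 0")
  subsample <- checkCount(subsample, "subsample")
  structure(list(nPlots = nPlots, plotSide = plotSide, pixelSize = pixelSize,
                 wavelengths = as.numeric(wavelengths),
                 gradientStrength = gradientStrength, noiseSd = noiseSd,
                 shadeFraction = shadeFraction, soilFraction = soilFraction,
                 shadeFactor = shadeFactor, subsample = subsample,
                 totalCover = totalCover, seed = seed),
            class = "SceneConfig")
}

# Height-ranked crown ownership on a subcell grid for one plot.
# Returns an integer matrix (0 = open, i = index of owning tree row) with
# ties in height broken by tree record order (first record wins).
crownOwnership <- function(trees, plotSide, res) {
  n <- round(plotSide / res)
  centers <- (seq_len(n) - 0.5) * res
  owner <- matrix(0L, n, n)     # [row = y, col = x]
  height <- matrix(-Inf, n, n)
  for (i in seq_len(nrow(trees))) {
    r <- trees$crown_diameter_m[i] / 2
    cx <- trees$x_m[i]; cy <- trees$y_m[i]
    xs <- which(abs(centers - cx) <= r)
    ys <- which(abs(centers - cy) <= r)
    if (!length(xs) || !length(ys)) next
    dx2 <- (centers[xs] - cx)^2
    dy2 <- (centers[ys] - cy)^2
    inside <- outer(dy2, dx2, "+") <= r^2
    h <- trees$height_m[i]
    sub <- height[ys, xs, drop = FALSE]
    upd <- inside & (h > sub)
    if (any(upd)) {
      sub[upd] <- h
      height[ys, xs] <- sub
      osub <- owner[ys, xs, drop = FALSE]
      osub[upd] <- i
      owner[ys, xs] <- osub
    }
  }
  owner
}

# Aggregate a subcell indicator matrix to per-pixel fractions.
# m: (pp*sub) x (pp*sub) logical/numeric; returns pp x pp means.
blockMean <- function(m, sub) {
  pp <- nrow(m) / sub
  dim(m) <- c(sub, pp, sub, pp)
  apply(m, c(2L, 4L), mean)
}

# Place crowns for one plot: per tree species, crowns are added (stem
# uniform in the plot, diameter/height uniform in the species ranges) until
# the summed disc area reaches the species' target cover. Crowns may extend
# past the plot edge (clipped later by the ownership grid); placement never
# fails.
placeCrowns <- function(coverRow, library, plotSide) {
  area <- plotSide^2
  out <- list()
  treeSp <- rownames(library@spectra)[library@growthForm == "tree"]
  for (sp in treeSp) {
    target <- coverRow[[sp]] / 100 * area
    dmin <- library@crownRange[sp, 1L]
    if (target < 0.25 * pi * (dmin / 2)^2) next
    placed <- 0
    while (placed < target) {
      d <- stats::runif(1L, library@crownRange[sp, 1L],
                        library@crownRange[sp, 2L])
      h <- stats::runif(1L, library@heightRange[sp, 1L],
                        library@heightRange[sp, 2L])
      out[[length(out) + 1L]] <-
        data.frame(species = sp,
                   x_m = stats::runif(1L, 0, plotSide),
                   y_m = stats::runif(1L, 0, plotSide),
                   crown_diameter_m = d, height_m = h)
      placed <- placed + pi * (d / 2)^2
    }
  }
  if (!length(out))
    return(data.frame(species = character(), x_m = numeric(),
                      y_m = numeric(), crown_diameter_m = numeric(),
                      height_m = numeric()))
  do.call(rbind, out)
}

#' Render a synthetic hyperspectral scene
#'
#' Realizes a community matrix as a georeferenced reflectance cube with
#' known ground truth. Tree-species cover becomes circular crowns (stems
#' uniform in the plot, crowns clipped to the plot for cover accounting)
#' rasterized with height-ranked occlusion; the open area of every pixel is
#' filled with the plot's herbaceous understory mixture. Each pixel spectrum
#' is the area-weighted mixture of the visible species endmembers; a random
#' subset of pixels is rendered as pure bare soil, another as shaded
#' (spectrum times `shadeFactor`), and additive Gaussian noise truncated to
#' \[0, 1\] is applied last. Per-plot leaf area index increases with
#' vegetation cover. Plots are tiled on a square mosaic; grid slots beyond
#' `nPlots` are bare soil.
#'
#' @param communities result of [simulateCommunities()] (list with `cover`
#'   and `gradient`), or a plots x species percent-cover matrix.
#' @param library the [SpeciesLibrary-class] the communities refer to.
#' @param config a [sceneConfig()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return a [SyntheticScene-class].
#' @examples
#' tr <- simulatePhylogeny(5, seed = 1)
#' lib <- simulateEndmembers(tr, seq(400, 2400, by = 100), seed = 1)
#' cm <- simulateCommunities(4, lib, seed = 2)
#' sc <- renderScene(cm, lib, sceneConfig(nPlots = 4,
#'   wavelengths = seq(400, 2400, by = 100)), seed = 3)
#' sc
#' @export
renderScene <- function(communities, library, config = sceneConfig(),
                        seed = config$seed) {
  if (is.matrix(communities))
    communities <- list(cover = communities,
                        gradient = stats::setNames(
                          rep(NA_real_, nrow(communities)),
                          rownames(communities)))
  cover <- communities$cover
  stopIfNot(is(library, "SpeciesLibrary"), "'library' must be a SpeciesLibrary")
  stopIfNot(identical(colnames(cover), rownames(library@spectra)),
            "community species must match the library species ids")
  stopIfNot(identical(as.numeric(config$wavelengths),
                      as.numeric(library@wavelengths)),
            "config and library wavelength grids differ")

  nPlots <- nrow(cover)
  pp <- round(config$plotSide / config$pixelSize)  # pixels per plot edge
  sub <- config$subsample
  wl <- config$wavelengths
  nb <- length(wl)
  species <- rownames(library@spectra)
  herb <- species[library@growthForm == "herb"]
  soil <- soilSpectrum(wl)

  gridCols <- ceiling(sqrt(nPlots))
  gridRows <- ceiling(nPlots / gridCols)
  nrowPx <- gridRows * pp
  ncolPx <- gridCols * pp

  withSeed(seed, {
    values <- array(rep(soil, each = nrowPx * ncolPx),
                    c(nrowPx, ncolPx, nb))
    dominant <- matrix("soil", nrowPx, ncolPx)
    shadeFlag <- matrix(FALSE, nrowPx, ncolPx)
    soilFlag <- matrix(TRUE, nrowPx, ncolPx)
    plots <- data.frame(plot_id = rownames(cover),
                        xmin = NA_real_, ymin = NA_real_,
                        xmax = NA_real_, ymax = NA_real_)
    treeList <- vector("list", nPlots)
    trueCover <- matrix(0, nPlots, length(species),
                        dimnames = dimnames(cover))
    understory <- matrix(0, nPlots, length(herb),
                         dimnames = list(rownames(cover), herb))
    lai <- numeric(nPlots)

    for (p in seq_len(nPlots)) {
      gr <- (p - 1L) %/% gridCols   # grid row (0-based, from bottom)
      gc <- (p - 1L) %% gridCols
      x0 <- gc * config$plotSide
      y0 <- gr * config$plotSide
      plots[p, 2:5] <- c(x0, y0, x0 + config$plotSide, y0 + config$plotSide)

      herbCov <- cover[p, herb]
      herbRel <- if (length(herb) && sum(herbCov) > 0)
        herbCov / sum(herbCov) else stats::setNames(numeric(length(herb)), herb)

      trees <- placeCrowns(stats::setNames(as.numeric(cover[p, ]),
                                           colnames(cover)),
                           library, config$plotSide)
      owner <- crownOwnership(trees, config$plotSide,
                              config$pixelSize / sub)

      # per-pixel crown fraction by species, clipped to the plot
      fracPix <- matrix(0, pp * pp, length(species),
                        dimnames = list(NULL, species))
      if (nrow(trees)) {
        for (sp in unique(trees$species)) {
          idx <- which(trees$species == sp)
          fracPix[, sp] <- as.vector(blockMean(
            matrix(as.numeric(owner %in% idx), nrow(owner)), sub))
        }
      }
      fCrownPix <- rowSums(fracPix)             # per pixel, column-major
      fCrown <- mean(fCrownPix)                 # plot crown fraction
      openPix <- 1 - fCrownPix
      if (length(herb))
        fracPix[, herb] <- fracPix[, herb] +
          outer(openPix, as.numeric(herbRel))

      spec <- fracPix %*% library@spectra       # pixels x bands

      # ground truth for the plot
      treeVis <- colMeans(fracPix[, species, drop = FALSE]) * 100
      treeVis[herb] <- 0
      comb <- treeVis
      if (length(herb))
        comb[herb] <- comb[herb] + as.numeric(herbRel) * (1 - fCrown) * 100
      trueCover[p, ] <- comb
      if (length(herb)) understory[p, ] <- herbRel * 100

      # whole-pixel soil and shade draws
      nPix <- pp * pp
      isSoil <- stats::runif(nPix) < config$soilFraction
      isShade <- stats::runif(nPix) < config$shadeFraction
      spec[isSoil, ] <- rep(soil, each = sum(isSoil))
      spec[isShade, ] <- spec[isShade, , drop = FALSE] * config$shadeFactor
      if (config$noiseSd > 0)
        spec <- spec + matrix(stats::rnorm(length(spec), 0, config$noiseSd),
                              nrow(spec))
      spec <- pmin(pmax(spec, 0), 1)

      dom <- species[max.col(fracPix, ties.method = "first")]
      dom[rowSums(fracPix) == 0] <- "soil"
      dom[isSoil] <- "soil"

      rows <- gr * pp + seq_len(pp)
      cols <- gc * pp + seq_len(pp)
      # pixel vectors are column-major within the plot: index = (col-1)*pp+row
      values[rows, cols, ] <- array(spec, c(pp, pp, nb))
      dominant[rows, cols] <- matrix(dom, pp, pp)
      shadeFlag[rows, cols] <- matrix(isShade, pp, pp)
      soilFlag[rows, cols] <- matrix(isSoil, pp, pp)

      vegFrac <- 1 - mean(isSoil)
      lai[p] <- min(3.8, max(0.13,
        vegFrac * (0.8 + 3.0 * fCrown) * exp(stats::rnorm(1L, 0, 0.05))))

      if (nrow(trees))
        treeList[[p]] <- cbind(plot_id = rownames(cover)[p], trees)
    }

    treeTab <- if (any(!vapply(treeList, is.null, logical(1L))))
      do.call(rbind, treeList[!vapply(treeList, is.null, logical(1L))])
    else
      data.frame(plot_id = character(), species = character(),
                 x_m = numeric(), y_m = numeric(),
                 crown_diameter_m = numeric(), height_m = numeric())
    rownames(treeTab) <- NULL

    cube <- spectralCube(values, wl, pixelSize = config$pixelSize,
                         origin = c(0, 0), plots = plots)
    new("SyntheticScene", cube = cube, trees = treeTab,
        understory = understory, cover = trueCover,
        lai = data.frame(plot_id = rownames(cover), lai = lai),
        truth = list(dominant = dominant, shade = shadeFlag,
                     soil = soilFlag, gradient = communities$gradient,
                     inputCover = cover))
  })
}
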