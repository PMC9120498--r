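#' Masking configuration
#'
#' Thresholds and band windows for pixel masking. Defaults follow standard
#' airborne-spectroscopy practice: atmospheric water-vapour windows
#' 1340-1445 nm and 1790-1955 nm, spectrum tails at <= 400 nm and
#' >= 2400 nm removed, NIR shade index averaged over 752-1048 nm with
#' vegetation-type thresholds (forest 0.18, shrubland 0.20, grassland 0.22),
#' a site-specific NDVI threshold (0.2 for sparse through 0.8 for dense
#' vegetation), and a plot retained only when at least half its pixels pass
#' both masks. The NDVI red/NIR windows are a convention choice (red
#' 650-680 nm, NIR 780-800 nm) and configurable.
#'
#' @param waterWindows list of length-2 numeric vectors, closed wavelength
#'   intervals (nm) removed as atmospheric water absorption bands.
#' @param lowerCut,upperCut bands at `<= lowerCut` or `>= upperCut` nm are
#'   removed.
#' @param redWindow,nirWindow closed wavelength windows (nm) whose band
#'   means define NDVI.
#' @param shadeWindow closed window (nm) whose band mean defines the NIR
#'   shade index.
#' @param shadeThresholds named numeric, minimum shade index per vegetation
#'   type.
#' @param ndviThreshold default minimum NDVI (sites can override in
#'   [extractPlotPixels()]).
#' @param minValidFraction minimum fraction of plot pixels that must pass
#'   both masks for the plot to be retained (default 0.5, inclusive).
#' @return a validated list of class `MaskConfig`.
#' @examples
#' cfg <- maskConfig(ndviThreshold = 0.4)
#' @export
maskConfig <- function(waterWindows = list(c(1340, 1445), c(1790, 1955)),
                       lowerCut = 400, upperCut = 2400,
                       redWindow = c(650, 680), nirWindow = c(780, 800),
                       shadeWindow = c(752, 1048),
                       shadeThresholds = c(forest = 0.18, shrubland = 0.20,
                                           grassland = 0.22),
                       ndviThreshold = 0.2,
                       minValidFraction = 0.5) {
  stopIfNot(is.list(waterWindows) &&
              all(vapply(waterWindows, length, 1L) == 2L),
            "'waterWindows' must be a list of length-2 ranges")
  stopIfNot(lowerCut < upperCut, "'lowerCut' must be below 'upperCut'")
  stopIfNot(ndviThreshold >= -1 && ndviThreshold <= 1,
            "'ndviThreshold' must lie in [-1, 1]")
  stopIfNot(all(shadeThresholds >= 0 & shadeThresholds <= 1),
            "'shadeThresholds' must lie in [0, 1]")
  stopIfNot(minValidFraction >= 0 && minValidFraction <= 1,
            "'minValidFraction' must lie in [0, 1]")
  for (w in c(list(redWindow, nirWindow, shadeWindow), waterWindows))
    stopIfNot(length(w) == 2L && w[1L] <= w[2L],
              "band windows must be increasing length-2 ranges")
  structure(list(waterWindows = waterWindows, lowerCut = lowerCut,
                 upperCut = upperCut, redWindow = redWindow,
                 nirWindow = nirWindow, shadeWindow = shadeWindow,
                 shadeThresholds = shadeThresholds,
                 ndviThreshold = ndviThreshold,
                 minValidFraction = minValidFraction),
            class = "MaskConfig")
}

# Indices of wavelengths kept after tail and water-window removal.
retainedBandIndices <- function(wavelengths, config) {
  keep <- wavelengths > config$lowerCut & wavelengths < config$upperCut
  for (w in config$waterWindows)
    keep <- keep & !(wavelengths >= w[1L] & wavelengths <= w[2L])
  which(keep)
}

#' Remove spectrum tails and atmospheric water absorption bands
#'
#' Drops bands at wavelengths `<= lowerCut` (400 nm), `>= upperCut`
#' (2400 nm), or inside any of the closed water-absorption windows
#' (1340-1445 nm, 1790-1955 nm by default).
#'
#' @param cube a [SpectralCube-class].
#' @param config a [maskConfig()].
#' @return the cube restricted to the retained bands.
#' @examples
#' wl <- seq(380, 2505, by = 5)
#' cube <- spectralCube(array(0.3, c(2, 2, length(wl))), wl)
#' length(wavelengths(dropBadBands(cube)))
#' @export
dropBadBands <- function(cube, config = maskConfig()) {
  stopIfNot(is(cube, "SpectralCube"), "'cube' must be a SpectralCube")
  keep <- retainedBandIndices(cube@wavelengths, config)
  stopIfNot(length(keep) > 0L,
            "band exclusion removed every band; check the wavelength grid")
  spectralCube(cube@values[, , keep, drop = FALSE],
               cube@wavelengths[keep], pixelSize = cube@pixelSize,
               origin = cube@origin, plots = cube@plots)
}

# Mean over the bands inside a closed wavelength window, per pixel.
windowMean <- function(cube, window, what) {
  idx <- which(cube@wavelengths >= window[1L] & cube@wavelengths <= window[2L])
  stopIfNot(length(idx) > 0L, "no band falls inside the %s window", what)
  if (length(idx) == 1L) cube@values[, , idx]
  else apply(cube@values[, , idx, drop = FALSE], c(1L, 2L), mean)
}

#' Per-pixel NDVI
#'
#' NDVI = (NIR - red) / (NIR + red), computed from band-window means of the
#' (unnormalized) reflectance. Pixels with red = NIR = 0 are NA.
#'
#' @param cube a [SpectralCube-class] (before band exclusion; the windows
#'   survive exclusion either way).
#' @param redWindow,nirWindow closed wavelength windows (nm).
#' @return numeric matrix of NDVI in \[-1, 1\] (NA where undefined).
#' @examples
#' wl <- c(660, 790)
#' v <- array(c(0.05, 0.45), c(1, 1, 2))
#' computeNDVI(spectralCube(v, wl))  # 0.8
#' @export
computeNDVI <- function(cube, redWindow = c(650, 680),
                        nirWindow = c(780, 800)) {
  stopIfNot(is(cube, "SpectralCube"), "'cube' must be a SpectralCube")
  red <- windowMean(cube, redWindow, "red")
  nir <- windowMean(cube, nirWindow, "NIR")
  out <- (nir - red) / (nir + red)
  out[nir + red == 0] <- NA_real_
  out
}

#' Per-pixel NIR shade index
#'
#' Arithmetic mean reflectance over the closed 752-1048 nm window; low
#' values flag shaded canopy.
#'
#' @param cube a [SpectralCube-class].
#' @param window closed wavelength window (nm), default `c(752, 1048)`.
#' @return numeric matrix in \[0, 1\].
#' @export
computeNIRShadeIndex <- function(cube, window = c(752, 1048)) {
  stopIfNot(is(cube, "SpectralCube"), "'cube' must be a SpectralCube")
  windowMean(cube, window, "NIR shade")
}

# Map-coordinate centres of all pixels of a cube (pixels column-major).
pixelCenters <- function(cube) {
  d <- dim(cube@values)
  xs <- cube@origin[1L] + (seq_len(d[2L]) - 0.5) * cube@pixelSize
  ys <- cube@origin[2L] + (seq_len(d[1L]) - 0.5) * cube@pixelSize
  list(x = xs, y = ys)
}

#' Extract the masked pixels of one plot
#'
#' Collects the pixels whose centres fall inside the plot rectangle
#' (half-open cells), applies the NDVI and NIR shade masks (both inclusive,
#' `>=` threshold) on the original reflectance, and keeps the plot only if
#' the passing fraction reaches `minValidFraction` (default: at least 50%
#' of all plot pixels). The returned matrix carries the band-excluded
#' spectra of the retained pixels.
#'
#' @param cube the full [SpectralCube-class] (all bands; NDVI and shade are
#'   computed before band exclusion).
#' @param plot a plot id present in `plotPolygons(cube)`, or a one-row
#'   data.frame with `plot_id`, `xmin`, `ymin`, `xmax`, `ymax`.
#' @param config a [maskConfig()].
#' @param vegetationType `"forest"`, `"shrubland"` or `"grassland"`; selects
#'   the shade threshold.
#' @param ndviThreshold site-specific NDVI threshold; defaults to
#'   `config$ndviThreshold`.
#' @return a [PlotPixelMatrix-class], or `NULL` (with a message) when the
#'   plot fails the minimum-valid-fraction rule. The fraction of passing
#'   pixels is attached as attribute `validFraction` in both cases (on the
#'   rejection marker via the message only; use [extractSitePixels()] for a
#'   tabulated report).
#' @export
extractPlotPixels <- function(cube, plot, config = maskConfig(),
                              vegetationType = "forest",
                              ndviThreshold = config$ndviThreshold) {
  stopIfNot(is(cube, "SpectralCube"), "'cube' must be a SpectralCube")
  if (is.character(plot)) {
    row <- cube@plots[cube@plots$plot_id == plot, , drop = FALSE]
    stopIfNot(nrow(row) == 1L, "plot '%s' not found in the cube", plot)
  } else row <- plot
  stopIfNot(vegetationType %in% names(config$shadeThresholds),
            "unknown vegetation type '%s'", vegetationType)

  ctr <- pixelCenters(cube)
  cIn <- which(ctr$x >= row$xmin & ctr$x < row$xmax)
  rIn <- which(ctr$y >= row$ymin & ctr$y < row$ymax)
  stopIfNot(length(cIn) > 0L && length(rIn) > 0L,
            "plot '%s' does not intersect the raster", row$plot_id)

  ndvi <- computeNDVI(cube, config$redWindow, config$nirWindow)[rIn, cIn,
                                                               drop = FALSE]
  shade <- computeNIRShadeIndex(cube, config$shadeWindow)[rIn, cIn,
                                                          drop = FALSE]
  pass <- !is.na(ndvi) & ndvi >= ndviThreshold &
    shade >= config$shadeThresholds[[vegetationType]]
  validFraction <- mean(pass)

  if (validFraction < config$minValidFraction) {
    message(sprintf("plot '%s' rejected: %.1f%% of pixels pass (minimum %.0f%%)",
                    row$plot_id, 100 * validFraction,
                    100 * config$minValidFraction))
    return(NULL)
  }

  keep <- retainedBandIndices(cube@wavelengths, config)
  vals <- cube@values[rIn, cIn, keep, drop = FALSE]
  m <- matrix(vals, nrow = length(rIn) * length(cIn),
              ncol = length(keep))
  coords <- cbind(x = rep(ctr$x[cIn], each = length(rIn)),
                  y = rep(ctr$y[rIn], times = length(cIn)))
  sel <- as.vector(pass)
  out <- new("PlotPixelMatrix", plotId = as.character(row$plot_id),
             values = m[sel, , drop = FALSE],
             wavelengths = cube@wavelengths[keep],
             coords = coords[sel, , drop = FALSE],
             normalized = FALSE)
  attr(out, "validFraction") <- validFraction
  out
}

#' Extract and mask all plots of a cube
#'
#' Applies [extractPlotPixels()] to every plot polygon of the cube and
#' reports which plots were rejected by the minimum-valid-fraction rule.
#'
#' @inheritParams extractPlotPixels
#' @param vegetationType one type for the whole site, or a vector named by
#'   plot id.
#' @return list with `pixels` (named list of retained
#'   [PlotPixelMatrix-class]) and `report` (data.frame: `plot_id`,
#'   `validFraction`, `retained`).
#' @export
extractSitePixels <- function(cube, config = maskConfig(),
                              vegetationType = "forest",
                              ndviThreshold = config$ndviThreshold) {
  plots <- cube@plots
  types <- if (length(vegetationType) == 1L)
    stats::setNames(rep(vegetationType, nrow(plots)), plots$plot_id)
  else vegetationType
  pixels <- list()
  report <- data.frame(plot_id = plots$plot_id,
                       validFraction = NA_real_, retained = FALSE)
  for (i in seq_len(nrow(plots))) {
    id <- plots$plot_id[i]
    ppm <- withCallingHandlers(
      extractPlotPixels(cube, plots[i, , drop = FALSE], config,
                        types[[id]], ndviThreshold),
      message = function(m) invokeRestart("muffleMessage"))
    if (!is.null(ppm)) {
      report$validFraction[i] <- attr(ppm, "validFraction")
      report$retained[i] <- TRUE
      pixels[[id]] <- ppm
    } else {
      # recompute the fraction for the report
      row <- plots[i, , drop = FALSE]
      ctr <- pixelCenters(cube)
      cIn <- ctr$x >= row$xmin & ctr$x < row$xmax
      rIn <- ctr$y >= row$ymin & ctr$y < row$ymax
      nd <- computeNDVI(cube, config$redWindow, config$nirWindow)[rIn, cIn]
      sh <- computeNIRShadeIndex(cube, config$shadeWindow)[rIn, cIn]
      report$validFraction[i] <-
        mean(!is.na(nd) & nd >= ndviThreshold &
               sh >= config$shadeThresholds[[types[[id]]]])
    }
  }
  list(pixels = pixels, report = report)
}

#' Brightness-normalize pixel spectra
#'
#' Divides every pixel spectrum by its Euclidean norm, removing overall
#' illumination/brightness differences (a shaded spectrum and its unshaded
#' original become identical). Idempotent. Zero-norm rows are dropped with
#' a warning.
#'
#' @param x a [PlotPixelMatrix-class] or a numeric pixels x bands matrix.
#' @return the same type, rows scaled to unit norm.
#' @examples
#' brightnessNormalize(matrix(c(3, 4), 1))  # 0.6 0.8
#' @export
brightnessNormalize <- function(x) {
  if (is(x, "PlotPixelMatrix")) {
    nrm <- sqrt(rowSums(x@values^2))
    keep <- nrm > 0
    if (!all(keep))
      warning(sprintf("%d zero-norm pixel spectra dropped", sum(!keep)))
    return(new("PlotPixelMatrix", plotId = x@plotId,
               values = x@values[keep, , drop = FALSE] / nrm[keep],
               wavelengths = x@wavelengths,
               coords = x@coords[keep, , drop = FALSE], normalized = TRUE))
  }
  stopIfNot(is.matrix(x) && is.numeric(x), "'x' must be a numeric matrix")
  nrm <- sqrt(rowSums(x^2))
  keep <- nrm > 0
  if (!all(keep))
    warning(sprintf("%d zero-norm pixel spectra dropped", sum(!keep)))
  x[keep, , drop = FALSE] / nrm[keep]
}
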