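#' @import methods
NULL

#' SpectralCube: a band-indexed reflectance raster
#'
#' Container for a georeferenced hyperspectral reflectance image together with
#' its wavelength grid and the polygons of the vegetation plots laid out on
#' it. Values are unitless surface reflectance in \[0, 1\] (NA allowed for
#' nodata). The array is indexed \[row, col, band\]; row 1 is the southern
#' (bottom) edge, map coordinates are metres with the origin at the
#' lower-left corner of the raster.
#'
#' @slot values numeric array, nrow x ncol x nband reflectance.
#' @slot wavelengths numeric, band-centre wavelengths in nm, strictly
#'   increasing, one per band.
#' @slot pixelSize numeric(1), pixel edge length in metres.
#' @slot origin numeric(2), map coordinates (x, y) of the raster's
#'   lower-left corner.
#' @slot plots data.frame with columns `plot_id`, `xmin`, `ymin`, `xmax`,
#'   `ymax` giving axis-aligned plot rectangles in map coordinates.
#'
#' @seealso [spectralCube()], [dropBadBands()], [extractPlotPixels()]
#' @export
setClass("SpectralCube",
  representation(
    values = "array",
    wavelengths = "numeric",
    pixelSize = "numeric",
    origin = "numeric",
    plots = "data.frame"
  )
)

setValidity("SpectralCube", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "'values' must be a 3-d array [row, col, band]")
  else {
    if (d[3L] != length(object@wavelengths))
      msg <- c(msg, "number of bands must equal length(wavelengths)")
    rng <- range(object@values, na.rm = TRUE)
    if (is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 1))
      msg <- c(msg, "reflectance values must lie in [0, 1]")
  }
  if (is.unsorted(object@wavelengths, strictly = TRUE))
    msg <- c(msg, "'wavelengths' must be strictly increasing")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number")
  if (length(object@origin) != 2L)
    msg <- c(msg, "'origin' must have length 2")
  need <- c("plot_id", "xmin", "ymin", "xmax", "ymax")
  if (nrow(object@plots) > 0L && !all(need %in% names(object@plots)))
    msg <- c(msg, sprintf("'plots' must have columns %s",
                          paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralCube
#'
#' @param values nrow x ncol x nband reflectance array in \[0, 1\].
#' @param wavelengths band-centre wavelengths (nm), strictly increasing.
#' @param pixelSize pixel edge length in metres (default 1).
#' @param origin map coordinates of the lower-left raster corner.
#' @param plots data.frame of plot rectangles (`plot_id`, `xmin`, `ymin`,
#'   `xmax`, `ymax`); may be empty.
#' @return A [SpectralCube-class] object.
#' @examples
#' wl <- seq(400, 2400, by = 100)
#' cube <- spectralCube(array(0.2, c(4, 4, length(wl))), wl)
#' dim(cube)
#' @export
spectralCube <- function(values, wavelengths, pixelSize = 1,
                         origin = c(0, 0),
                         plots = data.frame(plot_id = character(),
                                            xmin = numeric(), ymin = numeric(),
                                            xmax = numeric(), ymax = numeric())) {
  new("SpectralCube", values = values, wavelengths = as.numeric(wavelengths),
      pixelSize = as.numeric(pixelSize), origin = as.numeric(origin),
      plots = plots)
}

#' SpeciesLibrary: per-species endmember spectra and growth attributes
#'
#' One entry per species: a pure ("endmember") reflectance spectrum on the
#' working wavelength grid, the growth form used by the scene renderer
#' (`"tree"` crowns occlude, `"herb"` fills the understory), and the ranges
#' from which crown diameters and heights are drawn.
#'
#' @slot spectra numeric matrix, species x bands, reflectance in \[0, 1\];
#'   rownames are species ids.
#' @slot wavelengths numeric, nm, strictly increasing.
#' @slot growthForm character, `"tree"` or `"herb"` per species.
#' @slot crownRange numeric matrix species x 2, min/max crown diameter (m).
#' @slot heightRange numeric matrix species x 2, min/max height (m).
#' @seealso [simulateEndmembers()]
#' @export
setClass("SpeciesLibrary",
  representation(
    spectra = "matrix",
    wavelengths = "numeric",
    growthForm = "character",
    crownRange = "matrix",
    heightRange = "matrix"
  )
)

setValidity("SpeciesLibrary", function(object) {
  msg <- character()
  n <- nrow(object@spectra)
  if (is.null(rownames(object@spectra)) ||
      anyDuplicated(rownames(object@spectra)))
    msg <- c(msg, "'spectra' must have unique rownames (species ids)")
  if (ncol(object@spectra) != length(object@wavelengths))
    msg <- c(msg, "spectrum length must equal wavelength-grid length")
  if (any(object@spectra < 0) || any(object@spectra > 1))
    msg <- c(msg, "all reflectance must be in [0, 1]")
  if (length(object@growthForm) != n ||
      !all(object@growthForm %in% c("tree", "herb")))
    msg <- c(msg, "'growthForm' must be 'tree' or 'herb', one per species")
  if (nrow(object@crownRange) != n || nrow(object@heightRange) != n)
    msg <- c(msg, "'crownRange'/'heightRange' must have one row per species")
  if (length(msg)) msg else TRUE
})

#' PlotPixelMatrix: masked pixel spectra of one plot
#'
#' The retained (mask-passing) pixel spectra of a single plot after band
#' exclusion, as pixels x bands, with pixel map coordinates and a flag
#' recording whether rows have been brightness-normalized to unit Euclidean
#' norm.
#'
#' @slot plotId character(1).
#' @slot values numeric matrix, pixels x retained bands.
#' @slot wavelengths numeric, retained band wavelengths (nm).
#' @slot coords numeric matrix, pixels x 2 map coordinates of pixel centres.
#' @slot normalized logical(1), TRUE once rows have unit norm.
#' @seealso [extractPlotPixels()], [brightnessNormalize()]
#' @export
setClass("PlotPixelMatrix",
  representation(
    plotId = "character",
    values = "matrix",
    wavelengths = "numeric",
    coords = "matrix",
    normalized = "logical"
  )
)

setValidity("PlotPixelMatrix", function(object) {
  msg <- character()
  if (length(object@plotId) != 1L)
    msg <- c(msg, "'plotId' must be a single id")
  if (ncol(object@values) != length(object@wavelengths))
    msg <- c(msg, "column count must equal length(wavelengths)")
  if (nrow(object@coords) != nrow(object@values))
    msg <- c(msg, "'coords' must have one row per pixel")
  if (isTRUE(object@normalized) && nrow(object@values) > 0L) {
    nrm <- sqrt(rowSums(object@values^2))
    if (any(abs(nrm - 1) > 1e-9))
      msg <- c(msg, "normalized flag set but row norms differ from 1")
  }
  if (length(msg)) msg else TRUE
})

#' SpectralPCA: pooled principal components of plot pixel spectra
#'
#' Result of a principal component analysis fitted on the pooled pixels of
#' all retained plots of one site, with distance-preserving (type I) scaling:
#' columns (bands) are centred on the pooled mean, not standardized, and
#' pixel scores are projections onto unit-norm eigenvectors, so Euclidean
#' distances among scores with all components equal distances among centred
#' spectra.
#'
#' @slot center numeric, pooled band means used for centring.
#' @slot rotation numeric matrix, bands x k retained unit eigenvectors.
#' @slot eigenvalues numeric, all eigenvalues (non-increasing, >= 0).
#' @slot varianceFraction numeric, per-component fraction of total variance.
#' @slot k integer(1), number of retained components.
#' @slot scores numeric matrix, pixels x k scores of the pooled pixels.
#' @slot plot factor, plot id of each pooled pixel row.
#' @seealso [fitPooledPCA()], [spectralAlpha()]
#' @export
setClass("SpectralPCA",
  representation(
    center = "numeric",
    rotation = "matrix",
    eigenvalues = "numeric",
    varianceFraction = "numeric",
    k = "integer",
    scores = "matrix",
    plot = "factor"
  )
)

setValidity("SpectralPCA", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (any(ev < -1e-8 * max(abs(ev), 1)))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (is.unsorted(rev(ev)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (ncol(object@rotation) != object@k)
    msg <- c(msg, "'rotation' must have k columns")
  if (ncol(object@scores) != object@k)
    msg <- c(msg, "'scores' must have k columns")
  if (length(object@plot) != nrow(object@scores))
    msg <- c(msg, "'plot' must label every score row")
  g <- crossprod(object@rotation)
  if (max(abs(g - diag(ncol(g)))) > 1e-8)
    msg <- c(msg, "retained eigenvectors must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' CoinertiaResult: co-inertia analysis of two plot-level tables
#'
#' Co-inertia of a spectral table X (plots x spectral features) and a
#' community table Y (plots x species features): the singular value
#' decomposition of the cross-covariance matrix t(Y) X / n. Eigenvalues are
#' squared singular values; their sum is the total co-inertia; the RV
#' coefficient normalizes it by the Frobenius norms of the two
#' self-covariances. A permutation p-value is attached by
#' [coinertiaTest()] (NA until then).
#'
#' @slot eigenvalues numeric, squared singular values, non-increasing.
#' @slot totalCoinertia numeric(1), sum of eigenvalues.
#' @slot rv numeric(1), RV coefficient in \[0, 1\].
#' @slot xLoadings,yLoadings numeric matrices of co-inertia axes (columns).
#' @slot xCenter,yCenter numeric, column means removed from each table.
#' @slot pValue numeric(1), permutation p-value or NA.
#' @slot nPerm integer(1), number of permutations used (0 if untested).
#' @seealso [coinertia()], [coinertiaTest()], [varianceExplained()]
#' @export
setClass("CoinertiaResult",
  representation(
    eigenvalues = "numeric",
    totalCoinertia = "numeric",
    rv = "numeric",
    xLoadings = "matrix",
    yLoadings = "matrix",
    xCenter = "numeric",
    yCenter = "numeric",
    pValue = "numeric",
    nPerm = "integer"
  )
)

setValidity("CoinertiaResult", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (any(ev < -1e-10 * max(abs(ev), 1)))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (is.unsorted(rev(ev)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (object@rv < -1e-10 || object@rv > 1 + 1e-10)
    msg <- c(msg, "RV must lie in [0, 1]")
  if (!is.na(object@pValue) && (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "p-value must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticScene: a rendered synthetic study site with ground truth
#'
#' Everything the scene renderer produces for one site: the reflectance cube
#' with plot polygons, the stem-mapped tree table, the understory percent
#' cover table, the true top-of-canopy combined cover, per-plot leaf area
#' index, and the pixel-level ground truth (dominant species, shade and
#' bare-soil flags) needed to verify masking and diversity recovery.
#'
#' @slot cube a [SpectralCube-class].
#' @slot trees data.frame: `plot_id`, `species`, `x_m`, `y_m` (plot-local,
#'   origin at the plot's lower-left corner), `crown_diameter_m`, `height_m`.
#' @slot understory numeric matrix, plots x herb species percent cover
#'   (fractions of plot area below the crown layer).
#' @slot cover numeric matrix, plots x species true combined top-of-canopy
#'   percent cover (crown layer + rescaled understory).
#' @slot lai data.frame: `plot_id`, `lai`.
#' @slot truth list with elements `dominant` (character matrix, per-pixel
#'   dominant species or "soil"), `shade`, `soil` (logical matrices),
#'   `gradient` (named numeric, per-plot gradient position), `inputCover`
#'   (the community matrix the renderer was asked to realize).
#' @seealso [renderScene()]
#' @export
setClass("SyntheticScene",
  representation(
    cube = "SpectralCube",
    trees = "data.frame",
    understory = "matrix",
    cover = "matrix",
    lai = "data.frame",
    truth = "list"
  )
)

setValidity("SyntheticScene", function(object) {
  msg <- character()
  if (any(object@cover < -1e-9))
    msg <- c(msg, "cover must be non-negative")
  if (nrow(object@cover) > 0L &&
      any(rowSums(object@cover) > 100 + 1e-6))
    msg <- c(msg, "combined cover rows must sum to <= 100")
  if (length(msg)) msg else TRUE
})
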