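#' Band-centre wavelengths of an object
#'
#' @param x a [SpectralCube-class], [SpeciesLibrary-class] or
#'   [PlotPixelMatrix-class].
#' @return numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpeciesLibrary", function(x) x@wavelengths)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "PlotPixelMatrix", function(x) x@wavelengths)

#' Reflectance values
#'
#' @param x a [SpectralCube-class] (3-d array) or [PlotPixelMatrix-class]
#'   (pixels x bands matrix).
#' @return the underlying numeric array or matrix.
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' @rdname reflectance
#' @export
setMethod("reflectance", "SpectralCube", function(x) x@values)

#' @rdname reflectance
#' @export
setMethod("reflectance", "PlotPixelMatrix", function(x) x@values)

#' @rdname reflectance
#' @export
setMethod("reflectance", "SpeciesLibrary", function(x) x@spectra)

#' Plot polygons of a cube
#'
#' @param x a [SpectralCube-class].
#' @return data.frame of plot rectangles.
#' @export
setGeneric("plotPolygons", function(x) standardGeneric("plotPolygons"))

#' @rdname plotPolygons
#' @export
setMethod("plotPolygons", "SpectralCube", function(x) x@plots)

#' @describeIn SpectralCube-class dimensions of the value array.
#' @param x a SpectralCube.
#' @export
setMethod("dim", "SpectralCube", function(x) dim(x@values))

#' Plot id of a pixel matrix
#'
#' @param x a [PlotPixelMatrix-class].
#' @return character(1) plot id.
#' @export
setGeneric("plotId", function(x) standardGeneric("plotId"))

#' @rdname plotId
#' @export
setMethod("plotId", "PlotPixelMatrix", function(x) x@plotId)

#' Accessors for SyntheticScene components
#'
#' @param x a [SyntheticScene-class].
#' @return `sceneCube`: the [SpectralCube-class]; `sceneTrees`: the stem
#'   map data.frame; `sceneUnderstory` / `sceneCover`: percent-cover
#'   matrices; `sceneLAI`: per-plot LAI data.frame; `sceneTruth`: the
#'   ground-truth list.
#' @name scene-accessors
NULL

#' @rdname scene-accessors
#' @export
setGeneric("sceneCube", function(x) standardGeneric("sceneCube"))
#' @rdname scene-accessors
#' @export
setMethod("sceneCube", "SyntheticScene", function(x) x@cube)

#' @rdname scene-accessors
#' @export
setGeneric("sceneTrees", function(x) standardGeneric("sceneTrees"))
#' @rdname scene-accessors
#' @export
setMethod("sceneTrees", "SyntheticScene", function(x) x@trees)

#' @rdname scene-accessors
#' @export
setGeneric("sceneUnderstory", function(x) standardGeneric("sceneUnderstory"))
#' @rdname scene-accessors
#' @export
setMethod("sceneUnderstory", "SyntheticScene", function(x) x@understory)

#' @rdname scene-accessors
#' @export
setGeneric("sceneCover", function(x) standardGeneric("sceneCover"))
#' @rdname scene-accessors
#' @export
setMethod("sceneCover", "SyntheticScene", function(x) x@cover)

#' @rdname scene-accessors
#' @export
setGeneric("sceneLAI", function(x) standardGeneric("sceneLAI"))
#' @rdname scene-accessors
#' @export
setMethod("sceneLAI", "SyntheticScene", function(x) x@lai)

#' @rdname scene-accessors
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))
#' @rdname scene-accessors
#' @export
setMethod("sceneTruth", "SyntheticScene", function(x) x@truth)

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpectralCube: %d x %d pixels, %d bands (%.0f-%.0f nm), %g m pixels, %d plots\n",
              d[1L], d[2L], d[3L], min(object@wavelengths),
              max(object@wavelengths), object@pixelSize,
              nrow(object@plots)))
})

setMethod("show", "SpeciesLibrary", function(object) {
  cat(sprintf("SpeciesLibrary: %d species (%d tree, %d herb), %d bands\n",
              nrow(object@spectra), sum(object@growthForm == "tree"),
              sum(object@growthForm == "herb"), ncol(object@spectra)))
})

setMethod("show", "PlotPixelMatrix", function(object) {
  cat(sprintf("PlotPixelMatrix '%s': %d pixels x %d bands%s\n",
              object@plotId, nrow(object@values), ncol(object@values),
              if (isTRUE(object@normalized)) " (brightness-normalized)" else ""))
})

setMethod("show", "SpectralPCA", function(object) {
  cat(sprintf("SpectralPCA: %d components retained (%.1f%% of variance), %d pixels, %d plots\n",
              object@k, 100 * sum(object@varianceFraction[seq_len(object@k)]),
              nrow(object@scores), nlevels(object@plot)))
})

setMethod("show", "CoinertiaResult", function(object) {
  cat(sprintf("CoinertiaResult: total co-inertia %.4g, RV = %.3f",
              object@totalCoinertia, object@rv))
  if (!is.na(object@pValue))
    cat(sprintf(", p = %.4g (%d permutations)", object@pValue, object@nPerm))
  cat("\n")
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d plots, %d trees, %d species; ",
              nrow(object@cover), nrow(object@trees), ncol(object@cover)))
  show(object@cube)
})
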