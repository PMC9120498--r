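#' Pooled PCA of plot pixel spectra with distance-preserving scaling
#'
#' Fits one principal component analysis on the pooled pixels of all
#' retained plots of a site. Scaling is type I ("distance biplot"): band
#' columns are centred on the pooled mean and not standardized, and pixel
#' scores are projections onto unit eigenvectors, so Euclidean distances
#' among full score vectors equal distances among centred spectra.
#' Components are retained until more than `varianceTarget` of the total
#' variance is explained (default > 0.95); `varianceTarget = 1` retains all
#' components with non-negligible eigenvalue.
#'
#' The eigendecomposition runs on the band covariance matrix when there are
#' fewer bands than pixels and on the pixel Gram matrix otherwise; the two
#' routes agree to numerical tolerance.
#'
#' @param pixels named list of brightness-normalized
#'   [PlotPixelMatrix-class] objects on one band grid (e.g.
#'   `extractSitePixels()$pixels` after [brightnessNormalize()]), or a
#'   single pixels x bands matrix.
#' @param varianceTarget fraction of total variance that must be exceeded
#'   by the retained components (default 0.95).
#' @param plot optional factor labelling the rows when `pixels` is a
#'   matrix.
#' @return a [SpectralPCA-class].
#' @examples
#' m <- matrix(rnorm(200), 40, 5)
#' fitPooledPCA(m, plot = factor(rep(c("a", "b"), each = 20)))
#' @export
fitPooledPCA <- function(pixels, varianceTarget = 0.95, plot = NULL) {
  if (is.list(pixels)) {
    mats <- lapply(pixels, function(p) {
      stopIfNot(is(p, "PlotPixelMatrix"), "'pixels' must be PlotPixelMatrix objects")
      p@values
    })
    plot <- factor(rep(vapply(pixels, function(p) p@plotId, character(1L)),
                       vapply(mats, nrow, integer(1L))))
    x <- do.call(rbind, mats)
  } else {
    x <- pixels
    if (is.null(plot)) plot <- factor(rep("all", nrow(x)))
    plot <- factor(plot)
  }
  n <- nrow(x)
  stopIfNot(n >= 2L, "pooled PCA needs at least 2 pixels")
  stopIfNot(varianceTarget > 0 && varianceTarget <= 1,
            "'varianceTarget' must lie in (0, 1]")

  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  p <- ncol(x)

  if (p <= n) {
    ev <- eigen(crossprod(xc) / n, symmetric = TRUE)
    values <- pmax(ev$values, 0)
    vectors <- ev$vectors
  } else {
    ev <- eigen(tcrossprod(xc) / n, symmetric = TRUE)
    values <- pmax(ev$values, 0)
    pos <- values > 0
    # band-space eigenvectors recovered from pixel-space ones
    vectors <- crossprod(xc, ev$vectors[, pos, drop = FALSE]) /
      rep(sqrt(values[pos] * n), each = p)
    values <- values[pos]
  }
  total <- sum(values)
  vf <- values / total
  tol <- 1e-12 * max(values, 1)
  if (varianceTarget >= 1) {
    k <- sum(values > tol)
  } else {
    k <- which(cumsum(vf) > varianceTarget)[1L]
    if (is.na(k)) k <- length(values)
  }
  rot <- vectors[, seq_len(k), drop = FALSE]
  new("SpectralPCA", center = center, rotation = rot,
      eigenvalues = values, varianceFraction = vf, k = as.integer(k),
      scores = xc %*% rot, plot = plot)
}

#' Spectral alpha-diversity per plot
#'
#' SD_alpha of a plot is the mean (over pixels) of the squared deviation of
#' every pixel's retained-component score vector from the plot's mean score
#' vector: `SD_alpha = (1/n) * sum_pixels sum_components (score - mean)^2`,
#' i.e. the sum over retained components of the biased per-plot variance.
#'
#' @param x a [SpectralPCA-class] (one row per plot in the result), or a
#'   numeric score matrix for a single plot.
#' @return data.frame with `plot_id`, `sd_alpha`, `n` (pixel count).
#' @examples
#' spectralAlpha(matrix(c(-1, 1), 2, 1))  # sd_alpha = 1
#' @export
spectralAlpha <- function(x) {
  oneBlock <- function(s, id) {
    n <- nrow(s)
    if (n == 0L) {
      warning(sprintf("plot '%s' has no pixels; skipped", id))
      return(NULL)
    }
    dev <- sweep(s, 2L, colMeans(s))
    data.frame(plot_id = id, sd_alpha = sum(dev^2) / n, n = n)
  }
  if (is(x, "SpectralPCA")) {
    out <- lapply(levels(x@plot), function(id)
      oneBlock(x@scores[x@plot == id, , drop = FALSE], id))
    do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  } else {
    stopIfNot(is.matrix(x) && nrow(x) >= 1L,
              "'x' must be a score matrix with >= 1 row")
    oneBlock(x, "plot")
  }
}

#' Plot-level mean spectra
#'
#' Per-band arithmetic mean of each plot's brightness-normalized retained
#' pixels, the unit of spectral beta-diversity.
#'
#' @param pixels named list of [PlotPixelMatrix-class] objects (normalized),
#'   or one such object.
#' @return numeric matrix, plots x bands (a single named row for one plot).
#' @export
plotMeanSpectra <- function(pixels) {
  if (is(pixels, "PlotPixelMatrix")) pixels <- list(pixels)
  rows <- lapply(pixels, function(p) {
    stopIfNot(is(p, "PlotPixelMatrix"), "'pixels' must be PlotPixelMatrix objects")
    if (nrow(p@values) == 0L) {
      warning(sprintf("plot '%s' has no retained pixels; skipped", p@plotId))
      return(NULL)
    }
    colMeans(p@values)
  })
  ids <- vapply(pixels, function(p) p@plotId, character(1L))
  keep <- !vapply(rows, is.null, logical(1L))
  out <- do.call(rbind, rows[keep])
  rownames(out) <- unname(ids[keep])
  out
}

#' Spectral beta-diversity: distances among plot mean spectra
#'
#' Full symmetric matrix of pairwise Euclidean distances among the
#' plot-level mean spectra of a site.
#'
#' @param meanSpectra plots x bands matrix from [plotMeanSpectra()] (or any
#'   plots x features matrix with plot rownames).
#' @return symmetric numeric matrix with zero diagonal.
#' @examples
#' spectralBetaDistances(rbind(a = c(0, 0), b = c(3, 4)))  # 5
#' @export
spectralBetaDistances <- function(meanSpectra) {
  stopIfNot(is.matrix(meanSpectra) && nrow(meanSpectra) >= 2L,
            "need mean spectra for at least 2 plots")
  as.matrix(stats::dist(meanSpectra))
}
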