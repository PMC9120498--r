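# Column-centre a table with uniform row weights.
centerColumns <- function(x) sweep(as.matrix(x), 2L, colMeans(x))

#' Co-inertia analysis of two plot-level tables
#'
#' Measures the concordance between a spectral table X (plots x features,
#' e.g. plot mean spectra or their PCA scores) and a community table Y
#' (plots x species, Hellinger-transformed cover). Both tables are
#' column-centred with uniform row weights; the co-inertia axes are the
#' singular vectors of the cross-covariance matrix `t(Yc) Xc / n`, the
#' eigenvalues its squared singular values (their sum, the total
#' co-inertia, equals the squared Frobenius norm of the cross-covariance),
#' and the RV coefficient normalizes the total co-inertia by the Frobenius
#' norms of the two self-covariance matrices, giving a value in \[0, 1\]
#' with RV = 1 for Y = X.
#'
#' @param x,y numeric matrices with the same plots in the same row order.
#' @return a [CoinertiaResult-class] (permutation p-value NA; see
#'   [coinertiaTest()]).
#' @examples
#' x <- matrix(rnorm(18), 6)
#' coinertia(x, x)  # RV = 1
#' @export
coinertia <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopIfNot(nrow(x) == nrow(y), "'x' and 'y' must have the same plots")
  stopIfNot(nrow(x) >= 3L, "co-inertia needs at least 3 plots")
  n <- nrow(x)
  xc <- centerColumns(x)
  yc <- centerColumns(y)
  cross <- crossprod(yc, xc) / n
  sv <- svd(cross)
  ev <- sv$d^2
  total <- sum(ev)
  sxx <- crossprod(xc) / n
  syy <- crossprod(yc) / n
  denom <- sqrt(sum(sxx^2) * sum(syy^2))
  rv <- if (denom > 0) total / denom else 0
  new("CoinertiaResult", eigenvalues = ev, totalCoinertia = total,
      rv = min(rv, 1), xLoadings = sv$v, yLoadings = sv$u,
      xCenter = colMeans(x), yCenter = colMeans(y),
      pValue = NA_real_, nPerm = 0L)
}

#' Monte-Carlo permutation test for co-inertia
#'
#' Permutes the rows of Y uniformly at random `nPerm` times (default 999)
#' and compares the total co-inertia (sum of eigenvalues, i.e. the squared
#' Frobenius norm of the cross-covariance) of each permutation with the
#' observed one: `p = (1 + #{permuted >= observed}) / (nPerm + 1)`.
#' Deterministic under a fixed seed.
#'
#' @inheritParams coinertia
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed.
#' @return a [CoinertiaResult-class] with `pValue` and `nPerm` filled in.
#' @export
coinertiaTest <- function(x, y, nPerm = 999, seed = NULL) {
  nPerm <- checkCount(nPerm, "nPerm")
  res <- coinertia(x, y)
  n <- nrow(as.matrix(x))
  xc <- centerColumns(as.matrix(x))
  yc <- centerColumns(as.matrix(y))
  obs <- res@totalCoinertia
  count <- withSeed(seed, {
    hits <- 0L
    for (i in seq_len(nPerm)) {
      stat <- sum((crossprod(yc[sample.int(n), , drop = FALSE], xc) / n)^2)
      if (stat >= obs) hits <- hits + 1L
    }
    hits
  })
  res@pValue <- (1 + count) / (nPerm + 1)
  res@nPerm <- as.integer(nPerm)
  validObject(res)
  res
}

#' Fraction of community variance captured by the co-inertia axes
#'
#' One plausible operationalization (redundancy-style, flagged
#' non-canonical): Y is regressed on the plot scores of X on the first
#' `nAxes` co-inertia axes, and the fraction is the explained sum of
#' squares over the total sum of squares of centred Y. It is 1 when Y = X
#' with all axes, 0 when the tables are orthogonal, and non-decreasing in
#' `nAxes`.
#'
#' @param result a [CoinertiaResult-class] from [coinertia()].
#' @param x,y the tables the result was fitted on.
#' @param nAxes number of co-inertia axes used (default: all).
#' @return numeric fraction in \[0, 1\].
#' @export
varianceExplained <- function(result, x, y,
                              nAxes = length(result@eigenvalues)) {
  stopIfNot(is(result, "CoinertiaResult"), "'result' must be a CoinertiaResult")
  nAxes <- min(nAxes, ncol(result@xLoadings))
  xc <- sweep(as.matrix(x), 2L, result@xCenter)
  yc <- sweep(as.matrix(y), 2L, result@yCenter)
  tot <- sum(yc^2)
  if (tot == 0) return(0)
  f <- xc %*% result@xLoadings[, seq_len(nAxes), drop = FALSE]
  qrF <- qr(f)
  fitted <- qr.fitted(qrF, yc)
  max(0, min(1, sum(fitted^2) / tot))
}
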