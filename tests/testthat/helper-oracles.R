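# Independent brute-force oracles. These deliberately use naive loops or a
# different decomposition route than the package implementation.

bfSdAlpha <- function(scores) {
  n <- nrow(scores)
  ctr <- colMeans(scores)
  total <- 0
  for (i in seq_len(n))
    for (j in seq_len(ncol(scores)))
      total <- total + (scores[i, j] - ctr[j])^2
  total / n
}

bfEuclidean <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      out[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  out
}

bfHellinger <- function(cover) {
  n <- nrow(cover)
  out <- matrix(0, n, n, dimnames = list(rownames(cover), rownames(cover)))
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      p <- cover[i, ] / sum(cover[i, ])
      q <- cover[j, ] / sum(cover[j, ])
      out[i, j] <- sqrt(sum((sqrt(p) - sqrt(q))^2))
    }
  out
}

# OLS via explicit normal equations and the closed-form slope t-test.
bfOLS <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  t <- b / se
  list(slope = b, intercept = a, r2 = sxy^2 / (sxx * syy), t = t,
       p = 2 * stats::pt(-abs(t), n - 2))
}

# PCA eigenvalues from an explicitly accumulated covariance matrix.
bfPcaEigenvalues <- function(x) {
  ctr <- colMeans(x)
  S <- matrix(0, ncol(x), ncol(x))
  for (i in seq_len(nrow(x)))
    S <- S + tcrossprod(x[i, ] - ctr)
  eigen(S / nrow(x), symmetric = TRUE, only.values = TRUE)$values
}

# Co-inertia eigenvalues via the explicitly formed cross-covariance and an
# eigendecomposition (the package uses an SVD).
bfCoinertiaEigenvalues <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  M <- t(yc) %*% xc / nrow(x)
  ev <- eigen(M %*% t(M), symmetric = TRUE, only.values = TRUE)$values
  sort(pmax(ev, 0), decreasing = TRUE)
}

# PSE by literal evaluation of the published formula.
bfPSE <- function(m, C) {
  m <- m[m > 0]
  C <- C[names(m), names(m)]
  M <- sum(m)
  (M * sum(m * diag(C)) - as.numeric(t(m) %*% C %*% m)) / (M^2 - sum(m^2))
}

# Exact visible crown areas via polygon clipping (shapely, called through
# the system python). `maps` is a list of tree data.frames; returns a list
# of per-tree visible areas (m^2), clipped to the plot square.
shapelyVisibleAreas <- function(maps, plotSide) {
  payload <- list(side = plotSide, maps = lapply(maps, function(tr)
    lapply(seq_len(nrow(tr)), function(i)
      list(x = tr$x_m[i], y = tr$y_m[i], r = tr$crown_diameter_m[i] / 2,
           h = tr$height_m[i]))))
  infile <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  out <- system2("python", test_path("oracle-visible-cover.py"),
                 stdin = infile, stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}
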