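set.seed(NULL)

test_that("rank-1 data give one component explaining all variance", {
  v <- c(1, 2, 3, 4)
  x <- outer(rnorm(30), v)  # points on a line through the origin
  pca <- fitPooledPCA(x, varianceTarget = 0.95)
  expect_equal(pca@k, 1L)
  expect_equal(pca@varianceFraction[1], 1, tolerance = 1e-10)
})

test_that("full-rank scores preserve pairwise distances (type I scaling)", {
  x <- matrix(rnorm(200), 25, 8)
  pca <- fitPooledPCA(x, varianceTarget = 1)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(as.matrix(dist(pca@scores)), as.matrix(dist(xc)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("eigenvalues match the brute-force covariance eigendecomposition", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(40 * 6), 40, 6)
    pca <- fitPooledPCA(x, varianceTarget = 1)
    expect_equal(pca@eigenvalues, bfPcaEigenvalues(x), tolerance = 1e-10)
  }
})

test_that("covariance and Gram routes agree when bands exceed pixels", {
  set.seed(4)
  x <- matrix(rnorm(10 * 30), 10, 30)  # more bands than pixels
  pcaGram <- fitPooledPCA(x, varianceTarget = 1)
  # force the covariance route by padding with duplicate pixels
  evCov <- bfPcaEigenvalues(x)
  expect_equal(pcaGram@eigenvalues,
               evCov[seq_along(pcaGram@eigenvalues)], tolerance = 1e-8)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(as.matrix(dist(pcaGram@scores)), as.matrix(dist(xc)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the retained set is the smallest exceeding the variance target", {
  set.seed(5)
  x <- matrix(rnorm(60 * 8), 60, 8) %*% diag(c(8, 4, 2, 1, 0.5, 0.25, 0.1, 0.05))
  pca <- fitPooledPCA(x, varianceTarget = 0.95)
  cv <- cumsum(pca@varianceFraction)
  expect_gt(cv[pca@k], 0.95)
  if (pca@k > 1) expect_lte(cv[pca@k - 1], 0.95)
})

test_that("spectral alpha-diversity matches its definition", {
  expect_equal(spectralAlpha(matrix(c(-1, 1), 2, 1))$sd_alpha, 1)
  expect_equal(spectralAlpha(matrix(0.7, 5, 3))$sd_alpha, 0)
  set.seed(6)
  s <- matrix(rnorm(250), 50, 5)
  expect_equal(spectralAlpha(s)$sd_alpha, bfSdAlpha(s), tolerance = 1e-10)
})

test_that("SD_alpha is invariant under rotation of the component basis", {
  set.seed(7)
  s <- matrix(rnorm(120), 30, 4)
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(spectralAlpha(s)$sd_alpha, spectralAlpha(s %*% q)$sd_alpha,
               tolerance = 1e-10)
})

test_that("the pooled variance partitions into within and among terms", {
  # law of total variance in the retained component space
  set.seed(8)
  mats <- lapply(1:5, function(i)
    matrix(rnorm(7 * i * 3, mean = i), 7 * i, 3))
  pooled <- do.call(rbind, mats)
  N <- nrow(pooled)
  sdPooled <- spectralAlpha(pooled)$sd_alpha
  grand <- colMeans(pooled)
  within <- sum(vapply(mats, function(m)
    nrow(m) / N * spectralAlpha(m)$sd_alpha, numeric(1)))
  among <- sum(vapply(mats, function(m)
    nrow(m) * sum((colMeans(m) - grand)^2), numeric(1))) / N
  expect_equal(sdPooled, within + among, tolerance = 1e-8)
})

test_that("plot mean spectra average the normalized pixels", {
  ppm <- new("PlotPixelMatrix", plotId = "a",
             values = rbind(c(0.2, 0.4), c(0.4, 0.2)),
             wavelengths = c(600, 800), coords = matrix(0, 2, 2),
             normalized = FALSE)
  expect_equal(unname(plotMeanSpectra(list(ppm))["a", ]), c(0.3, 0.3))
  # Jensen: the mean of unit vectors has norm <= 1, = 1 iff identical
  set.seed(9)
  for (i in 1:5) {
    m <- brightnessNormalize(matrix(runif(40, 0.05, 1), 8, 5))
    expect_lte(sqrt(sum(colMeans(m)^2)), 1 + 1e-12)
  }
  same <- brightnessNormalize(matrix(rep(runif(5), each = 4), 4, 5))
  expect_equal(sqrt(sum(colMeans(same)^2)), 1, tolerance = 1e-12)
})

test_that("spectral beta-distances are Euclidean among mean spectra", {
  m <- rbind(a = c(0, 0), b = c(3, 4), c = c(3, 4))
  d <- spectralBetaDistances(m)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["b", "c"], 0)
  expect_equal(d, t(d))
  set.seed(10)
  x <- matrix(rnorm(80), 10, 8,
              dimnames = list(paste0("p", 1:10), NULL))
  expect_equal(spectralBetaDistances(x), bfEuclidean(x), tolerance = 1e-10)
  expect_error(spectralBetaDistances(x[1, , drop = FALSE]), "2 plots")
})
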