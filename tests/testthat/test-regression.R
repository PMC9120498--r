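distMat <- function(x, ids) {
  m <- as.matrix(dist(x))
  dimnames(m) <- list(ids, ids)
  m
}

test_that("an exact linear relation is recovered perfectly", {
  ids <- letters[1:5]
  tax <- distMat(c(0, 1, 3, 6, 10), ids)
  reg <- distanceRegression(2 * tax, tax)
  expect_equal(reg$slope, 2, tolerance = 1e-12)
  expect_equal(reg$intercept, 0, tolerance = 1e-12)
  expect_equal(reg$r2, 1, tolerance = 1e-12)
  expect_equal(reg$n, 10)  # 5 choose 2
})

test_that("a zero-variance regressor yields a missing slope", {
  ids <- letters[1:4]
  tax <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(tax) <- 0
  spec <- distMat(rnorm(4), ids)
  expect_message(reg <- distanceRegression(spec, tax), "zero variance")
  expect_true(is.na(reg$slope))
})

test_that("OLS statistics match the normal-equations oracle", {
  set.seed(71)
  ids <- paste0("p", 1:8)
  tax <- distMat(rnorm(8), ids)
  spec <- distMat(rnorm(8), ids)
  reg <- distanceRegression(spec, tax)
  bf <- bfOLS(tax[lower.tri(tax)], spec[lower.tri(spec)])
  expect_equal(reg$slope, bf$slope, tolerance = 1e-9)
  expect_equal(reg$intercept, bf$intercept, tolerance = 1e-9)
  expect_equal(reg$r2, bf$r2, tolerance = 1e-9)
  expect_equal(reg$t, bf$t, tolerance = 1e-9)
  expect_equal(reg$p, bf$p, tolerance = 1e-9)
})

test_that("the per-plot scope regresses mean distances", {
  set.seed(72)
  ids <- paste0("p", 1:6)
  tax <- distMat(rnorm(6), ids)
  spec <- distMat(rnorm(6), ids)
  reg <- distanceRegression(spec, tax, scope = "per-plot")
  x <- rowSums(tax) / 5
  y <- rowSums(spec) / 5
  bf <- bfOLS(x, y)
  expect_equal(reg$slope, bf$slope, tolerance = 1e-9)
  expect_equal(reg$n, 6)
})

test_that("mismatched plot ids are rejected", {
  a <- distMat(1:4, letters[1:4])
  b <- distMat(1:4, letters[2:5])
  expect_error(distanceRegression(a, b), "plot ids")
})

test_that("pooling across sites uses every site's pairs once", {
  set.seed(73)
  specList <- taxList <- list()
  for (s in c("s1", "s2")) {
    ids <- paste0(s, "_p", 1:5)
    taxList[[s]] <- distMat(rnorm(5), ids)
    specList[[s]] <- distMat(rnorm(5), ids)
  }
  out <- pooledDistanceRegression(specList, taxList)
  pooledRow <- out[out$scope == "across-sites", ]
  expect_equal(pooledRow$n, 20)  # 2 sites x 10 pairs
  xs <- c(taxList$s1[lower.tri(taxList$s1)], taxList$s2[lower.tri(taxList$s2)])
  ys <- c(specList$s1[lower.tri(specList$s1)],
          specList$s2[lower.tri(specList$s2)])
  bf <- bfOLS(xs, ys)
  expect_equal(pooledRow$slope, bf$slope, tolerance = 1e-9)
  expect_equal(nrow(out[out$scope == "per-site", ]), 2L)
})

test_that("the Mantel option returns a calibrated permutation p", {
  set.seed(74)
  ids <- paste0("p", 1:7)
  tax <- distMat(rnorm(7), ids)
  spec <- distMat(rnorm(7), ids)
  reg <- distanceRegression(spec, tax, mantel = TRUE, nPerm = 199, seed = 5)
  expect_gte(reg$p, 1 / 200)
  expect_lte(reg$p, 1)
  reg2 <- distanceRegression(spec, tax, mantel = TRUE, nPerm = 199, seed = 5)
  expect_identical(reg$p, reg2$p)
})

test_that("LAI class regressions recover an exact linear metric", {
  set.seed(75)
  n <- 24
  alpha <- data.frame(plot_id = paste0("p", 1:n),
                      sd_alpha = runif(n, 0.1, 2), n = 100)
  div <- data.frame(plot_id = alpha$plot_id,
                    richness = round(3 + 2 * alpha$sd_alpha),
                    shannon = 0.3 + 0.5 * alpha$sd_alpha,
                    pse = 0.9 - 0.1 * alpha$sd_alpha)
  lai <- data.frame(plot_id = alpha$plot_id,
                    lai = rep(c(0.3, 0.8, 1.5, 2.5), each = 6))
  out <- laiClassRegressions(alpha, div, lai)
  sh <- out[out$metric == "shannon", ]
  expect_equal(nrow(sh), 4L)
  expect_equal(sh$slope, rep(0.5, 4), tolerance = 1e-9)
  expect_equal(sh$r2, rep(1, 4), tolerance = 1e-9)
  expect_equal(sh$n, rep(6L, 4))
})

test_that("LAI class bounds follow the printed convention", {
  # class 1 is the closed interval [0.13, 0.634]
  alpha <- data.frame(plot_id = paste0("p", 1:6),
                      sd_alpha = c(1, 2, 3, 1.5, 2.5, 3.5), n = 10)
  div <- data.frame(plot_id = alpha$plot_id, richness = c(2, 4, 6, 3, 5, 7),
                    shannon = 1, pse = 0.5)
  lai <- data.frame(plot_id = alpha$plot_id,
                    lai = c(0.5, 0.13, 0.634, 0.3, 0.4, 0.6))
  out <- suppressWarnings(laiClassRegressions(alpha, div, lai))
  expect_true(all(out$lai_class == 1))
  expect_equal(unique(out$n), 6L)  # 0.5, 0.13 and 0.634 all in class 1
})

test_that("classes with fewer than three plots are skipped with a warning", {
  alpha <- data.frame(plot_id = paste0("p", 1:4),
                      sd_alpha = c(1, 2, 3, 4), n = 10)
  div <- data.frame(plot_id = alpha$plot_id, richness = 1:4,
                    shannon = 1, pse = 0.5)
  lai <- data.frame(plot_id = alpha$plot_id, lai = c(0.2, 0.3, 0.4, 2))
  expect_warning(out <- laiClassRegressions(alpha, div, lai), "skipped")
  expect_true(all(out$lai_class == 1))
})

test_that("a shuffled response gives calibrated naive p-values", {
  # null calibration: regress shuffled metrics on sd_alpha, 200 replicates
  set.seed(76)
  n <- 20
  x <- runif(n)
  rejections <- 0
  for (r in 1:200) {
    y <- rnorm(n)
    p <- specDiv:::olsFit(x, sample(y))$p
    if (p < 0.05) rejections <- rejections + 1
  }
  lo <- qbinom(0.025, 200, 0.05)
  hi <- qbinom(0.975, 200, 0.05)
  expect_gte(rejections, lo)
  expect_lte(rejections, hi)
})
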