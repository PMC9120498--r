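test_that("band exclusion removes tails and water windows", {
  wl <- seq(380, 2505, by = 5)  # the default 426-band grid
  cube <- spectralCube(array(0.3, c(2, 2, length(wl))), wl)
  dropped <- dropBadBands(cube)
  kept <- wavelengths(dropped)
  expect_false(any(kept == 1400))
  expect_false(any(kept <= 400 | kept >= 2400))
  # brute-force enumeration of the retained grid
  manual <- wl[wl > 400 & wl < 2400 &
                 !(wl >= 1340 & wl <= 1445) & !(wl >= 1790 & wl <= 1955)]
  expect_identical(kept, manual)
  expect_lt(length(kept), length(wl))
})

test_that("a grid with no bad bands passes through unchanged", {
  wl <- seq(500, 1300, by = 10)
  cube <- spectralCube(array(0.2, c(2, 2, length(wl))), wl)
  expect_identical(wavelengths(dropBadBands(cube)), as.numeric(wl))
  expect_identical(reflectance(dropBadBands(cube)), reflectance(cube))
})

test_that("removing every band is an error", {
  cube <- spectralCube(array(0.2, c(1, 1, 2)), c(390, 2450))
  expect_error(dropBadBands(cube), "every band")
})

test_that("NDVI follows its arithmetic definition", {
  cube <- spectralCube(array(c(0.05, 0.45), c(1, 1, 2)), c(660, 790))
  expect_equal(as.numeric(computeNDVI(cube)), 0.8, tolerance = 1e-12)
  cube2 <- spectralCube(array(c(0.3, 0.3), c(1, 1, 2)), c(660, 790))
  expect_equal(as.numeric(computeNDVI(cube2)), 0, tolerance = 1e-12)
  expect_error(computeNDVI(cube, redWindow = c(100, 200)), "red window")
})

test_that("rendered soil pixels have lower NDVI than vegetated ones", {
  lib <- monocultureLibrary(form = "tree")
  em <- reflectance(lib)[1, ]
  soil <- soilSpectrum(wlCoarse)
  vals <- array(NA_real_, c(1, 2, length(wlCoarse)))
  vals[1, 1, ] <- em
  vals[1, 2, ] <- soil
  cube <- spectralCube(vals, wlCoarse)
  nd <- computeNDVI(cube)
  expect_lt(nd[1, 2], nd[1, 1])
  expect_lt(nd[1, 2], 0.2)
  expect_gt(nd[1, 1], 0.6)
})

test_that("the NIR shade index is the window mean and scales linearly", {
  vals <- array(NA_real_, c(1, 1, 3))
  vals[1, 1, ] <- c(0.2, 0.4, 0.6)
  cube <- spectralCube(vals, c(752, 902, 1048))
  expect_equal(as.numeric(computeNIRShadeIndex(cube)), 0.4, tolerance = 1e-12)
  shaded <- spectralCube(vals * 0.1, c(752, 902, 1048))
  expect_equal(as.numeric(computeNIRShadeIndex(shaded)),
               0.04, tolerance = 1e-12)
  constant <- spectralCube(array(0.3, c(2, 2, 5)),
                           seq(760, 1040, length.out = 5))
  expect_true(all(abs(computeNIRShadeIndex(constant) - 0.3) < 1e-12))
})

# Build a 20 x 20 plot cube where exactly `nPass` pixels pass the NDVI mask
# (all pass the shade mask).
maskBoundaryCube <- function(nPass) {
  wl <- c(660, 790, 900)
  vals <- array(NA_real_, c(20, 20, 3))
  pass <- seq_len(400) <= nPass
  red <- ifelse(pass, 0.05, 0.50)
  vals[, , 1] <- matrix(red, 20, 20)
  vals[, , 2] <- 0.5
  vals[, , 3] <- 0.5
  spectralCube(vals, wl, plots = data.frame(
    plot_id = "p1", xmin = 0, ymin = 0, xmax = 20, ymax = 20))
}

test_that("a 20 m plot at 1 m pixels has 400 candidate pixels, all kept when passing", {
  cube <- maskBoundaryCube(400)
  ppm <- extractPlotPixels(cube, "p1")
  expect_equal(nrow(reflectance(ppm)), 400L)
  expect_equal(attr(ppm, "validFraction"), 1)
})

test_that("the 50% plot rule is inclusive at the boundary", {
  expect_message(
    rej <- extractPlotPixels(maskBoundaryCube(199), "p1"), "rejected")
  expect_null(rej)
  kept <- extractPlotPixels(maskBoundaryCube(200), "p1")
  expect_s4_class(kept, "PlotPixelMatrix")
  expect_equal(nrow(reflectance(kept)), 200L)
})

test_that("raising a threshold never enlarges the retained pixel set", {
  fix <- makeTestScene(nPlots = 4, seed = 31)
  cube <- sceneCube(fix$scene)
  poly <- plotPolygons(cube)[1, , drop = FALSE]
  pixAt <- function(ndvi, shade) {
    cfg <- maskConfig(shadeThresholds = c(forest = shade))
    p <- extractPlotPixels(cube, poly, cfg, "forest", ndviThreshold = ndvi)
    if (is.null(p)) matrix(numeric(), 0, 2) else p@coords
  }
  base <- pixAt(0.2, 0.10)
  for (case in list(c(0.5, 0.10), c(0.2, 0.20), c(0.7, 0.25))) {
    sub <- pixAt(case[1], case[2])
    expect_true(all(paste(sub[, 1], sub[, 2]) %in%
                      paste(base[, 1], base[, 2])))
    expect_lte(nrow(sub), nrow(base))
  }
})

test_that("retained pixels match a brute-force per-pixel re-evaluation", {
  fix <- makeTestScene(nPlots = 4, seed = 32)
  cube <- sceneCube(fix$scene)
  cfg <- maskConfig()
  ext <- extractSitePixels(cube, cfg, "forest", ndviThreshold = 0.3)
  nd <- computeNDVI(cube)
  sh <- computeNIRShadeIndex(cube)
  polys <- plotPolygons(cube)
  for (i in seq_len(nrow(polys))) {
    rows <- (polys$ymin[i] + 1):polys$ymax[i]
    cols <- (polys$xmin[i] + 1):polys$xmax[i]
    pass <- nd[rows, cols] >= 0.3 & sh[rows, cols] >= 0.18
    id <- polys$plot_id[i]
    if (mean(pass) >= 0.5) {
      expect_equal(nrow(reflectance(ext$pixels[[id]])), sum(pass))
    } else {
      expect_false(id %in% names(ext$pixels))
    }
    expect_equal(ext$report$validFraction[i], mean(pass))
  }
})

test_that("brightness normalization is exact, idempotent and scale-invariant", {
  expect_equal(brightnessNormalize(matrix(c(3, 4), 1)),
               matrix(c(0.6, 0.8), 1), tolerance = 1e-12)
  m <- matrix(runif(50, 0.1, 0.9), 10, 5)
  n1 <- brightnessNormalize(m)
  expect_equal(brightnessNormalize(n1), n1, tolerance = 1e-12)
  expect_equal(brightnessNormalize(m * 0.1), n1, tolerance = 1e-12)
  expect_true(all(abs(sqrt(rowSums(n1^2)) - 1) < 1e-12))
  expect_warning(brightnessNormalize(rbind(m, 0)), "zero-norm")
})
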