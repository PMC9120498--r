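#' Run configuration for the end-to-end pipeline
#'
#' Bundles and validates every tunable of a full run. Unknown arguments are
#' rejected (the constructor has no `...`), and per-stage seeds are derived
#' deterministically from the single root seed.
#'
#' @param nSites number of independent synthetic sites.
#' @param nSpecies species per site.
#' @param scene a [sceneConfig()].
#' @param mask a [maskConfig()].
#' @param varianceTarget PCA retained-variance target (default 0.95).
#' @param resolution crown-rasterization resolution in metres for
#'   [visibleCrownCover()] (default 0.1).
#' @param nTrees number of replicate phylogenies over which PSE is
#'   averaged (default 1).
#' @param nPerm co-inertia permutations (default 999).
#' @param vegetationType vegetation type used for the shade threshold.
#' @param writePixels write the per-plot masked pixel matrices as CSV.
#' @param writeRasters write the reflectance cube and truth rasters
#'   (default TRUE; disable for lightweight summary-only runs).
#' @param seed root seed for the whole run.
#' @param logLevel `"info"` or `"quiet"`.
#' @return a validated list of class `RunConfig`.
#' @export
runConfig <- function(nSites = 3L, nSpecies = 12L, scene = sceneConfig(),
                      mask = maskConfig(), varianceTarget = 0.95,
                      resolution = 0.1, nTrees = 1L, nPerm = 999L,
                      vegetationType = "forest", writePixels = TRUE,
                      writeRasters = TRUE,
                      seed = 1L, logLevel = c("info", "quiet")) {
  logLevel <- match.arg(logLevel)
  stopIfNot(inherits(scene, "SceneConfig"), "'scene' must be a sceneConfig()")
  stopIfNot(inherits(mask, "MaskConfig"), "'mask' must be a maskConfig()")
  stopIfNot(varianceTarget > 0 && varianceTarget <= 1,
            "'varianceTarget' must lie in (0, 1]")
  stopIfNot(resolution > 0 && resolution <= 0.5,
            "'resolution' must lie in (0, 0.5]")
  structure(list(nSites = checkCount(nSites, "nSites"),
                 nSpecies = checkCount(nSpecies, "nSpecies", 2L),
                 scene = scene, mask = mask,
                 varianceTarget = varianceTarget, resolution = resolution,
                 nTrees = checkCount(nTrees, "nTrees"),
                 nPerm = checkCount(nPerm, "nPerm"),
                 vegetationType = vegetationType,
                 writePixels = isTRUE(writePixels),
                 writeRasters = isTRUE(writeRasters),
                 seed = checkCount(seed, "seed", 0L), logLevel = logLevel),
            class = "RunConfig")
}

withStage <- function(stage, quiet, expr) {
  if (!quiet) message(sprintf("[%s] started", stage))
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
  if (!quiet)
    message(sprintf("[%s] done in %.1f s", stage,
                    proc.time()[["elapsed"]] - t0))
  out
}

# Analyse one simulated site end to end; returns the per-site tables.
analyseSite <- function(site, config, outDir) {
  quiet <- config$logLevel == "quiet"
  sdir <- file.path(outDir, site)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  baseSeed <- deriveSeed(config$seed, match(site, sprintf("site%02d",
                                                          1:config$nSites)) * 100L)

  sim <- withStage(paste0(site, ":simulate"), quiet, {
    phylos <- lapply(seq_len(config$nTrees), function(i)
      simulatePhylogeny(config$nSpecies, seed = baseSeed + i))
    lib <- simulateEndmembers(phylos[[1L]], config$scene$wavelengths,
                              seed = baseSeed + 20L)
    cm <- simulateCommunities(config$scene$nPlots, lib,
                              config$scene$gradientStrength,
                              seed = baseSeed + 30L,
                              totalCover = config$scene$totalCover)
    scene <- renderScene(cm, lib, config$scene, seed = baseSeed + 40L)
    ape::write.tree(phylos[[1L]], file.path(sdir, "phylogeny.nwk"))
    writeScene(scene, file.path(sdir, "scene"),
               rasters = config$writeRasters)
    list(phylos = phylos, lib = lib, cm = cm, scene = scene)
  })

  prep <- withStage(paste0(site, ":preprocess"), quiet, {
    ext <- extractSitePixels(sceneCube(sim$scene), config$mask,
                             config$vegetationType)
    pixels <- lapply(ext$pixels, brightnessNormalize)
    data.table::fwrite(ext$report, file.path(sdir, "mask_report.csv"))
    if (config$writePixels)
      for (id in names(pixels))
        data.table::fwrite(as.data.frame(pixels[[id]]@values),
                           file.path(sdir, sprintf("pixels_%s.csv", id)))
    pixels
  })

  spectral <- withStage(paste0(site, ":spectral"), quiet, {
    stopIfNot(length(prep) >= 2L,
              "fewer than 2 plots passed the valid-pixel rule")
    pca <- fitPooledPCA(prep, config$varianceTarget)
    alpha <- spectralAlpha(pca)
    means <- plotMeanSpectra(prep)
    beta <- spectralBetaDistances(means)
    data.table::fwrite(alpha, file.path(sdir, "sd_alpha.csv"))
    writeMatrixCSV(beta, file.path(sdir, "spectral_beta.csv"))
    list(pca = pca, alpha = alpha, means = means, beta = beta)
  })

  plant <- withStage(paste0(site, ":plantdiv"), quiet, {
    retained <- names(prep)
    species <- rownames(sim$lib@spectra)
    cover <- matrix(0, length(retained), length(species),
                    dimnames = list(retained, species))
    trees <- sceneTrees(sim$scene)
    und <- sceneUnderstory(sim$scene)
    polys <- plotPolygons(sceneCube(sim$scene))
    for (id in retained) {
      tr <- trees[trees$plot_id == id, , drop = FALSE]
      p <- polys[polys$plot_id == id, ]
      vis <- if (nrow(tr))
        visibleCrownCover(tr, p$xmax - p$xmin, config$resolution)
      else list(perSpecies = numeric(), total = 0)
      cover[id, ] <- combineCover(
        100 * vis$perSpecies,
        stats::setNames(as.numeric(und[id, ]), colnames(und)),
        vis$total)[species]
    }
    cover[is.na(cover)] <- 0
    div <- diversityTable(cover, sim$phylos)
    taxBeta <- taxonomicBetaDistances(cover)
    writeMatrixCSV(cover, file.path(sdir, "cover_topdown.csv"))
    data.table::fwrite(div, file.path(sdir, "diversity.csv"))
    writeMatrixCSV(taxBeta, file.path(sdir, "taxonomic_beta.csv"))
    list(cover = cover, div = div, taxBeta = taxBeta)
  })

  stats <- withStage(paste0(site, ":stats"), quiet, {
    reg <- distanceRegression(spectral$beta, plant$taxBeta)
    coin <- coinertiaTest(spectral$means,
                          hellingerTransform(plant$cover),
                          nPerm = config$nPerm, seed = baseSeed + 50L)
    ve <- varianceExplained(coin, spectral$means,
                            hellingerTransform(plant$cover), nAxes = 2L)
    data.table::fwrite(cbind(site = site, reg),
                       file.path(sdir, "distance_regression.csv"))
    list(reg = reg, coin = coin, ve = ve)
  })

  list(site = site, sim = sim, pixels = prep, spectral = spectral,
       plant = plant, stats = stats)
}

#' Run the full pipeline: simulate, preprocess, diversity, statistics
#'
#' Simulates `nSites` independent synthetic sites, runs masking, pooled
#' PCA, spectral and plant alpha/beta-diversity and the site statistics,
#' pools the distance regression across sites, fits LAI-class regressions,
#' and writes every output (plus a manifest with content hashes) under
#' `outDir`. Identical config and seed give an identical manifest.
#'
#' @param config a [runConfig()].
#' @param outDir output directory.
#' @return invisibly, a list with the per-site results, the pooled
#'   regression, the LAI-class regressions and the manifest path.
#' @export
runAll <- function(config = runConfig(), outDir) {
  stopIfNot(inherits(config, "RunConfig"), "'config' must be a runConfig()")
  stopIfNot(!missing(outDir) && is.character(outDir),
            "'outDir' is required")
  quiet <- config$logLevel == "quiet"
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sites <- sprintf("site%02d", seq_len(config$nSites))
  results <- lapply(sites, analyseSite, config = config, outDir = outDir)
  names(results) <- sites

  pooled <- withStage("stats:across-sites", quiet, {
    specList <- lapply(results, function(r) r$spectral$beta)
    taxList <- lapply(results, function(r) r$plant$taxBeta)
    out <- pooledDistanceRegression(specList, taxList)
    data.table::fwrite(out, file.path(outDir, "distance_regression_pooled.csv"))
    out
  })

  laiReg <- withStage("stats:lai-classes", quiet, {
    alpha <- do.call(rbind, lapply(results, function(r) {
      a <- r$spectral$alpha
      a$plot_id <- paste(r$site, a$plot_id, sep = ":")
      a
    }))
    div <- do.call(rbind, lapply(results, function(r) {
      d <- r$plant$div
      d$plot_id <- paste(r$site, d$plot_id, sep = ":")
      d
    }))
    lai <- do.call(rbind, lapply(results, function(r) {
      l <- sceneLAI(r$sim$scene)
      l$plot_id <- paste(r$site, l$plot_id, sep = ":")
      l
    }))
    out <- suppressWarnings(laiClassRegressions(alpha, div, lai))
    if (!is.null(out))
      data.table::fwrite(out, file.path(outDir, "lai_class_regressions.csv"))
    out
  })

  summary <- list(
    n_sites = config$nSites,
    seed = config$seed,
    pooled_slope = pooled$slope[1L],
    pooled_r2 = pooled$r2[1L],
    pooled_p = pooled$p[1L],
    coinertia_rv = vapply(results, function(r) r$stats$coin@rv, numeric(1L)),
    coinertia_p = vapply(results, function(r) r$stats$coin@pValue, numeric(1L)),
    variance_explained = vapply(results, function(r) r$stats$ve, numeric(1L))
  )
  jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- sort(list.files(outDir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  hashes <- unname(tools::md5sum(file.path(outDir, files)))
  manifest <- data.frame(file = files, md5 = hashes)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(results = results, pooled = pooled, laiClasses = laiReg,
                 manifest = file.path(outDir, "manifest.json")))
}
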