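# Readers and writers for the pipeline's on-disk formats. Everything is
# plain text: a JSON header + CSV pixel table for reflectance cubes,
# GeoJSON for plot polygons, Newick for phylogenies, CSV for all tables.

#' Write / read a SpectralCube as a JSON header + CSV pixel table
#'
#' `writeCube()` writes `<prefix>.json` (dimensions, wavelength grid, pixel
#' size, origin) plus `<prefix>.csv` (one row per pixel: `row`, `col`, then
#' one column per band), and the plot polygons as GeoJSON
#' (`<prefix>_plots.geojson`). `readCube()` reads the triplet back.
#'
#' @param cube a [SpectralCube-class].
#' @param prefix file path without extension.
#' @return `writeCube()`: invisibly, the paths written. `readCube()`: the
#'   cube.
#' @export
writeCube <- function(cube, prefix) {
  d <- dim(cube@values)
  header <- list(nrow = d[1L], ncol = d[2L], nband = d[3L],
                 wavelengths_nm = cube@wavelengths,
                 pixel_size_m = cube@pixelSize,
                 origin = cube@origin)
  jsonlite::write_json(header, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  idx <- expand.grid(row = seq_len(d[1L]), col = seq_len(d[2L]))
  m <- matrix(cube@values, d[1L] * d[2L], d[3L])
  colnames(m) <- sprintf("b%04.0f", cube@wavelengths)
  data.table::fwrite(cbind(idx, m), paste0(prefix, ".csv"))
  writePlotsGeoJSON(cube@plots, paste0(prefix, "_plots.geojson"))
  invisible(paste0(prefix, c(".json", ".csv", "_plots.geojson")))
}

#' @rdname writeCube
#' @export
readCube <- function(prefix) {
  stopIfNot(file.exists(paste0(prefix, ".json")),
            "cube header not found: %s.json", prefix)
  header <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- data.table::fread(paste0(prefix, ".csv"))
  vals <- as.matrix(tab[, -(1:2)])
  stopIfNot(nrow(vals) == header$nrow * header$ncol,
            "pixel table does not match the header dimensions")
  arr <- array(vals, c(header$nrow, header$ncol, header$nband))
  plots <- readPlotsGeoJSON(paste0(prefix, "_plots.geojson"))
  spectralCube(arr, header$wavelengths_nm, header$pixel_size_m,
               header$origin, plots)
}

#' Write / read plot rectangles as GeoJSON
#'
#' Each plot becomes a Polygon feature with a `plot_id` property; the ring
#' runs counter-clockwise from the lower-left corner.
#'
#' @param plots data.frame with `plot_id`, `xmin`, `ymin`, `xmax`, `ymax`.
#' @param path output path.
#' @export
writePlotsGeoJSON <- function(plots, path) {
  features <- lapply(seq_len(nrow(plots)), function(i) {
    p <- plots[i, ]
    ring <- list(c(p$xmin, p$ymin), c(p$xmax, p$ymin), c(p$xmax, p$ymax),
                 c(p$xmin, p$ymax), c(p$xmin, p$ymin))
    list(type = "Feature",
         properties = list(plot_id = p$plot_id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePlotsGeoJSON
#' @export
readPlotsGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    xy <- do.call(rbind, lapply(f$geometry$coordinates[[1L]], unlist))
    data.frame(plot_id = f$properties$plot_id,
               xmin = min(xy[, 1L]), ymin = min(xy[, 2L]),
               xmax = max(xy[, 1L]), ymax = max(xy[, 2L]))
  })
  do.call(rbind, rows)
}

#' Write a SyntheticScene to a directory
#'
#' Writes the reflectance cube (JSON + CSV + GeoJSON), the stem map and
#' percent-cover tables, per-plot LAI and the pixel ground truth as plain
#' text files.
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created if needed).
#' @param rasters also write the reflectance cube and pixel ground-truth
#'   rasters (default TRUE; tables are always written).
#' @return invisibly, the files written.
#' @export
writeScene <- function(scene, dir, rasters = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (rasters) writeCube(scene@cube, file.path(dir, "reflectance"))
  else writePlotsGeoJSON(scene@cube@plots, file.path(dir, "plots.geojson"))
  data.table::fwrite(scene@trees, file.path(dir, "trees.csv"))
  coverDF <- function(m) data.frame(plot_id = rownames(m),
                                    as.data.frame(m), check.names = FALSE)
  data.table::fwrite(coverDF(scene@understory),
                     file.path(dir, "understory_cover.csv"))
  data.table::fwrite(coverDF(scene@cover), file.path(dir, "combined_cover.csv"))
  data.table::fwrite(scene@lai, file.path(dir, "lai.csv"))
  if (rasters) {
    tr <- scene@truth
    data.table::fwrite(as.data.frame(tr$dominant),
                       file.path(dir, "truth_dominant.csv"))
    data.table::fwrite(as.data.frame(tr$soil),
                       file.path(dir, "truth_soil.csv"))
    data.table::fwrite(as.data.frame(tr$shade),
                       file.path(dir, "truth_shade.csv"))
  }
  invisible(list.files(dir, full.names = TRUE))
}

# Distance matrix / cover matrix CSV helpers (plot ids in the first column).
writeMatrixCSV <- function(m, path) {
  data.table::fwrite(data.frame(plot_id = rownames(m), as.data.frame(m),
                                check.names = FALSE), path)
  invisible(path)
}

readMatrixCSV <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  m
}
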