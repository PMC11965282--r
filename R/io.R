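#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows from the top of the
#' grid. Values are written with 17 significant digits so that read/write
#' round-trips are exact.
#'
#' @param mat numeric matrix (`NA` = nodata).
#' @param path output path (`.asc`).
#' @param xll,yll lower-left corner coordinates in metres.
#' @param cellsize pixel edge length in metres.
#' @param nodata nodata sentinel written to the file.
#' @return `path`, invisibly.
#' @export
write_asc <- function(mat, path, xll = 0, yll = 0, cellsize = 10,
                      nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(mat)),
    sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  m <- mat
  m[is.na(m)] <- nodata
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path input `.asc` path.
#' @return numeric matrix with attributes `xll`, `yll`, `cellsize`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  vals <- stats::setNames(vapply(hdr, function(h) as.numeric(h[2]), numeric(1)),
                          vapply(hdr, function(h) tolower(h[1]), character(1)))
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- do.call(rbind, lapply(body, as.numeric))
  if (nrow(m) != vals["nrows"] || ncol(m) != vals["ncols"]) {
    abort(sprintf("grid dimensions in %s do not match its header", path),
          class = "plasticmapr_io_error")
  }
  m[m == vals["nodata_value"]] <- NA_real_
  attr(m, "xll") <- unname(vals["xllcorner"])
  attr(m, "yll") <- unname(vals["yllcorner"])
  attr(m, "cellsize") <- unname(vals["cellsize"])
  m
}

#' Write a synthetic scene to a directory
#'
#' One ASCII grid per band and date (optical: blue/green/red/nir/cloud_prob;
#' radar: vv/vh), the truth map, the field table as CSV, and a JSON manifest
#' listing dates, band files and grid metadata.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- scene$truth$pixel_size
  manifest <- list(pixel_size = ps,
                   grid = dim(scene$truth$codes),
                   optical = list(), radar = list())
  for (a in scene$optical) {
    files <- list()
    for (b in c("blue", "green", "red", "nir", "cloud_prob")) {
      fn <- sprintf("optical_%03d_%s.asc", a$doy, b)
      write_asc(a[[b]], file.path(dir, fn), cellsize = ps)
      files[[b]] <- fn
    }
    manifest$optical[[length(manifest$optical) + 1L]] <-
      list(doy = a$doy, files = files)
  }
  for (a in scene$radar) {
    files <- list()
    for (b in c("vv", "vh")) {
      fn <- sprintf("radar_%03d_%s.asc", a$doy, b)
      write_asc(a[[b]], file.path(dir, fn), cellsize = ps)
      files[[b]] <- fn
    }
    manifest$radar[[length(manifest$radar) + 1L]] <-
      list(doy = a$doy, orbit = a$orbit, files = files)
  }
  write_asc(scene$truth$codes, file.path(dir, "truth.asc"), cellsize = ps)
  utils::write.csv(scene$fields, file.path(dir, "fields.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene directory back into acquisition lists
#'
#' Inverse of [write_scene()]: rebuilds the optical and radar series (sorted
#' by date), the truth map and the field table, enforcing grid consistency
#' across all files.
#'
#' @param dir directory written by [write_scene()].
#' @return list with `optical`, `radar`, `truth`, `fields`.
#' @export
read_raster_series <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    abort(sprintf("no acquisitions: %s has no manifest.json", dir),
          class = "plasticmapr_io_error")
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  gd <- unlist(manifest$grid)
  ps <- manifest$pixel_size
  check_grid <- function(m, fn) {
    if (nrow(m) != gd[1] || ncol(m) != gd[2]) {
      abort(sprintf("grid of %s (%dx%d) does not match the manifest (%dx%d)",
                    fn, nrow(m), ncol(m), gd[1], gd[2]),
            class = "plasticmapr_io_error")
    }
    m
  }
  if (!length(manifest$optical)) {
    abort(sprintf("no acquisitions listed in %s", mpath),
          class = "plasticmapr_io_error")
  }
  optical <- lapply(manifest$optical, function(e) {
    b <- lapply(e$files, function(fn) check_grid(read_asc(file.path(dir, fn)), fn))
    optical_acquisition(e$doy, b$blue, b$green, b$red, b$nir, b$cloud_prob)
  })
  radar <- lapply(manifest$radar, function(e) {
    b <- lapply(e$files, function(fn) check_grid(read_asc(file.path(dir, fn)), fn))
    radar_acquisition(e$doy, b$vv, b$vh, e$orbit)
  })
  optical <- optical[order(vapply(optical, `[[`, integer(1), "doy"))]
  radar <- radar[order(vapply(radar, `[[`, integer(1), "doy"))]
  truth_path <- file.path(dir, "truth.asc")
  truth <- if (file.exists(truth_path)) {
    class_map(check_grid(read_asc(truth_path), "truth.asc"), pixel_size = ps)
  } else NULL
  fields_path <- file.path(dir, "fields.csv")
  fields <- if (file.exists(fields_path)) {
    tibble::as_tibble(utils::read.csv(fields_path))
  } else NULL
  list(optical = optical, radar = radar, truth = truth, fields = fields)
}

#' Write a class map as an ASCII grid with a class-name sidecar
#'
#' @param map a [class_map()].
#' @param path output `.asc` path; a `.json` sidecar with the level names is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_class_map <- function(map, path) {
  write_asc(map$codes, path, cellsize = map$pixel_size)
  jsonlite::write_json(list(levels = map$levels, pixel_size = map$pixel_size),
                       sub("\\.asc$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a class map written by [write_class_map()]
#' @param path `.asc` path.
#' @return a [class_map()].
#' @export
read_class_map <- function(path) {
  meta <- jsonlite::read_json(sub("\\.asc$", ".json", path),
                              simplifyVector = TRUE)
  m <- read_asc(path)
  class_map(matrix(as.integer(m), nrow(m), ncol(m)),
            levels = meta$levels, pixel_size = meta$pixel_size)
}

#' Write a hexagon summary as GeoJSON
#'
#' Hexagon polygons (clipped to the extent) with their summary attributes as
#' a GeoJSON FeatureCollection in the grid's metric coordinates.
#'
#' @param grid a [build_hex_grid()].
#' @param summary tibble keyed by `hex_id`.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_hex_geojson <- function(grid, summary, path) {
  feats <- lapply(seq_len(nrow(grid$hexes)), function(i) {
    h <- grid$hexes[i, ]
    props <- as.list(summary[summary$hex_id == h$hex_id, , drop = FALSE])
    props$vertices <- NULL
    ring <- h$vertices[[1]]
    ring <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature",
         properties = lapply(props, function(v) if (length(v)) v[[1]] else NULL),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
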