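#' @importFrom rlang abort warn %||%
#' @importFrom stats quantile rgamma rnorm runif lm pt sd median predict
#' @importFrom utils head modifyList
NULL

# ---- internal helpers for matrix "rasters" -----------------------------------
# Rasters are plain numeric matrices (rows = grid rows, cols = grid cols).
# Row 1 is the top of the scene; x/y coordinates place the grid origin at the
# lower-left corner so that x = (col - 0.5) * pixel_size and
# y = (nrow - row + 0.5) * pixel_size for pixel centres.

stopifnot_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix", name), class = "plasticmapr_config_error")
  }
  invisible(x)
}

same_dim <- function(a, b) identical(dim(a), dim(b))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half away from zero
#'
#' Report-style rounding used when formatting accuracy percentages: ties go
#' away from zero, matching how map-accuracy tables are conventionally printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Pixel-centre coordinates of a grid
#'
#' @param nrow,ncol grid dimensions in pixels.
#' @param pixel_size pixel edge length in metres.
#' @return list with matrices `x` and `y` (metres, origin at the lower-left
#'   grid corner).
#' @keywords internal
pixel_centres <- function(nrow, ncol, pixel_size) {
  x <- matrix(rep((seq_len(ncol) - 0.5) * pixel_size, each = nrow), nrow, ncol)
  y <- matrix(rep((nrow - seq_len(nrow) + 0.5) * pixel_size, times = ncol), nrow, ncol)
  list(x = x, y = y)
}

# ---- acquisition containers --------------------------------------------------

#' Optical acquisition
#'
#' One date of co-registered optical imagery: four reflectance bands in
#' \eqn{[0, 1]}, a per-pixel cloud probability in percent, and a validity mask.
#'
#' @param doy acquisition day of year (1-366).
#' @param blue,green,red,nir reflectance matrices in \eqn{[0, 1]}.
#' @param cloud_prob cloud probability matrix in \eqn{[0, 100]}.
#' @param valid logical validity matrix; defaults to all valid.
#' @return an object of class `optical_acquisition`.
#' @export
optical_acquisition <- function(doy, blue, green, red, nir, cloud_prob,
                                valid = NULL) {
  if (doy < 1 || doy > 366) {
    abort("`doy` must be in 1..366", class = "plasticmapr_domain_error")
  }
  for (nm in c("blue", "green", "red", "nir", "cloud_prob")) {
    stopifnot_matrix(get(nm), nm)
  }
  bands <- list(blue = blue, green = green, red = red, nir = nir)
  if (!all(vapply(bands, same_dim, logical(1), b = blue)) ||
      !same_dim(cloud_prob, blue)) {
    abort("all optical bands must share the same dimensions",
          class = "plasticmapr_config_error")
  }
  if (is.null(valid)) valid <- matrix(TRUE, nrow(blue), ncol(blue))
  structure(
    list(doy = as.integer(doy), blue = blue, green = green, red = red,
         nir = nir, cloud_prob = cloud_prob, valid = valid),
    class = "optical_acquisition"
  )
}

#' Radar acquisition
#'
#' One date of dual-polarised radar backscatter (VV and VH, decibels).
#'
#' @param doy acquisition day of year.
#' @param vv,vh backscatter coefficient matrices in dB.
#' @param orbit `"ascending"` or `"descending"`.
#' @return an object of class `radar_acquisition`.
#' @export
radar_acquisition <- function(doy, vv, vh, orbit = c("ascending", "descending")) {
  orbit <- match.arg(orbit)
  stopifnot_matrix(vv, "vv"); stopifnot_matrix(vh, "vh")
  if (!same_dim(vv, vh)) {
    abort("`vv` and `vh` must share dimensions", class = "plasticmapr_config_error")
  }
  structure(list(doy = as.integer(doy), vv = vv, vh = vh, orbit = orbit),
            class = "radar_acquisition")
}

#' Fused optical-radar acquisition
#'
#' The unit produced by sensor pairing and index computation: 11 co-registered
#' bands (blue, green, red, nir, ndvi, gndvi, bndvi, msavi, vv, vh,
#' vvvh_ratio) plus a validity mask. Before [compute_indices()] is applied the
#' index bands may be absent.
#'
#' @param doy optical day of year of the pair.
#' @param bands named list of band matrices.
#' @param valid logical validity matrix.
#' @param radar_doy day of year of the paired radar acquisition.
#' @return an object of class `fused_acquisition`.
#' @export
fused_acquisition <- function(doy, bands, valid, radar_doy = NA_integer_) {
  structure(list(doy = as.integer(doy), bands = bands, valid = valid,
                 radar_doy = as.integer(radar_doy)),
            class = "fused_acquisition")
}

#' The 11 fused band names
#' @return character vector of the 11 band names in canonical order.
#' @export
fused_band_names <- function() {
  c("blue", "green", "red", "nir", "ndvi", "gndvi", "bndvi", "msavi",
    "vv", "vh", "vvvh_ratio")
}

#' Fused annual series
#'
#' Chronologically ordered collection of [fused_acquisition()] objects over a
#' common grid; the unit that all feature extraction consumes.
#'
#' @param acquisitions list of `fused_acquisition` objects.
#' @param pixel_size pixel edge length in metres.
#' @return an object of class `fused_series`.
#' @export
fused_series <- function(acquisitions, pixel_size = 10) {
  ord <- order(vapply(acquisitions, `[[`, integer(1), "doy"))
  structure(list(acquisitions = acquisitions[ord], pixel_size = pixel_size),
            class = "fused_series")
}

#' @export
length.fused_series <- function(x) length(x$acquisitions)

#' @export
print.fused_series <- function(x, ...) {
  doys <- vapply(x$acquisitions, `[[`, integer(1), "doy")
  cat(sprintf("<fused_series> %d acquisitions, doy %s..%s, %d bands each\n",
              length(doys), min(doys), max(doys),
              length(x$acquisitions[[1]]$bands)))
  invisible(x)
}

# ---- class map ---------------------------------------------------------------

#' Class levels of the plasticulture map
#' @return `c("PFF", "PMF", "PCV")`: plastic-free farmland, plastic-mulched
#'   farmland, plastic cover above vegetation.
#' @export
plastic_classes <- function() c("PFF", "PMF", "PCV")

#' Categorical class map
#'
#' Per-pixel land-use label over `{PFF, PMF, PCV}` with `NA` as nodata.
#'
#' @param codes integer matrix of 1-based level codes (`NA` = nodata), or a
#'   character matrix of labels.
#' @param levels class labels, default [plastic_classes()].
#' @param pixel_size pixel edge length in metres.
#' @return an object of class `class_map`.
#' @export
class_map <- function(codes, levels = plastic_classes(), pixel_size = 10) {
  if (is.character(codes)) {
    codes <- matrix(match(codes, levels), nrow(codes), ncol(codes))
  }
  bad <- codes[!is.na(codes)]
  if (length(bad) && (any(bad < 1) || any(bad > length(levels)))) {
    abort("class codes outside the declared levels", class = "plasticmapr_config_error")
  }
  structure(list(codes = codes, levels = levels, pixel_size = pixel_size),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(x$levels[x$codes], levels = x$levels), useNA = "no")
  cat(sprintf("<class_map> %dx%d @ %gm | %s | nodata %d\n",
              nrow(x$codes), ncol(x$codes), x$pixel_size,
              paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
              sum(is.na(x$codes))))
  invisible(x)
}

#' Labels of a class map as a character matrix
#' @param map a [class_map()].
#' @return character matrix of labels with `NA` for nodata.
#' @export
class_map_labels <- function(map) {
  matrix(map$levels[map$codes], nrow(map$codes), ncol(map$codes))
}

#' Convert a class map to a tibble of pixels
#'
#' @param x a [class_map()].
#' @param ... unused.
#' @return tibble with `row`, `col`, `x`, `y` (metres) and `class`.
#' @export
as_tibble.class_map <- function(x, ...) {
  nr <- nrow(x$codes); nc <- ncol(x$codes)
  cc <- pixel_centres(nr, nc, x$pixel_size)
  cls <- factor(x$levels[as.vector(x$codes)], levels = x$levels)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = as.vector(cc$x), y = as.vector(cc$y),
    class = cls
  )
}
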