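#' Bare-soil frequency index from an NDVI series
#'
#' For each pixel, counts NDVI observations below versus at-or-above the
#' series midpoint and normalises their difference:
#' \deqn{soil\_cover = \frac{\#\{NDVI_i < NDVI_{mid}\} - \#\{NDVI_i \ge NDVI_{mid}\}}{n}}
#' with \eqn{NDVI_{mid} = (NDVI_{max} + NDVI_{min})/2} taken from the same
#' pixel's series. Values above 0 mark pixels observed more often in
#' bare-soil than in vegetated conditions; a constant series yields -1 (every
#' observation satisfies the \eqn{\ge} branch). Pixels with no valid
#' observation are nodata.
#'
#' @param series a [fused_series()] with an `ndvi` band, or a list with an
#'   `ndvi` 3-d array and `valid` array.
#' @return object of class `soil_cover_layer`: matrices `soil_cover`
#'   (\eqn{[-1, 1]}), `n`, `ndvi_mid`, `ndvi_max`, `ndvi_min`.
#' @export
soil_cover <- function(series) {
  acqs <- series$acquisitions
  nr <- nrow(acqs[[1]]$valid); nc <- ncol(acqs[[1]]$valid)
  npix <- nr * nc
  V <- matrix(vapply(acqs, function(a) as.vector(a$bands$ndvi), numeric(npix)),
              npix, length(acqs))
  valid <- matrix(vapply(acqs, function(a) as.vector(a$valid), logical(npix)),
                  npix, length(acqs))
  V[!valid | is.na(V)] <- NA_real_
  n <- rowSums(!is.na(V))
  mx <- suppressWarnings(apply(V, 1, max, na.rm = TRUE))
  mi <- suppressWarnings(apply(V, 1, min, na.rm = TRUE))
  mid <- (mx + mi) / 2
  below <- rowSums(V < mid, na.rm = TRUE)
  at_or_above <- rowSums(V >= mid, na.rm = TRUE)
  sc <- (below - at_or_above) / n
  sc[n == 0] <- NA_real_
  mid[n == 0] <- NA_real_; mx[n == 0] <- NA_real_; mi[n == 0] <- NA_real_
  structure(list(soil_cover = matrix(sc, nr, nc), n = matrix(n, nr, nc),
                 ndvi_mid = matrix(mid, nr, nc),
                 ndvi_max = matrix(mx, nr, nc),
                 ndvi_min = matrix(mi, nr, nc),
                 pixel_size = series$pixel_size),
            class = "soil_cover_layer")
}

# ---- hexagonal grid ----------------------------------------------------------

# Sutherland-Hodgman clipping of a convex polygon (matrix of x,y rows)
# against the rectangle [xmin, xmax] x [ymin, ymax].
clip_to_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    if (!nrow(pts)) return(pts)
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1) n else i - 1, ]
      ci <- inside(cur); pi <- inside(prev)
      if (ci) {
        if (!pi) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pi) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, axis) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  poly <- clip_edge(poly, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  poly <- clip_edge(poly, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  poly <- clip_edge(poly, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  poly <- clip_edge(poly, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  poly
}

shoelace_area <- function(poly) {
  if (is.null(nrow(poly)) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Regular hexagonal grid over an extent
#'
#' Flat-topped regular hexagons of the requested nominal area tiling the
#' rectangular extent, with edge hexagons clipped to it. Interior hexagons
#' have area \eqn{(3\sqrt{3}/2) s^2} where `s` is the side length.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in metres.
#' @param hex_area_ha nominal hexagon area in hectares (the country-scale
#'   default of 11.6e3 ha scales down for synthetic scenes).
#' @return object of class `hex_grid`: tibble `hexes` with `hex_id`, axial
#'   coordinates `q`, `r`, centre coordinates, clipped `area_ha` and a
#'   vertex list-column; plus the side length `s` and the extent.
#' @export
build_hex_grid <- function(extent, hex_area_ha) {
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3]) {
    abort("`extent` must be c(xmin, xmax, ymin, ymax) with positive spans",
          class = "plasticmapr_config_error")
  }
  if (hex_area_ha <= 0) {
    abort("`hex_area_ha` must be positive", class = "plasticmapr_config_error")
  }
  area_m2 <- hex_area_ha * 1e4
  s <- sqrt(2 * area_m2 / (3 * sqrt(3)))
  x0 <- extent[1]; y0 <- extent[3]
  # flat-top axial layout: centre(q, r) = (x0 + 1.5 s q, y0 + sqrt(3) s (r + q/2))
  qmax <- ceiling((extent[2] - x0) / (1.5 * s)) + 1L
  hexes <- list()
  ang <- seq(0, 300, by = 60) * pi / 180
  vx <- s * cos(ang); vy <- s * sin(ang)
  for (q in seq(-1L, qmax)) {
    cx <- x0 + 1.5 * s * q
    rmin <- floor((extent[3] - y0) / (sqrt(3) * s) - q / 2) - 1L
    rmax <- ceiling((extent[4] - y0) / (sqrt(3) * s) - q / 2) + 1L
    for (r in seq(rmin, rmax)) {
      cy <- y0 + sqrt(3) * s * (r + q / 2)
      poly <- cbind(cx + vx, cy + vy)
      poly_clip <- clip_to_rect(poly, extent[1], extent[2], extent[3], extent[4])
      a <- shoelace_area(poly_clip)
      if (a <= 0) next
      hexes[[length(hexes) + 1L]] <- tibble::tibble(
        hex_id = sprintf("h%d_%d", q, r), q = q, r = r, cx = cx, cy = cy,
        area_ha = a / 1e4, clipped = a < shoelace_area(poly) * (1 - 1e-9),
        vertices = list(poly_clip)
      )
    }
  }
  structure(list(hexes = dplyr::bind_rows(hexes), s = s, extent = extent,
                 hex_area_ha = hex_area_ha),
            class = "hex_grid")
}

#' Assign points to hexagons
#'
#' Exact nearest-centre assignment via axial cube rounding; every point of
#' the extent belongs to exactly one hexagon.
#'
#' @param grid a [build_hex_grid()] result.
#' @param x,y point coordinates in metres.
#' @return character vector of `hex_id`s (`NA` for points whose hexagon is
#'   not part of the grid, i.e. points outside the extent).
#' @export
hex_assign <- function(grid, x, y) {
  s <- grid$s
  x <- x - grid$extent[1]; y <- y - grid$extent[3]
  qf <- (2 / 3) * x / s
  rf <- (-1 / 3 * x + sqrt(3) / 3 * y) / s
  # cube rounding
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  ids <- sprintf("h%d_%d", as.integer(rx), as.integer(rz))
  ids[!ids %in% grid$hexes$hex_id] <- NA_character_
  ids
}

#' Per-hexagon class areas
#'
#' Sums the mapped area of each class within each hexagon (pixel count times
#' pixel area); totals are conserved across the grid.
#'
#' @param map a [class_map()].
#' @param grid a [build_hex_grid()] sharing the map's coordinate frame
#'   (origin at the lower-left map corner).
#' @return tibble: `hex_id`, `area_pff_ha`, `area_pmf_ha`, `area_pcv_ha`,
#'   `area_classified_ha`.
#' @export
hex_aggregate_area <- function(map, grid) {
  nr <- nrow(map$codes); nc <- ncol(map$codes)
  cc <- pixel_centres(nr, nc, map$pixel_size)
  ids <- hex_assign(grid, as.vector(cc$x), as.vector(cc$y))
  px_ha <- map$pixel_size^2 / 1e4
  lab <- as.vector(class_map_labels(map))
  df <- tibble::tibble(hex_id = ids, class = lab)
  df <- df[!is.na(df$hex_id), ]
  out <- df |>
    dplyr::group_by(.data$hex_id) |>
    dplyr::summarise(
      area_pff_ha = sum(.data$class == "PFF", na.rm = TRUE) * px_ha,
      area_pmf_ha = sum(.data$class == "PMF", na.rm = TRUE) * px_ha,
      area_pcv_ha = sum(.data$class == "PCV", na.rm = TRUE) * px_ha,
      area_classified_ha = sum(!is.na(.data$class)) * px_ha,
      .groups = "drop"
    )
  dplyr::left_join(dplyr::select(grid$hexes, "hex_id", "cx", "cy", "area_ha"),
                   out, by = "hex_id") |>
    tidyr::replace_na(list(area_pff_ha = 0, area_pmf_ha = 0,
                           area_pcv_ha = 0, area_classified_ha = 0))
}

#' Per-hexagon regression of FPD on soil_cover
#'
#' Ordinary least squares of the frequency of plastic detection on the
#' bare-soil index over the valid pixels of each hexagon. A high R-squared
#' means plastic detections track bare-soil observation counts — the
#' signature of soil-driven false positives. Hexagons with fewer than
#' `min_pixels` valid pixels, or with a zero-variance regressor, are
#' undefined (`NA`, not 0).
#'
#' @param fpd a [compute_fpd()] result.
#' @param soil a [soil_cover()] result on the same grid.
#' @param grid a [build_hex_grid()].
#' @param min_pixels minimum valid pixels per regression (default 30).
#' @return tibble: `hex_id`, `n_pixels`, `r_squared`, `slope`, `p_value`.
#' @export
hex_regression <- function(fpd, soil, grid, min_pixels = 30) {
  nr <- nrow(fpd$fpd); nc <- ncol(fpd$fpd)
  cc <- pixel_centres(nr, nc, fpd$pixel_size)
  ids <- hex_assign(grid, as.vector(cc$x), as.vector(cc$y))
  df <- tibble::tibble(hex_id = ids, fpd = as.vector(fpd$fpd),
                       sc = as.vector(soil$soil_cover))
  df <- df[!is.na(df$hex_id) & !is.na(df$fpd) & !is.na(df$sc), ]
  fit_one <- function(d) {
    n <- nrow(d)
    if (n < min_pixels || stats::var(d$sc) == 0) {
      return(tibble::tibble(n_pixels = n, r_squared = NA_real_,
                            slope = NA_real_, p_value = NA_real_))
    }
    fit <- lm(fpd ~ sc, data = d)
    sm <- summary(fit)
    tibble::tibble(n_pixels = n, r_squared = sm$r.squared,
                   slope = unname(stats::coef(fit)[2]),
                   p_value = sm$coefficients[2, 4])
  }
  res <- df |>
    dplyr::group_by(.data$hex_id) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup()
  dplyr::left_join(dplyr::select(grid$hexes, "hex_id", "cx", "cy"),
                   res, by = "hex_id")
}

#' Flag false-hotspot hexagons
#'
#' A hexagon is flagged when its FPD~soil_cover regression reaches the
#' R-squared threshold at the required significance; flagged hexagons can
#' then be masked out of the class map with [mask_flagged()]. Flagging is
#' monotone in both thresholds.
#'
#' @param summary tibble from [hex_regression()] (optionally joined with
#'   [hex_aggregate_area()]).
#' @param r2_threshold minimum R-squared (default 0.3, the lower edge of a
#'   moderate correlation).
#' @param p_threshold maximum slope p-value (default 1e-4, a 0.01%
#'   significance level).
#' @return `summary` with a logical `flagged` column (`FALSE` where the
#'   regression is undefined).
#' @export
flag_hotspots <- function(summary, r2_threshold = 0.3, p_threshold = 1e-4) {
  dplyr::mutate(summary, flagged = !is.na(.data$r_squared) &
                  .data$r_squared >= r2_threshold &
                  !is.na(.data$p_value) & .data$p_value <= p_threshold)
}

#' Null the plasticulture classes inside flagged hexagons
#'
#' @param map a [class_map()].
#' @param grid the [build_hex_grid()] used for flagging.
#' @param summary a [flag_hotspots()] result.
#' @return the masked [class_map()].
#' @export
mask_flagged <- function(map, grid, summary) {
  flagged <- summary$hex_id[summary$flagged]
  if (!length(flagged)) return(map)
  nr <- nrow(map$codes); nc <- ncol(map$codes)
  cc <- pixel_centres(nr, nc, map$pixel_size)
  ids <- hex_assign(grid, as.vector(cc$x), as.vector(cc$y))
  plastic <- map$codes %in% match(c("PMF", "PCV"), map$levels)
  kill <- matrix(ids %in% flagged, nr, nc) & plastic
  codes <- map$codes
  codes[kill] <- NA_integer_
  class_map(codes, levels = map$levels, pixel_size = map$pixel_size)
}
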