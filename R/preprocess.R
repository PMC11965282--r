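#' Preprocessing configuration
#'
#' Tunables of the cloud-filtering, speckle-smoothing and sensor-pairing
#' stage.
#'
#' @param scene_cloud_max maximum per-scene cloud fraction; optical
#'   acquisitions with a larger cloudy-pixel fraction are dropped entirely
#'   (default 0.60).
#' @param pixel_cloud_prob_threshold cloud-probability threshold in percent at
#'   or above which a pixel counts as cloudy (default 40).
#' @param speckle_radius_m radius in metres of the circular focal-mean speckle
#'   filter (default 50, i.e. an 81-pixel disc on a 10 m grid).
#' @param pairing_window_days maximum day gap when attaching the closest
#'   radar acquisition to each optical acquisition (default 5).
#' @param min_obs minimum number of valid observations a pixel needs for
#'   annual aggregation (default 5).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(scene_cloud_max = 0.60,
                              pixel_cloud_prob_threshold = 40,
                              speckle_radius_m = 50,
                              pairing_window_days = 5,
                              min_obs = 5) {
  if (scene_cloud_max <= 0 || pixel_cloud_prob_threshold <= 0 ||
      speckle_radius_m <= 0 || pairing_window_days < 0) {
    abort("preprocess thresholds must be positive (pairing window >= 0)",
          class = "plasticmapr_config_error")
  }
  structure(list(scene_cloud_max = scene_cloud_max,
                 pixel_cloud_prob_threshold = pixel_cloud_prob_threshold,
                 speckle_radius_m = speckle_radius_m,
                 pairing_window_days = pairing_window_days,
                 min_obs = min_obs),
            class = "preprocess_config")
}

#' Drop optical acquisitions with excessive scene cloud cover
#'
#' An acquisition is dropped when the fraction of its pixels whose cloud
#' probability reaches `pixel_threshold` exceeds `max_frac`; the order of the
#' surviving acquisitions is preserved.
#'
#' @param optical_series list of [optical_acquisition()] objects.
#' @param max_frac maximum tolerated cloudy-pixel fraction per scene.
#' @param pixel_threshold per-pixel cloud-probability threshold in percent.
#' @return the filtered list, with attribute `"dropped_doys"` recording the
#'   days of year removed.
#' @export
filter_scene_cloud_fraction <- function(optical_series, max_frac = 0.6,
                                        pixel_threshold = 40) {
  fracs <- vapply(optical_series, function(a) {
    mean(a$cloud_prob >= pixel_threshold)
  }, numeric(1))
  keep <- fracs <= max_frac
  if (!any(keep)) {
    abort("no usable acquisitions: every scene exceeds the cloud-fraction limit",
          class = "plasticmapr_empty_series_error")
  }
  out <- optical_series[keep]
  attr(out, "dropped_doys") <-
    vapply(optical_series[!keep], `[[`, integer(1), "doy")
  out
}

#' Mask cloudy pixels of an optical acquisition
#'
#' Clears the validity mask wherever the cloud probability reaches
#' `threshold`; band values under the cleared mask are never used downstream.
#'
#' @param acq an [optical_acquisition()].
#' @param threshold cloud-probability threshold in percent.
#' @return the acquisition with an updated `valid` mask.
#' @export
mask_clouds <- function(acq, threshold = 40) {
  acq$valid <- acq$valid & (acq$cloud_prob < threshold)
  acq
}

# Offsets (dr, dc) of the discrete disc: pixel centres within radius_px of the
# target centre. radius_px = 5 gives the 81-member disc of a 50 m radius on a
# 10 m grid.
disc_offsets <- function(radius_px) {
  r <- floor(radius_px)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius_px^2, , drop = FALSE]
}

#' Focal mean over a discrete disc
#'
#' Replaces each pixel by the mean over the disc of pixels whose centre lies
#' within `radius_px` pixels of the target centre. Edge pixels use the
#' in-bounds subset of the disc; `NA` cells are excluded from both numerator
#' and denominator.
#'
#' @param mat numeric matrix.
#' @param radius_px disc radius in pixel units.
#' @return matrix of disc means (`NA` where no disc member is available).
#' @export
focal_disc_mean <- function(mat, radius_px) {
  off <- disc_offsets(radius_px)
  nr <- nrow(mat); nc <- ncol(mat)
  ok <- !is.na(mat)
  vals <- ifelse(ok, mat, 0)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (i in seq_len(nrow(off))) {
    dr <- off$dr[i]; dc <- off$dc[i]
    r_dst <- max(1, 1 - dr):min(nr, nr - dr)
    c_dst <- max(1, 1 - dc):min(nc, nc - dc)
    r_src <- r_dst + dr
    c_src <- c_dst + dc
    acc[r_dst, c_dst] <- acc[r_dst, c_dst] + vals[r_src, c_src]
    cnt[r_dst, c_dst] <- cnt[r_dst, c_dst] + ok[r_src, c_src]
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Circular focal-mean speckle filter
#'
#' Smooths both backscatter bands of a radar acquisition with the mean over a
#' discrete disc of `radius_m` metres (81 pixels for 50 m on a 10 m grid).
#'
#' @param acq a [radar_acquisition()].
#' @param radius_m smoothing radius in metres.
#' @param pixel_size pixel edge length in metres.
#' @return the acquisition with smoothed `vv` and `vh`.
#' @export
speckle_focal_mean <- function(acq, radius_m = 50, pixel_size = 10) {
  if (radius_m < pixel_size) {
    abort("`radius_m` must be at least one pixel", class = "plasticmapr_config_error")
  }
  radius_px <- radius_m / pixel_size
  acq$vv <- focal_disc_mean(acq$vv, radius_px)
  acq$vh <- focal_disc_mean(acq$vh, radius_px)
  acq
}

#' Pair each optical acquisition with its closest radar acquisition
#'
#' For every optical acquisition the radar acquisition minimising the
#' absolute day gap is attached, provided the gap does not exceed
#' `window_days`; optical acquisitions without a partner are dropped. Ties
#' between equidistant radar dates are broken toward the earlier date. Both
#' orbits are eligible.
#'
#' @param optical_series list of (cloud-masked) [optical_acquisition()]s.
#' @param radar_series list of (speckle-filtered) [radar_acquisition()]s.
#' @param window_days maximum |day gap|.
#' @param pixel_size pixel edge length in metres carried to the fused series.
#' @return a [fused_series()] of pre-index [fused_acquisition()]s carrying
#'   the 4 optical bands, `vv`, `vh` and the optical validity mask; attribute
#'   `"pairing"` holds a tibble of (optical_doy, radar_doy, gap) with dropped
#'   dates marked by `NA` radar_doy.
#' @export
pair_sensors <- function(optical_series, radar_series, window_days = 5,
                         pixel_size = 10) {
  if (!length(optical_series) || !length(radar_series)) {
    abort("both series must be non-empty", class = "plasticmapr_empty_series_error")
  }
  radar_doys <- vapply(radar_series, `[[`, integer(1), "doy")
  fused <- list()
  log <- vector("list", length(optical_series))
  for (i in seq_along(optical_series)) {
    opt <- optical_series[[i]]
    gaps <- abs(radar_doys - opt$doy)
    best <- min(gaps)
    # ties toward the earlier radar date
    j <- which(gaps == best)[which.min(radar_doys[gaps == best])]
    if (best <= window_days) {
      rad <- radar_series[[j]]
      fused[[length(fused) + 1L]] <- fused_acquisition(
        doy = opt$doy,
        bands = list(blue = opt$blue, green = opt$green, red = opt$red,
                     nir = opt$nir, vv = rad$vv, vh = rad$vh),
        valid = opt$valid,
        radar_doy = rad$doy
      )
      log[[i]] <- tibble::tibble(optical_doy = opt$doy,
                                 radar_doy = rad$doy, gap = best)
    } else {
      log[[i]] <- tibble::tibble(optical_doy = opt$doy,
                                 radar_doy = NA_integer_, gap = best)
    }
  }
  if (!length(fused)) {
    abort("empty fused series: no optical acquisition has a radar partner within the window",
          class = "plasticmapr_empty_series_error")
  }
  out <- fused_series(fused, pixel_size = pixel_size)
  attr(out, "pairing") <- dplyr::bind_rows(log)
  out
}

#' Compute the spectral indices and the VV/VH ratio of a fused acquisition
#'
#' Adds the four optical indices and the dB-domain VV/VH ratio so that the
#' acquisition carries the canonical 11 bands:
#' \deqn{NDVI = (NIR - red)/(NIR + red)}
#' \deqn{GNDVI = (NIR - green)/(NIR + green)}
#' \deqn{BNDVI = (NIR - blue)/(NIR + blue)}
#' \deqn{MSAVI = (2 NIR + 1 - \sqrt{(2 NIR + 1)^2 - 8 (NIR - red)})/2}
#' The VV/VH ratio is computed as `vv - vh`, the logarithm of the linear
#' ratio since the inputs are backscatter in dB. Pixels with a zero
#' normalised-difference denominator are marked invalid; MSAVI is clamped to
#' \eqn{[-1, 1]} to guard degenerate reflectances. Idempotent: recomputing on
#' an 11-band acquisition leaves it unchanged.
#'
#' @param acq a pre-index [fused_acquisition()] with bands blue, green, red,
#'   nir, vv, vh.
#' @return the acquisition with all 11 bands and an updated validity mask.
#' @export
compute_indices <- function(acq) {
  b <- acq$bands
  needed <- c("blue", "green", "red", "nir", "vv", "vh")
  if (!all(needed %in% names(b))) {
    abort(sprintf("missing bands: %s",
                  paste(setdiff(needed, names(b)), collapse = ", ")),
          class = "plasticmapr_config_error")
  }
  nd <- function(a, bb) {
    den <- a + bb
    out <- (a - bb) / den
    out[den == 0] <- NA_real_
    out
  }
  ndvi <- nd(b$nir, b$red)
  gndvi <- nd(b$nir, b$green)
  bndvi <- nd(b$nir, b$blue)
  disc <- (2 * b$nir + 1)^2 - 8 * (b$nir - b$red)
  msavi <- (2 * b$nir + 1 - sqrt(pmax(disc, 0))) / 2
  msavi <- clamp(msavi, -1, 1)
  acq$bands <- list(blue = b$blue, green = b$green, red = b$red, nir = b$nir,
                    ndvi = ndvi, gndvi = gndvi, bndvi = bndvi, msavi = msavi,
                    vv = b$vv, vh = b$vh, vvvh_ratio = b$vv - b$vh)
  degenerate <- is.na(ndvi) | is.na(gndvi) | is.na(bndvi)
  acq$valid <- acq$valid & !degenerate
  acq
}

#' Run the full preprocessing stage
#'
#' Scene-level cloud filtering, per-pixel cloud masking, speckle smoothing,
#' sensor pairing and index computation, in that order, producing the fused
#' 11-band annual series all feature extraction consumes.
#'
#' @param optical_series list of [optical_acquisition()]s.
#' @param radar_series list of [radar_acquisition()]s.
#' @param config a [preprocess_config()].
#' @param pixel_size pixel edge length in metres.
#' @return a [fused_series()]; attributes `"pairing"` and `"dropped_doys"`
#'   record the pairing table and the cloud-filtered dates.
#' @export
preprocess_series <- function(optical_series, radar_series,
                              config = preprocess_config(), pixel_size = 10) {
  optical_series <- filter_scene_cloud_fraction(
    optical_series, config$scene_cloud_max, config$pixel_cloud_prob_threshold)
  dropped <- attr(optical_series, "dropped_doys")
  optical_series <- lapply(optical_series, mask_clouds,
                           threshold = config$pixel_cloud_prob_threshold)
  radar_series <- lapply(radar_series, speckle_focal_mean,
                         radius_m = config$speckle_radius_m,
                         pixel_size = pixel_size)
  fused <- pair_sensors(optical_series, radar_series,
                        window_days = config$pairing_window_days,
                        pixel_size = pixel_size)
  pairing <- attr(fused, "pairing")
  fused$acquisitions <- lapply(fused$acquisitions, compute_indices)
  attr(fused, "pairing") <- pairing
  attr(fused, "dropped_doys") <- dropped
  fused
}
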