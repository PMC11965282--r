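mk_optical <- function(doy, cloud_frac, nr = 8, nc = 8) {
  cp <- matrix(0, nr, nc)
  n_cloud <- round(cloud_frac * nr * nc)
  if (n_cloud > 0) cp[seq_len(n_cloud)] <- 90
  optical_acquisition(doy, matrix(0.1, nr, nc), matrix(0.2, nr, nc),
                      matrix(0.2, nr, nc), matrix(0.5, nr, nc), cp)
}

test_that("scene-level cloud filter keeps exactly the scenes at or below the limit", {
  clear <- mk_optical(100, 0)
  clouded <- mk_optical(150, 1)
  kept <- filter_scene_cloud_fraction(list(clear, clouded), max_frac = 0.6)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$doy, 100L)
  expect_equal(attr(kept, "dropped_doys"), 150L)

  all_clear <- lapply(c(50L, 120L, 200L), mk_optical, cloud_frac = 0)
  expect_length(filter_scene_cloud_fraction(all_clear, 0.6), 3)

  expect_error(filter_scene_cloud_fraction(list(clouded), 0.6),
               class = "plasticmapr_empty_series_error")
})

test_that("cloud filter agrees with a brute-force per-scene pixel count", {
  set.seed(7)
  series <- lapply(1:12, function(i) {
    a <- mk_optical(i * 25, 0, nr = 16, nc = 16)
    a$cloud_prob <- matrix(runif(256, 0, 100), 16, 16)
    a
  })
  kept <- filter_scene_cloud_fraction(series, max_frac = 0.6,
                                      pixel_threshold = 40)
  fracs <- vapply(series, function(a) sum(a$cloud_prob >= 40) / 256, numeric(1))
  expect_equal(vapply(kept, `[[`, integer(1), "doy"),
               vapply(series[fracs <= 0.6], `[[`, integer(1), "doy"))
})

test_that("per-pixel cloud masking clears exactly the pixels at or above the threshold", {
  a <- mk_optical(100, 0, nr = 16, nc = 16)
  expect_identical(mask_clouds(a, 40)$valid, a$valid)  # all clear
  a$cloud_prob <- matrix(100, 16, 16)
  expect_false(any(mask_clouds(a, 40)$valid))
  set.seed(1)
  a$cloud_prob <- matrix(runif(256, 0, 100), 16, 16)
  m <- mask_clouds(a, 40)
  expect_equal(sum(!m$valid), sum(a$cloud_prob >= 40))
})

test_that("the 50 m focal disc on a 10 m grid has 81 members and averages exactly", {
  # constant raster: mean of constants is the constant
  const <- matrix(3.5, 20, 20)
  acq <- radar_acquisition(10, const, const)
  sm <- speckle_focal_mean(acq, radius_m = 50, pixel_size = 10)
  expect_equal(sm$vh, const, tolerance = 1e-12)

  # impulse response: centre value 1/81
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  out <- focal_disc_mean(imp, 5)
  expect_equal(out[11, 11], 1 / 81, tolerance = 1e-12)
  # disc membership: pixels at offsets with dr^2+dc^2 <= 25 see the impulse
  got <- which(out > 0, arr.ind = TRUE)
  d2 <- (got[, 1] - 11)^2 + (got[, 2] - 11)^2
  expect_true(all(d2 <= 25))
  expect_equal(nrow(got), 81)
})

test_that("focal disc mean equals the naive per-pixel oracle, edges included", {
  set.seed(21)
  m <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(focal_disc_mean(m, 5), naive_disc_mean(m, 5),
               tolerance = 1e-10)
  # with missing values excluded from numerator and denominator
  m[sample(length(m), 100)] <- NA
  expect_equal(focal_disc_mean(m, 5), naive_disc_mean(m, 5),
               tolerance = 1e-10)
})

test_that("sensor pairing picks the closest radar date within the window", {
  mk_radar <- function(doy) radar_acquisition(doy, matrix(-12, 8, 8),
                                              matrix(-18, 8, 8))
  opt <- list(mk_optical(100, 0))
  fused <- pair_sensors(opt, list(mk_radar(97), mk_radar(104)), window_days = 5)
  expect_equal(fused$acquisitions[[1]]$radar_doy, 97L)

  expect_error(pair_sensors(opt, list(mk_radar(106)), window_days = 5),
               class = "plasticmapr_empty_series_error")

  # equidistant radar dates break toward the earlier one
  fused <- pair_sensors(opt, list(mk_radar(98), mk_radar(102)), window_days = 5)
  expect_equal(fused$acquisitions[[1]]$radar_doy, 98L)
})

test_that("pairing matches an exhaustive argmin oracle on random dates", {
  set.seed(3)
  odoys <- sort(sample(1:366, 20))
  rdoys <- sort(sample(1:366, 20))
  opt <- lapply(odoys, mk_optical, cloud_frac = 0)
  rad <- lapply(rdoys, function(d) radar_acquisition(d, matrix(-12, 8, 8),
                                                     matrix(-18, 8, 8)))
  fused <- pair_sensors(opt, rad, window_days = 5)
  # oracle: for every optical date, scan all radar dates
  expected <- list()
  for (d in odoys) {
    gaps <- abs(rdoys - d)
    best <- min(gaps)
    if (best > 5) next
    cand <- rdoys[gaps == best]
    expected[[length(expected) + 1L]] <- c(optical = d, radar = min(cand))
  }
  got <- vapply(fused$acquisitions, function(a) c(a$doy, a$radar_doy),
                integer(2))
  expect_equal(unname(got[1, ]), vapply(expected, `[[`, numeric(1), "optical"))
  expect_equal(unname(got[2, ]), vapply(expected, `[[`, numeric(1), "radar"))
})

test_that("spectral indices match their printed formulas", {
  mk <- function(nir, red) {
    fused_acquisition(100, bands = list(
      blue = matrix(0.1, 2, 2), green = matrix(0.2, 2, 2),
      red = matrix(red, 2, 2), nir = matrix(nir, 2, 2),
      vv = matrix(-12, 2, 2), vh = matrix(-18, 2, 2)),
      valid = matrix(TRUE, 2, 2))
  }
  eq <- compute_indices(mk(0.4, 0.4))
  expect_equal(eq$bands$ndvi[1, 1], 0)
  expect_equal(eq$bands$msavi[1, 1], 0)  # sqrt((2n+1)^2) = 2n+1

  expect_equal(compute_indices(mk(0.8, 0.2))$bands$ndvi[1, 1], 0.6)
  expect_equal(compute_indices(mk(1, 0))$bands$msavi[1, 1], 1)  # (3-sqrt(1))/2

  expect_equal(eq$bands$vvvh_ratio[1, 1], -12 - (-18))
})

test_that("index computation is idempotent, mask-preserving, and masks degenerate pixels", {
  a <- fused_acquisition(50, bands = list(
    blue = matrix(c(0.1, 0), 2, 1), green = matrix(c(0.2, 0), 2, 1),
    red = matrix(c(0.3, 0), 2, 1), nir = matrix(c(0.5, 0), 2, 1),
    vv = matrix(-10, 2, 1), vh = matrix(-17, 2, 1)),
    valid = matrix(TRUE, 2, 1))
  once <- compute_indices(a)
  expect_false(once$valid[2, 1])  # nir + red = 0: degenerate pixel masked
  expect_true(once$valid[1, 1])
  twice <- compute_indices(once)
  expect_equal(twice$bands, once$bands)
  expect_equal(twice$valid, once$valid)
})

test_that("full preprocessing yields a chronologically sorted 11-band fused series", {
  sc <- generate_scene(scene_config(
    grid_size = c(24, 24), n_optical_dates = 8, n_radar_dates = 12,
    field_layout = list(field_spec(c(4, 12), c(4, 12), "PFF")),
    cloud_fraction_mean = 0.3, seed = 2))
  fused <- preprocess_series(sc$optical, sc$radar)
  doys <- vapply(fused$acquisitions, `[[`, integer(1), "doy")
  expect_equal(doys, sort(doys))
  for (a in fused$acquisitions) {
    expect_named(a$bands, fused_band_names())
  }
  pairing <- attr(fused, "pairing")
  expect_true(all(pairing$gap[!is.na(pairing$radar_doy)] <= 5))
})
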