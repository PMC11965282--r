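ndvi_only_series <- function(values) {
  # values: [r, c, t] NDVI array; other bands constant
  dims <- dim(values)
  bands <- lapply(fused_band_names(), function(b) array(0.3, dims))
  names(bands) <- fused_band_names()
  bands$ndvi <- values
  series_from_arrays(bands)
}

test_that("soil_cover follows its defining count contrast", {
  # constant series: every obs is >= mid, so (0 - n)/n = -1
  v <- array(0.4, c(1, 1, 6))
  expect_equal(soil_cover(ndvi_only_series(v))$soil_cover[1, 1], -1)

  # symmetric pair: one below, one at/above
  v2 <- array(c(0.1, 0.9), c(1, 1, 2))
  expect_equal(soil_cover(ndvi_only_series(v2))$soil_cover[1, 1], 0)

  # mid = 0.5; two below, one at/above: (2 - 1)/3
  v3 <- array(c(0.1, 0.2, 0.9), c(1, 1, 3))
  sc3 <- soil_cover(ndvi_only_series(v3))
  expect_equal(sc3$soil_cover[1, 1], 1 / 3)
  expect_equal(sc3$ndvi_mid[1, 1], 0.5)
})

test_that("soil_cover equals the naive oracle on random series and handles empty pixels", {
  set.seed(23)
  v <- array(runif(8 * 8 * 20, -0.1, 0.9), c(8, 8, 20))
  series <- ndvi_only_series(v)
  valid <- array(runif(8 * 8 * 20) > 0.2, c(8, 8, 20))
  for (t in 1:20) series$acquisitions[[t]]$valid <- valid[, , t]
  sc <- soil_cover(series)
  expect_equal(sc$soil_cover, naive_soil_cover(v, valid), tolerance = 1e-10)
  expect_true(all(sc$soil_cover >= -1 & sc$soil_cover <= 1, na.rm = TRUE))
  ok <- !is.na(sc$ndvi_mid)
  expect_true(all(sc$ndvi_min[ok] <= sc$ndvi_mid[ok] &
                    sc$ndvi_mid[ok] <= sc$ndvi_max[ok]))

  # a pixel with no valid observation is nodata
  for (t in 1:20) series$acquisitions[[t]]$valid[1, 1] <- FALSE
  expect_true(is.na(soil_cover(series)$soil_cover[1, 1]))
})

test_that("hexagonal grid tiles the extent with equal interior hexagons", {
  extent <- c(0, 1280, 0, 1920)
  grid <- build_hex_grid(extent, hex_area_ha = 4)
  interior <- grid$hexes[!grid$hexes$clipped, ]
  expect_gt(nrow(interior), 0)
  expect_true(all(abs(interior$area_ha - 4) / 4 < 1e-3))
  # tiling conserves total area
  extent_ha <- (extent[2] - extent[1]) * (extent[4] - extent[3]) / 1e4
  expect_equal(sum(grid$hexes$area_ha), extent_ha, tolerance = 1e-3)
})

test_that("every pixel centre is assigned to exactly one hexagon of the grid", {
  extent <- c(0, 320, 0, 480)
  grid <- build_hex_grid(extent, hex_area_ha = 1)
  cc <- plasticmapr:::pixel_centres(48, 32, 10)
  ids <- hex_assign(grid, as.vector(cc$x), as.vector(cc$y))
  expect_false(any(is.na(ids)))
  expect_true(all(ids %in% grid$hexes$hex_id))
  # assignment is a function: re-assignment is identical
  expect_identical(ids, hex_assign(grid, as.vector(cc$x), as.vector(cc$y)))
})

test_that("per-hexagon areas tally pixels exactly and conserve totals", {
  grid <- build_hex_grid(c(0, 200, 0, 200), hex_area_ha = 1)
  # 100 PMF pixels in the hexagon containing (55, 55)
  codes <- matrix(NA_integer_, 20, 20)
  target <- hex_assign(grid, 55, 55)
  cc <- plasticmapr:::pixel_centres(20, 20, 10)
  in_target <- matrix(hex_assign(grid, as.vector(cc$x), as.vector(cc$y)) ==
                        target, 20, 20)
  px <- which(in_target)[1:100]
  codes[px] <- 2L
  m <- class_map(codes, pixel_size = 10)
  areas <- hex_aggregate_area(m, grid)
  expect_equal(areas$area_pmf_ha[areas$hex_id == target], 1.0)
  expect_equal(sum(areas$area_pmf_ha), 1.0)

  # empty map: all areas zero
  empty <- class_map(matrix(NA_integer_, 20, 20), pixel_size = 10)
  expect_equal(sum(hex_aggregate_area(empty, grid)$area_classified_ha), 0)

  # random map: per-hexagon sums equal a brute-force tally and conserve totals
  set.seed(9)
  codes2 <- matrix(sample(c(1:3, NA), 400, TRUE), 20, 20)
  m2 <- class_map(codes2, pixel_size = 10)
  areas2 <- hex_aggregate_area(m2, grid)
  ids <- hex_assign(grid, as.vector(cc$x), as.vector(cc$y))
  for (h in unique(ids)) {
    expect_equal(areas2$area_pcv_ha[areas2$hex_id == h],
                 sum(codes2[matrix(ids == h, 20, 20)] == 3L, na.rm = TRUE) * 0.01)
  }
  expect_equal(sum(areas2$area_classified_ha),
               sum(!is.na(codes2)) * 0.01)
})

test_that("hexagon regression recovers exact fits and rejects degenerate input", {
  grid <- build_hex_grid(c(0, 400, 0, 400), hex_area_ha = 4)
  set.seed(31)
  sc_vals <- matrix(runif(1600, -1, 1), 40, 40)
  mk_layer <- function(m, cls) structure(
    list(fpd = m, n_classified = matrix(10L, 40, 40), pixel_size = 10),
    class = cls)
  soil <- structure(list(soil_cover = sc_vals, pixel_size = 10),
                    class = "soil_cover_layer")

  exact <- mk_layer(0.5 * sc_vals + 0.1, "fpd_layer")
  # an exact linear relation makes lm warn about the perfect fit; expected here
  reg <- suppressWarnings(hex_regression(exact, soil, grid))
  expect_true(all(abs(reg$r_squared[!is.na(reg$r_squared)] - 1) < 1e-9))

  # independence: R^2 near zero on a large sample
  grid1 <- build_hex_grid(c(0, 1000, 0, 1000), hex_area_ha = 100)
  sc_big <- matrix(runif(1e4, -1, 1), 100, 100)
  soil_big <- structure(list(soil_cover = sc_big, pixel_size = 10),
                        class = "soil_cover_layer")
  indep <- structure(list(fpd = matrix(runif(1e4), 100, 100),
                          n_classified = matrix(10L, 100, 100),
                          pixel_size = 10), class = "fpd_layer")
  reg2 <- hex_regression(indep, soil_big, grid1)
  expect_true(all(reg2$r_squared[!is.na(reg2$r_squared)] < 0.01))

  # constant regressor: undefined, not zero
  soil_const <- structure(list(soil_cover = matrix(0.2, 40, 40),
                               pixel_size = 10), class = "soil_cover_layer")
  reg3 <- suppressWarnings(hex_regression(exact, soil_const, grid))
  expect_true(all(is.na(reg3$r_squared)))
})

test_that("hotspot flagging applies its thresholds monotonically", {
  s <- tibble::tibble(hex_id = c("a", "b", "c"),
                      r_squared = c(0.6, 0.2, NA),
                      p_value = c(1e-6, 1e-6, NA))
  fl <- flag_hotspots(s, 0.3, 1e-4)
  expect_equal(fl$flagged, c(TRUE, FALSE, FALSE))
  # raising the threshold never flags more hexagons
  for (t in seq(0, 1, by = 0.1)) {
    lo <- sum(flag_hotspots(s, t, 1e-4)$flagged)
    hi <- sum(flag_hotspots(s, min(t + 0.1, 1), 1e-4)$flagged)
    expect_lte(hi, lo)
  }
})

test_that("masking flagged hexagons nulls plasticulture but keeps PFF", {
  grid <- build_hex_grid(c(0, 200, 0, 200), hex_area_ha = 1)
  codes <- matrix(rep(1:3, length.out = 400), 20, 20)
  m <- class_map(codes, pixel_size = 10)
  cc <- plasticmapr:::pixel_centres(20, 20, 10)
  target <- hex_assign(grid, 100, 100)
  s <- tibble::tibble(hex_id = target, r_squared = 0.9, p_value = 1e-9)
  masked <- mask_flagged(m, grid, flag_hotspots(s))
  in_target <- matrix(hex_assign(grid, as.vector(cc$x), as.vector(cc$y)) ==
                        target, 20, 20)
  expect_true(all(is.na(masked$codes[in_target & codes != 1L])))
  expect_equal(masked$codes[in_target & codes == 1L],
               codes[in_target & codes == 1L])
  expect_equal(masked$codes[!in_target], codes[!in_target])
})
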