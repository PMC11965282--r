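const_series <- function(value, nT = 8, nr = 4, nc = 4) {
  bands <- lapply(fused_band_names(), function(b) array(value, c(nr, nc, nT)))
  names(bands) <- fused_band_names()
  series_from_arrays(bands)
}

test_that("aggregating a constant series gives the constant and zero spread", {
  agg <- aggregate_annual(const_series(0.42), min_obs = 5)
  expect_length(agg$bands, 121)
  for (s in c("p10", "p25", "p75", "p90", "mean", "max", "min")) {
    expect_equal(agg$bands[[paste0("ndvi_", s)]][1, 1], 0.42)
  }
  for (s in c("iqr", "stddev", "p90p10", "maxmin")) {
    expect_equal(agg$bands[[paste0("vh_", s)]][2, 3], 0)
  }
})

test_that("percentiles use linear interpolation between order statistics", {
  # series 0..9 at one pixel
  bands <- lapply(fused_band_names(), function(b) {
    a <- array(0, c(1, 1, 10)); a[1, 1, ] <- 0:9; a
  })
  names(bands) <- fused_band_names()
  agg <- aggregate_annual(series_from_arrays(bands), min_obs = 5)
  expect_equal(agg$bands$ndvi_p10[1, 1], 0.9)
  expect_equal(agg$bands$ndvi_p90[1, 1], 8.1)
  expect_equal(agg$bands$ndvi_iqr[1, 1], 4.5)
  expect_equal(agg$bands$ndvi_maxmin[1, 1], 9)
})

test_that("every aggregation statistic matches the naive per-pixel oracle", {
  series <- random_fused_series(nr = 8, nc = 8, nT = 30, seed = 13)
  agg <- aggregate_annual(series, min_obs = 5)
  valid <- simplify2array(lapply(series$acquisitions, `[[`, "valid"))
  for (bn in c("ndvi", "vh", "blue")) {
    vals <- simplify2array(lapply(series$acquisitions,
                                  function(a) a$bands[[bn]]))
    oracle <- naive_aggregate(vals, valid, min_obs = 5)
    for (s in aggregation_stats()) {
      expect_equal(agg$bands[[paste(bn, s, sep = "_")]], oracle[[s]],
                   tolerance = 1e-10, info = paste(bn, s))
    }
  }
})

test_that("the order-statistic chain holds on every valid pixel", {
  agg <- aggregate_annual(random_fused_series(nr = 10, nc = 10, seed = 31))
  for (bn in c("ndvi", "vv")) {
    b <- function(s) agg$bands[[paste(bn, s, sep = "_")]]
    ok <- !is.na(b("max"))
    expect_true(all(b("max")[ok] >= b("p90")[ok] - 1e-12))
    expect_true(all(b("p90")[ok] >= b("p75")[ok] - 1e-12))
    expect_true(all(b("p75")[ok] >= b("p25")[ok] - 1e-12))
    expect_true(all(b("p25")[ok] >= b("p10")[ok] - 1e-12))
    expect_true(all(b("p10")[ok] >= b("min")[ok] - 1e-12))
    expect_true(all(b("iqr")[ok] >= 0) && all(b("maxmin")[ok] >= 0))
  }
})

test_that("pixels below the minimum observation count become nodata", {
  series <- random_fused_series(nr = 6, nc = 6, nT = 8, seed = 5,
                                p_invalid = 0)
  # silence one pixel on all but 3 dates
  for (t in 4:8) series$acquisitions[[t]]$valid[2, 2] <- FALSE
  agg <- aggregate_annual(series, min_obs = 5)
  expect_true(is.na(agg$bands$ndvi_mean[2, 2]))
  expect_equal(agg$n_obs[2, 2], 3)
  expect_false(is.na(agg$bands$ndvi_mean[1, 1]))
})

test_that("sample extraction returns one row per valid in-polygon pixel centre", {
  img <- list(bands = list(x1 = matrix(runif(400), 20, 20),
                           x2 = matrix(runif(400), 20, 20)),
              valid = matrix(TRUE, 20, 20))
  fields <- tibble::tibble(id = "P", row_min = 3, row_max = 7,
                           col_min = 4, col_max = 8, lab = "PMF")
  s <- extract_samples(img, fields, label_field = "lab")
  expect_equal(nrow(s), 25)
  expect_setequal(s$label, "PMF")

  img$valid[3:4, 4:8] <- FALSE  # 10 masked pixels
  s2 <- extract_samples(img, fields, label_field = "lab")
  expect_equal(nrow(s2), 15)

  # brute-force centre-in-rectangle oracle with partial overlap
  fields_off <- tibble::tibble(id = "Q", row_min = 18, row_max = 25,
                               col_min = -2, col_max = 5, lab = "PFF")
  s3 <- extract_samples(img, fields_off, label_field = "lab")
  oracle <- 0
  for (r in 1:20) for (cc in 1:20) {
    if (r >= 18 && r <= 25 && cc >= -2 && cc <= 5 && img$valid[r, cc]) {
      oracle <- oracle + 1
    }
  }
  expect_equal(nrow(s3), oracle)
  expect_warning(
    extract_samples(img, tibble::tibble(id = "Z", row_min = 50, row_max = 60,
                                        col_min = 50, col_max = 60,
                                        lab = "PFF"),
                    label_field = "lab"),
    "outside")
})

test_that("the binary forest separates well-separated classes and is seed-deterministic", {
  samples <- separable_binary_samples(seed = 0)
  clf <- train_binary_classifier(samples, seed = 1)
  X <- as.data.frame(dplyr::select(samples, -label))
  pred <- predict(clf, X, num.threads = 1)$predictions
  expect_equal(as.integer(as.character(pred)), samples$label)

  clf2 <- train_binary_classifier(samples, seed = 1)
  expect_equal(predict(clf2, X, num.threads = 1)$predictions, pred)

  # duplicating every row leaves majority predictions unchanged
  clf3 <- train_binary_classifier(dplyr::bind_rows(samples, samples), seed = 1)
  expect_equal(predict(clf3, X, num.threads = 1)$predictions, pred)

  expect_error(train_binary_classifier(dplyr::filter(samples, label == 0),
                                       seed = 1),
               class = "plasticmapr_config_error")
})

test_that("FPD is the mean of per-date binary outcomes over valid dates only", {
  samples <- separable_binary_samples(seed = 0)
  clf <- train_binary_classifier(samples, seed = 2)
  mu0 <- colMeans(dplyr::filter(samples, label == 0)[fused_band_names()])
  mu1 <- colMeans(dplyr::filter(samples, label == 1)[fused_band_names()])
  # 2x1 grid, 4 dates: pixel 1 follows pattern 1,0,1,1; pixel 2 always 0
  pattern <- c(1, 0, 1, 1)
  bands <- lapply(seq_along(fused_band_names()), function(i) {
    a <- array(0, c(2, 1, 4))
    for (t in 1:4) {
      a[1, 1, t] <- if (pattern[t] == 1) mu1[i] else mu0[i]
      a[2, 1, t] <- mu0[i]
    }
    a
  })
  names(bands) <- fused_band_names()
  series <- series_from_arrays(bands)
  fpd <- compute_fpd(series, clf)
  expect_equal(fpd$fpd[1, 1], 0.75)
  expect_equal(fpd$fpd[2, 1], 0)
  expect_equal(fpd$n_classified[1, 1], 4L)

  # masked dates drop out of numerator and denominator
  series$acquisitions[[2]]$valid[1, 1] <- FALSE
  fpd2 <- compute_fpd(series, clf)
  expect_equal(fpd2$fpd[1, 1], 1)  # outcomes 1,1,1 over 3 valid dates
  expect_equal(fpd2$n_classified[1, 1], 3L)

  # brute-force loop-over-dates oracle
  outcomes <- vapply(series$acquisitions,
                     function(a) predict_binary(clf, a)[1, 1], integer(1))
  expect_equal(fpd2$fpd[1, 1], mean(outcomes, na.rm = TRUE))
})

test_that("the stacked feature set carries exactly 122 bands", {
  run <- cached_small_run()
  expect_length(run$agg$bands, 121)
  expect_length(run$stack$bands, 122)
  expect_true("fpd" %in% names(run$stack$bands))
})
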