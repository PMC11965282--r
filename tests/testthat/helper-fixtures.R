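# Shared fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

# The default end-to-end run (the standard synthetic study conditions).
cached_default_run <- function() {
  if (is.null(.fixture_env$default_run)) {
    .fixture_env$default_run <- run_pipeline(default_pipeline_config(seed = 42))
  }
  .fixture_env$default_run
}

# A small, fast pipeline configuration for smoke and determinism tests.
small_pipeline_config <- function(seed = 7, out_dir = NULL) {
  pipeline_config(
    scene = scene_config(
      grid_size = c(80, 64),
      n_optical_dates = 14, n_radar_dates = 20,
      field_layout = default_field_layout(n_per_class = 4, n_clean = 4,
                                          n_confounder = 4, layout_cols = 4,
                                          seed = seed),
      seed = seed
    ),
    fpd_rf = rf_config(100, 5, seed = seed + 1L),
    final_rf = rf_config(100, 10, seed = seed + 2L),
    hex_area_ha = 4,
    out_dir = out_dir, seed = seed
  )
}

cached_small_run <- function() {
  if (is.null(.fixture_env$small_run)) {
    .fixture_env$small_run <- run_pipeline(small_pipeline_config())
  }
  .fixture_env$small_run
}

# Rectangular mask of the confounder / clean-control regions of a scene.
region_mask <- function(fields, which_rows, dim_rc) {
  m <- matrix(FALSE, dim_rc[1], dim_rc[2])
  for (i in which_rows) {
    m[fields$row_min[i]:fields$row_max[i],
      fields$col_min[i]:fields$col_max[i]] <- TRUE
  }
  m
}

# Build a tiny fused series directly from band arrays (values[r, c, t] per
# band), bypassing the simulator, for oracle tests.
series_from_arrays <- function(bands, valid = NULL, doys = NULL,
                               pixel_size = 10) {
  dims <- dim(bands[[1]])
  nT <- dims[3]
  if (is.null(doys)) doys <- seq(10, 350, length.out = nT)
  if (is.null(valid)) valid <- array(TRUE, dims)
  acqs <- lapply(seq_len(nT), function(t) {
    fused_acquisition(
      doy = round(doys[t]),
      bands = lapply(bands, function(a) matrix(a[, , t], dims[1], dims[2])),
      valid = matrix(valid[, , t], dims[1], dims[2])
    )
  })
  fused_series(acqs, pixel_size = pixel_size)
}

# Random 11-band fused series used by the formula-oracle tests.
random_fused_series <- function(nr = 32, nc = 32, nT = 30, seed = 99,
                                p_invalid = 0.1) {
  set.seed(seed)
  mk <- function(lo, hi) array(runif(nr * nc * nT, lo, hi), c(nr, nc, nT))
  blue <- mk(0, 1); green <- mk(0, 1); red <- mk(0, 1); nir <- mk(0, 1)
  vv <- mk(-25, -5); vh <- mk(-30, -10)
  valid <- array(runif(nr * nc * nT) > p_invalid, c(nr, nc, nT))
  bands <- list(
    blue = blue, green = green, red = red, nir = nir,
    ndvi = (nir - red) / (nir + red),
    gndvi = (nir - green) / (nir + green),
    bndvi = (nir - blue) / (nir + blue),
    msavi = (2 * nir + 1 - sqrt((2 * nir + 1)^2 - 8 * (nir - red))) / 2,
    vv = vv, vh = vh, vvvh_ratio = vv - vh
  )
  series_from_arrays(bands, valid = valid,
                     doys = sort(sample(1:366, nT)))
}

# Naive per-pixel disc mean: the independent oracle for the focal filter.
naive_disc_mean <- function(mat, radius_px) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(NA_real_, nr, nc)
  r <- floor(radius_px)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (di in -r:r) {
        for (dj in -r:r) {
          if (di^2 + dj^2 > radius_px^2) next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
          v <- mat[ii, jj]
          if (!is.na(v)) vals <- c(vals, v)
        }
      }
      if (length(vals)) out[i, j] <- mean(vals)
    }
  }
  out
}

# Naive per-pixel aggregation statistics: the oracle for aggregate_annual.
naive_aggregate <- function(values, valid, min_obs = 5) {
  # values, valid: [r, c, t]
  nr <- dim(values)[1]; nc <- dim(values)[2]
  stats <- aggregation_stats()
  out <- lapply(stats, function(s) matrix(NA_real_, nr, nc))
  names(out) <- stats
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      x <- values[i, j, ][valid[i, j, ]]
      x <- x[!is.na(x)]
      if (length(x) < min_obs) next
      q <- unname(quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7))
      out$p10[i, j] <- q[1]; out$p25[i, j] <- q[2]
      out$p75[i, j] <- q[3]; out$p90[i, j] <- q[4]
      out$mean[i, j] <- mean(x)
      out$max[i, j] <- max(x); out$min[i, j] <- min(x)
      out$iqr[i, j] <- q[3] - q[2]
      out$stddev[i, j] <- sqrt(mean((x - mean(x))^2))
      out$p90p10[i, j] <- q[4] - q[1]
      out$maxmin[i, j] <- max(x) - min(x)
    }
  }
  out
}

# Naive per-pixel soil_cover: the oracle for the bare-soil index.
naive_soil_cover <- function(ndvi, valid) {
  nr <- dim(ndvi)[1]; nc <- dim(ndvi)[2]
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      x <- ndvi[i, j, ][valid[i, j, ]]
      x <- x[!is.na(x)]
      n <- length(x)
      if (!n) next
      mid <- (max(x) + min(x)) / 2
      out[i, j] <- (sum(x - mid < 0) - sum(x - mid >= 0)) / n
    }
  }
  out
}

# Well-separated two-class samples on the 11 fused bands.
separable_binary_samples <- function(n_per_class = 60, seed = 0) {
  set.seed(seed)
  mk <- function(mu, label) {
    tibble::as_tibble(stats::setNames(
      lapply(seq_along(fused_band_names()),
             function(i) rnorm(n_per_class, mu[i], 0.02)),
      fused_band_names())) |>
      dplyr::mutate(label = label)
  }
  mu0 <- c(0.1, 0.15, 0.2, 0.3, 0.2, 0.2, 0.2, 0.2, -12, -19, 7)
  mu1 <- c(0.3, 0.35, 0.1, 0.6, 0.7, 0.6, 0.6, 0.5, -18, -25, 7)
  dplyr::bind_rows(mk(mu0, 0L), mk(mu1, 1L))
}
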