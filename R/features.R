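#' Names of the 11 annual aggregation statistics
#'
#' 10th/25th/75th/90th percentiles, mean, maximum, minimum, interquartile
#' range, standard deviation (population form), the 90th-10th percentile
#' difference and the max-min range.
#'
#' @return character vector of the 11 statistic suffixes.
#' @export
aggregation_stats <- function() {
  c("p10", "p25", "p75", "p90", "mean", "max", "min", "iqr", "stddev",
    "p90p10", "maxmin")
}

# Row-wise type-7 (linear interpolation) quantile on a row-sorted matrix S
# with per-row valid counts n.
row_quantile7 <- function(S, n, p) {
  i <- seq_len(nrow(S))
  h <- (n - 1) * p
  lo <- floor(h)
  frac <- h - lo
  v1 <- S[cbind(i, pmax(lo + 1, 1))]
  v2 <- S[cbind(i, pmin(lo + 2, pmax(n, 1)))]
  out <- v1 + frac * (v2 - v1)
  out[n == 0] <- NA_real_
  out
}

#' Annual aggregated features
#'
#' Reduces a fused annual series to 121 per-pixel features: the 11
#' aggregation statistics of [aggregation_stats()] applied to each of the 11
#' bands, computed over valid (cloud-free, paired) observations only.
#' Percentiles use linear interpolation between order statistics; the
#' standard deviation is the population form (divide by n). Pixels with fewer
#' than `min_obs` valid observations are set to nodata.
#'
#' @param series a [fused_series()] whose acquisitions carry the 11 bands.
#' @param min_obs minimum valid observations per pixel (default 5).
#' @return an object of class `aggregated_features`: `bands` is a named list
#'   of 121 matrices (`<band>_<stat>`), `n_obs` the per-pixel observation
#'   count.
#' @export
aggregate_annual <- function(series, min_obs = 5) {
  acqs <- series$acquisitions
  if (!length(acqs)) {
    abort("empty series", class = "plasticmapr_empty_series_error")
  }
  band_names <- fused_band_names()
  if (!all(band_names %in% names(acqs[[1]]$bands))) {
    abort("series acquisitions must carry all 11 bands (run compute_indices)",
          class = "plasticmapr_config_error")
  }
  nr <- nrow(acqs[[1]]$valid); nc <- ncol(acqs[[1]]$valid)
  npix <- nr * nc
  valid <- matrix(vapply(acqs, function(a) as.vector(a$valid), logical(npix)),
                  npix, length(acqs))
  out <- vector("list", 121L)
  nm <- character(121L)
  pos <- 0L
  n_obs_global <- NULL
  for (bn in band_names) {
    V <- matrix(vapply(acqs, function(a) as.vector(a$bands[[bn]]),
                       numeric(npix)), npix, length(acqs))
    V[!valid | is.na(V)] <- NA_real_
    n <- rowSums(!is.na(V))
    if (is.null(n_obs_global)) n_obs_global <- n
    S <- t(apply(V, 1, sort, na.last = TRUE))
    i <- seq_len(npix)
    n1 <- pmax(n, 1)
    p10 <- row_quantile7(S, n, 0.10)
    p25 <- row_quantile7(S, n, 0.25)
    p75 <- row_quantile7(S, n, 0.75)
    p90 <- row_quantile7(S, n, 0.90)
    mn <- rowMeans(V, na.rm = TRUE)
    mx <- S[cbind(i, n1)]
    mi <- S[, 1]
    dev <- V - mn
    sdev <- sqrt(rowSums(dev * dev, na.rm = TRUE) / n1)
    stats <- list(p10 = p10, p25 = p25, p75 = p75, p90 = p90, mean = mn,
                  max = mx, min = mi, iqr = p75 - p25, stddev = sdev,
                  p90p10 = p90 - p10, maxmin = mx - mi)
    low <- n < min_obs
    for (sn in aggregation_stats()) {
      v <- stats[[sn]]
      v[low] <- NA_real_
      pos <- pos + 1L
      out[[pos]] <- matrix(v, nr, nc)
      nm[pos] <- paste(bn, sn, sep = "_")
    }
  }
  names(out) <- nm
  structure(list(bands = out, n_obs = matrix(n_obs_global, nr, nc),
                 pixel_size = series$pixel_size, min_obs = min_obs),
            class = "aggregated_features")
}

#' @export
print.aggregated_features <- function(x, ...) {
  cat(sprintf("<aggregated_features> %d bands, %dx%d, median n_obs %d\n",
              length(x$bands), nrow(x$n_obs), ncol(x$n_obs),
              as.integer(median(x$n_obs))))
  invisible(x)
}

#' Extract labelled pixel samples from an image
#'
#' One row per unmasked pixel whose centre falls inside a field rectangle,
#' with the field's label attached — the sampling step that turns labelled
#' polygons into a training matrix.
#'
#' @param image an object with named band matrices in `$bands` and a logical
#'   `$valid` matrix (a [fused_acquisition()] or a feature stack).
#' @param fields tibble with `row_min`, `row_max`, `col_min`, `col_max`, an
#'   `id` column and the label column.
#' @param label_field name of the label column in `fields`.
#' @param max_per_field optional cap on pixels sampled per field (applied
#'   with the seeded RNG for reproducibility).
#' @param seed optional seed used when capping.
#' @return tibble with `field_id`, `row`, `col`, one column per band, and
#'   `label`. Fields contributing zero rows trigger a warning.
#' @export
extract_samples <- function(image, fields, label_field = "truth_class",
                            max_per_field = NULL, seed = NULL) {
  if (!is.null(seed)) local_rng(seed)
  nrb <- nrow(image$valid); ncb <- ncol(image$valid)
  rows_list <- vector("list", nrow(fields))
  for (k in seq_len(nrow(fields))) {
    f <- fields[k, ]
    r <- max(1, f$row_min):min(nrb, f$row_max)
    c <- max(1, f$col_min):min(ncb, f$col_max)
    if (f$row_min > nrb || f$col_min > ncb || f$row_max < 1 || f$col_max < 1) {
      warn(sprintf("field %s lies outside the grid: zero rows", f$id))
      next
    }
    idx <- expand.grid(row = r, col = c)
    ok <- image$valid[cbind(idx$row, idx$col)]
    idx <- idx[ok, , drop = FALSE]
    if (!nrow(idx)) {
      warn(sprintf("field %s fully masked: zero rows", f$id))
      next
    }
    if (!is.null(max_per_field) && nrow(idx) > max_per_field) {
      idx <- idx[sample.int(nrow(idx), max_per_field), , drop = FALSE]
    }
    vals <- lapply(image$bands, function(m) m[cbind(idx$row, idx$col)])
    rows_list[[k]] <- tibble::tibble(
      field_id = f$id, row = idx$row, col = idx$col,
      !!!vals, label = f[[label_field]]
    )
  }
  dplyr::bind_rows(rows_list)
}

#' Train the single-date binary plastic classifier
#'
#' Random forest separating plastic-covered surfaces (label 1: PMF or PCV)
#' from plastic-free farmland (label 0) on the 11 fused bands of designated
#' cloud-free reference date(s). Defaults: 300 trees, 5 variables per split.
#'
#' @param samples tibble from [extract_samples()] whose `label` is 0/1 (or a
#'   two-level factor/character).
#' @param n_trees number of trees.
#' @param vars_per_split variables tried at each split (mtry).
#' @param seed integer seed; required for reproducibility.
#' @return a fitted `ranger` classification forest.
#' @export
train_binary_classifier <- function(samples, n_trees = 300, vars_per_split = 5,
                                    seed) {
  feat <- dplyr::select(samples, dplyr::any_of(fused_band_names()))
  y <- factor(samples$label)
  if (nlevels(y) < 2) {
    abort("training samples contain a single class",
          class = "plasticmapr_config_error")
  }
  ranger::ranger(x = as.data.frame(feat), y = y,
                 num.trees = n_trees, mtry = vars_per_split,
                 seed = seed, num.threads = 1)
}

#' Per-pixel binary prediction on one fused acquisition
#' @param classifier forest from [train_binary_classifier()].
#' @param acq a [fused_acquisition()] with the 11 bands.
#' @return integer matrix of 0/1 predictions with `NA` on invalid pixels.
#' @export
predict_binary <- function(classifier, acq) {
  nr <- nrow(acq$valid); nc <- ncol(acq$valid)
  out <- matrix(NA_integer_, nr, nc)
  idx <- which(acq$valid)
  if (!length(idx)) return(out)
  X <- as.data.frame(lapply(acq$bands[fused_band_names()], `[`, idx))
  pred <- predict(classifier, X, num.threads = 1, seed = 1L)$predictions
  out[idx] <- as.integer(as.character(pred))
  out
}

#' Frequency of plastic detection (FPD)
#'
#' Classifies every valid observation of the series with the single-date
#' binary classifier and reduces the resulting time series of binary maps to
#' its pixel-wise mean: the fraction of acquisitions on which the pixel was
#' detected as plastic-covered. Masked dates are excluded from both
#' numerator and denominator; pixels never classified are nodata.
#'
#' @param series a [fused_series()] with 11-band acquisitions.
#' @param classifier forest from [train_binary_classifier()].
#' @return an object of class `fpd_layer` with matrices `fpd` (in
#'   \eqn{[0, 1]}) and `n_classified`.
#' @export
compute_fpd <- function(series, classifier) {
  acqs <- series$acquisitions
  nr <- nrow(acqs[[1]]$valid); nc <- ncol(acqs[[1]]$valid)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (a in acqs) {
    b <- predict_binary(classifier, a)
    ok <- !is.na(b)
    acc[ok] <- acc[ok] + b[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  fpd <- acc / cnt
  fpd[cnt == 0] <- NA_real_
  structure(list(fpd = fpd, n_classified = cnt,
                 pixel_size = series$pixel_size),
            class = "fpd_layer")
}

#' Stack the aggregated features and the FPD into the classifier input
#'
#' @param agg an [aggregate_annual()] result (121 bands).
#' @param fpd a [compute_fpd()] result.
#' @return an object of class `feature_stack` with 122 named band matrices
#'   and a validity mask (pixels valid in both branches).
#' @export
build_feature_stack <- function(agg, fpd) {
  bands <- c(agg$bands, list(fpd = fpd$fpd))
  if (length(bands) != 122L) {
    abort(sprintf("feature stack must have 122 bands, got %d", length(bands)),
          class = "plasticmapr_dimension_error")
  }
  valid <- !is.na(agg$bands[[1]]) & !is.na(fpd$fpd)
  structure(list(bands = bands, valid = valid, pixel_size = agg$pixel_size),
            class = "feature_stack")
}
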