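#' Random-forest configuration
#'
#' @param n_trees number of trees (default 300).
#' @param vars_per_split variables tried per split (default 10 for the final
#'   three-class model; the single-date binary model uses 5).
#' @param seed integer seed.
#' @return an object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 300, vars_per_split = 10, seed = 1) {
  if (n_trees < 1 || vars_per_split < 1) {
    abort("`n_trees` and `vars_per_split` must be >= 1",
          class = "plasticmapr_config_error")
  }
  structure(list(n_trees = as.integer(n_trees),
                 vars_per_split = as.integer(vars_per_split),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Train the final three-class classifier
#'
#' Random forest over the 122 stacked features (121 annual aggregated
#' features + FPD) predicting `{PFF, PMF, PCV}`. Defaults: 300 trees, 10
#' variables per split, Gini split criterion, impurity importance.
#'
#' @param samples tibble of training rows with the feature columns and a
#'   `label` column (at least two classes).
#' @param rf an [rf_config()].
#' @param check_features if `TRUE` (default) an input with a feature count
#'   other than 122 is rejected; disable for experiments.
#' @return a fitted `ranger` forest carrying impurity importances.
#' @export
train_final_classifier <- function(samples, rf = rf_config(),
                                   check_features = TRUE) {
  feat <- dplyr::select(samples,
                        -dplyr::any_of(c("label", "field_id", "row", "col")))
  if (check_features && ncol(feat) != 122L) {
    abort(sprintf("expected 122 features, got %d (set check_features = FALSE to override)",
                  ncol(feat)),
          class = "plasticmapr_dimension_error")
  }
  y <- factor(samples$label, levels = intersect(plastic_classes(),
                                                unique(samples$label)))
  if (nlevels(y) < 2) {
    abort("training samples contain a single class",
          class = "plasticmapr_config_error")
  }
  ranger::ranger(x = as.data.frame(feat), y = y,
                 num.trees = rf$n_trees, mtry = rf$vars_per_split,
                 importance = "impurity", seed = rf$seed, num.threads = 1)
}

#' Predict the class map from a feature stack
#'
#' Applies the trained classifier to every pixel that is valid in the stack
#' and `TRUE` in `mask` (the cropland-mask analogue); everything else is
#' nodata. Band names must match the training features.
#'
#' @param stack a [build_feature_stack()] result.
#' @param classifier forest from [train_final_classifier()].
#' @param mask logical matrix restricting prediction (default: all pixels).
#' @return a [class_map()].
#' @export
predict_map <- function(stack, classifier, mask = NULL) {
  needed <- classifier$forest$independent.variable.names
  missing <- setdiff(needed, names(stack$bands))
  if (length(missing)) {
    abort(sprintf("stack is missing training bands: %s",
                  paste(missing, collapse = ", ")),
          class = "plasticmapr_dimension_error")
  }
  nr <- nrow(stack$valid); nc <- ncol(stack$valid)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  codes <- matrix(NA_integer_, nr, nc)
  idx <- which(stack$valid & mask)
  if (length(idx)) {
    X <- as.data.frame(lapply(stack$bands[needed], `[`, idx))
    pred <- predict(classifier, X, num.threads = 1, seed = 1L)$predictions
    codes[idx] <- match(as.character(pred), plastic_classes())
  }
  class_map(codes, pixel_size = stack$pixel_size)
}

# 4-connected component labelling of a logical matrix (iterative BFS).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      nb <- integer(0)
      if (r > 1L) nb <- c(nb, p - 1L)
      if (r < nr) nb <- c(nb, p + 1L)
      if (c > 1L) nb <- c(nb, p - nr)
      if (c < nc) nb <- c(nb, p + nr)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Post-processing configuration for the sieve
#'
#' @param mmu_ha minimum mapping unit in hectares (default 0.25): smaller
#'   4-connected plasticulture patches are removed.
#' @param connectivity pixel connectivity; only 4 is supported.
#' @param replacement `"nodata"` (conservative default) or
#'   `"majority_neighbor"` for removed components.
#' @return an object of class `postprocess_config`.
#' @export
postprocess_config <- function(mmu_ha = 0.25, connectivity = 4,
                               replacement = c("nodata", "majority_neighbor")) {
  replacement <- match.arg(replacement)
  if (mmu_ha <= 0) abort("`mmu_ha` must be positive", class = "plasticmapr_config_error")
  if (connectivity != 4) {
    abort("only 4-connectivity is supported", class = "plasticmapr_config_error")
  }
  structure(list(mmu_ha = mmu_ha, connectivity = 4L, replacement = replacement),
            class = "postprocess_config")
}

#' Sieve small plasticulture patches from a class map
#'
#' Minimum-mapping-unit filter: 4-connected components of either
#' plasticulture class (PMF, PCV) whose area falls below `cfg$mmu_ha` are
#' removed (0.25 ha = 25 pixels on a 10 m grid); PFF and nodata are left
#' untouched. Removed pixels become nodata, or take the modal class of the
#' pixels bordering the component under `"majority_neighbor"`. Idempotent.
#'
#' @param map a [class_map()].
#' @param cfg a [postprocess_config()].
#' @return the sieved [class_map()]; attribute `"n_removed"` counts removed
#'   components.
#' @export
sieve <- function(map, cfg = postprocess_config()) {
  codes <- map$codes
  px_area_ha <- map$pixel_size^2 / 1e4
  min_px <- ceiling(cfg$mmu_ha / px_area_ha)
  n_removed <- 0L
  for (cls in c("PMF", "PCV")) {
    code <- match(cls, map$levels)
    mask <- !is.na(map$codes) & map$codes == code
    if (!any(mask)) next
    labels <- label_components(mask)
    sizes <- tabulate(labels)
    drop <- which(sizes < min_px)
    n_removed <- n_removed + length(drop)
    for (lab in drop) {
      px <- which(labels == lab)
      if (cfg$replacement == "nodata") {
        codes[px] <- NA_integer_
      } else {
        codes[px] <- majority_neighbor(map$codes, labels, lab)
      }
    }
  }
  out <- class_map(codes, levels = map$levels, pixel_size = map$pixel_size)
  attr(out, "n_removed") <- n_removed
  out
}

# Modal class among pixels bordering the component `lab`; nodata if none.
majority_neighbor <- function(codes, labels, lab) {
  nr <- nrow(codes)
  px <- which(labels == lab)
  nb <- unique(c(px - 1L, px + 1L, px - nr, px + nr))
  nb <- nb[nb >= 1L & nb <= length(codes)]
  nb <- setdiff(nb, px)
  vals <- codes[nb]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_integer_)
  as.integer(names(which.max(table(vals))))
}

#' Gini feature importance of a trained forest
#'
#' Summed decrease in Gini impurity over all trees, per feature, with
#' normalised scores and ranks.
#'
#' @param classifier forest trained with impurity importance
#'   ([train_final_classifier()]).
#' @return tibble with `feature`, `importance`, `importance_norm` (sums to 1)
#'   and `rank`, sorted by decreasing importance; class `feature_importance`.
#' @export
feature_importance <- function(classifier) {
  imp <- ranger::importance(classifier)
  if (is.null(imp) || !length(imp)) {
    abort("classifier was not trained with impurity importance",
          class = "plasticmapr_config_error")
  }
  out <- tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(importance_norm = .data$importance / sum(.data$importance),
                  rank = dplyr::row_number())
  class(out) <- c("feature_importance", class(out))
  out
}
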