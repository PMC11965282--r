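#' Confusion matrix from a class map and validation points
#'
#' Samples the predicted class at the pixel containing each validation field
#' centroid and tallies reference vs prediction. Entry \eqn{(i, j)} counts
#' observations with reference class \eqn{i} and predicted class \eqn{j}.
#' Rows with an `"unknown"`/`NA` reference label are excluded; centroids
#' falling on nodata are excluded by default (and counted in the
#' `"n_nodata"` attribute).
#'
#' @param map a [class_map()].
#' @param validation tibble with `centroid_row`, `centroid_col` and the label
#'   column.
#' @param label_field name of the reference-label column (e.g. `label_2020`
#'   or `label_binary`).
#' @param classes class set defining the matrix dimensions; defaults to the
#'   union of map levels and observed labels.
#' @param include_nodata if `TRUE`, nodata predictions get their own column
#'   instead of being excluded.
#' @return a `K x K` integer matrix (class `conf_mat`) with reference classes
#'   on rows and predicted classes on columns.
#' @export
confusion_matrix <- function(map, validation, label_field = "label_2020",
                             classes = NULL, include_nodata = FALSE) {
  ref <- as.character(validation[[label_field]])
  keep <- !is.na(ref) & ref != "unknown"
  validation <- validation[keep, ]
  ref <- ref[keep]
  pred <- class_map_labels(map)[cbind(validation$centroid_row,
                                      validation$centroid_col)]
  n_nodata <- sum(is.na(pred))
  if (include_nodata) {
    pred[is.na(pred)] <- "nodata"
  } else {
    ok <- !is.na(pred)
    ref <- ref[ok]; pred <- pred[ok]
  }
  if (is.null(classes)) {
    classes <- union(intersect(map$levels, union(ref, pred)),
                     union(ref, pred))
  }
  m <- table(factor(ref, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(m), nrow(m), ncol(m),
              dimnames = list(reference = classes, predicted = classes))
  structure(m, class = c("conf_mat", class(m)), n_nodata = n_nodata)
}

#' Build a confusion matrix from printed counts
#'
#' Convenience constructor for externally tabulated matrices (reference
#' classes on rows, predicted classes on columns).
#'
#' @param counts numeric matrix or vector (filled by row).
#' @param classes class names.
#' @return a `conf_mat` matrix.
#' @export
as_conf_mat <- function(counts, classes) {
  k <- length(classes)
  m <- matrix(as.integer(counts), k, k, byrow = !is.matrix(counts))
  dimnames(m) <- list(reference = classes, predicted = classes)
  structure(m, class = c("conf_mat", class(m)))
}

#' Accuracy metrics of a confusion matrix
#'
#' Overall accuracy (trace over total), per-class user accuracy (correct over
#' predicted-as-class: the commission view) and producer accuracy (correct
#' over reference-class: the omission view). Zero denominators yield `NA`,
#' reported as undefined rather than 0.
#'
#' @param m a `conf_mat` (reference rows, predicted columns).
#' @return object of class `accuracy_report`: list with `overall` (fraction),
#'   `total` count, and `per_class` tibble of `class`, `user_accuracy`,
#'   `producer_accuracy` (fractions).
#' @export
accuracy_metrics <- function(m) {
  total <- sum(m)
  if (!total) abort("empty confusion matrix", class = "plasticmapr_config_error")
  diagv <- diag(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  pa <- ifelse(rs > 0, diagv / rs, NA_real_)
  ua <- ifelse(cs > 0, diagv / cs, NA_real_)
  structure(
    list(overall = sum(diagv) / total, total = total,
         per_class = tibble::tibble(class = rownames(m),
                                    user_accuracy = unname(ua),
                                    producer_accuracy = unname(pa)),
         matrix = m),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> n = %d, overall accuracy %.1f%%\n",
              x$total, round_half_up(100 * x$overall, 1)))
  df <- x$per_class
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-18s UA %5.1f%%  PA %5.1f%%\n", df$class[i],
                round_half_up(100 * df$user_accuracy[i], 1),
                round_half_up(100 * df$producer_accuracy[i], 1)))
  }
  invisible(x)
}

#' Collapse the plasticulture classes to a binary form
#'
#' Sums the PMF and PCV rows/columns of a confusion matrix into a single
#' `plastic-covered` class (total count invariant), or recodes a label
#' vector the same way. Idempotent on already-binary input.
#'
#' @param x a `conf_mat` or a character vector of labels.
#' @param plastic_classes classes merged into `plastic-covered`.
#' @return binary `conf_mat` or recoded labels.
#' @export
merge_to_binary <- function(x, plastic_classes = c("PMF", "PCV")) {
  if (is.matrix(x)) {
    present <- intersect(plastic_classes, rownames(x))
    if (length(present) < 2) return(x)
    keep <- setdiff(rownames(x), present)
    classes <- c(keep, "plastic-covered")
    out <- matrix(0L, length(classes), length(classes),
                  dimnames = list(reference = classes, predicted = classes))
    grp <- ifelse(rownames(x) %in% present, "plastic-covered", rownames(x))
    for (i in seq_len(nrow(x))) {
      for (j in seq_len(ncol(x))) {
        out[grp[i], grp[j]] <- out[grp[i], grp[j]] + x[i, j]
      }
    }
    structure(out, class = c("conf_mat", class(out)))
  } else {
    ifelse(x %in% plastic_classes, "plastic-covered", x)
  }
}

#' Accuracy as a function of minimum field size
#'
#' Recomputes the accuracy metrics over the validation subsets with
#' `area_ha >= t` for thresholds `t = 0, step_ha, 2 step_ha, ...` up to the
#' largest field area — the sweep that shows how much of the omission error
#' sits in fields below the minimum mapping unit.
#'
#' @param map a [class_map()].
#' @param validation tibble with `area_ha`, centroid columns and the label
#'   column.
#' @param step_ha threshold step in hectares (default 0.25).
#' @param label_field reference-label column.
#' @param max_ha largest threshold; defaults to the maximum field area.
#' @return long tibble: `threshold_ha`, `n_fields`, `overall_accuracy`,
#'   `class`, `user_accuracy`, `producer_accuracy`.
#' @export
field_size_sweep <- function(map, validation, step_ha = 0.25,
                             label_field = "label_2020", max_ha = NULL) {
  if (is.null(max_ha)) max_ha <- max(validation$area_ha)
  thresholds <- seq(0, max_ha, by = step_ha)
  purrr::map_dfr(thresholds, function(t) {
    sub <- validation[validation$area_ha >= t, ]
    if (!nrow(sub)) return(NULL)
    m <- confusion_matrix(map, sub, label_field = label_field)
    if (!sum(m)) return(NULL)
    rep <- accuracy_metrics(m)
    dplyr::mutate(rep$per_class, threshold_ha = t, n_fields = nrow(sub),
                  overall_accuracy = rep$overall, .before = 1)
  })
}
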