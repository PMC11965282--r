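#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a confusion matrix into long counts
#'
#' @param x a `conf_mat`.
#' @param ... unused.
#' @return tibble with `reference`, `predicted`, `n`.
#' @export
tidy.conf_mat <- function(x, ...) {
  tibble::tibble(
    reference = rep(rownames(x), times = ncol(x)),
    predicted = rep(colnames(x), each = nrow(x)),
    n = as.integer(x)
  )
}

#' Tidy an accuracy report into one row per class
#'
#' @param x an `accuracy_report`.
#' @param percent if `TRUE`, report percentages rounded half-up to 1 decimal
#'   (the conventional table format) instead of raw fractions.
#' @param ... unused.
#' @return tibble with `class`, `user_accuracy`, `producer_accuracy`.
#' @export
tidy.accuracy_report <- function(x, percent = FALSE, ...) {
  out <- x$per_class
  if (percent) {
    out <- dplyr::mutate(out, dplyr::across(
      c("user_accuracy", "producer_accuracy"),
      ~ round_half_up(100 * .x, 1)))
  }
  out
}

#' One-row summary of an accuracy report
#'
#' @param x an `accuracy_report`.
#' @param ... unused.
#' @return tibble with `overall_accuracy` (fraction) and `n` (total count).
#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall, n = x$total)
}

#' Tidy an FPD layer into a pixel tibble
#'
#' @param x an `fpd_layer`.
#' @param ... unused.
#' @return tibble with `row`, `col`, `fpd`, `n_classified`.
#' @export
tidy.fpd_layer <- function(x, ...) {
  nr <- nrow(x$fpd); nc <- ncol(x$fpd)
  tibble::tibble(row = rep(seq_len(nr), times = nc),
                 col = rep(seq_len(nc), each = nr),
                 fpd = as.vector(x$fpd),
                 n_classified = as.vector(x$n_classified))
}

# ---- plots -------------------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a class map
#'
#' @param object a [class_map()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.class_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df[!is.na(df$class), ],
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(PFF = "#74c476", PMF = "#de2d26",
                                          PCV = "#3182bd",
                                          `plastic-covered` = "#756bb1"),
                               na.value = "grey90", drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [m]", y = "y [m]", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot an FPD layer
#'
#' @param object an `fpd_layer`.
#' @param pixel_size pixel edge length in metres.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fpd_layer <- function(object, pixel_size = object$pixel_size, ...) {
  df <- tidy(object)
  nr <- nrow(object$fpd)
  df$x <- (df$col - 0.5) * pixel_size
  df$y <- (nr - df$row + 0.5) * pixel_size
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$fpd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [m]", y = "y [m]", fill = "FPD") +
    ggplot2::theme_minimal()
}

#' Plot feature importances
#'
#' @param object a [feature_importance()] tibble.
#' @param top_n number of leading features shown.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.feature_importance <- function(object, top_n = 20, ...) {
  df <- utils::head(object, top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance,
                                   y = stats::reorder(.data$feature,
                                                      .data$importance))) +
    ggplot2::geom_col(fill = "#3182bd") +
    ggplot2::labs(x = "Gini importance (summed impurity decrease)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a field-size accuracy sweep
#'
#' @param sweep tibble from [field_size_sweep()].
#' @return a ggplot of producer/user accuracy per class against the minimum
#'   field size retained.
#' @export
plot_field_size_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep,
                              c("user_accuracy", "producer_accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold_ha, y = .data$value,
                                     colour = .data$class,
                                     linetype = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "minimum field size [ha]", y = "accuracy") +
    ggplot2::theme_minimal()
}
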