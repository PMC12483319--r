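# broom-style accessors and ggplot2 output for fitted objects and tables.

#' Tidy the training history of a model
#'
#' @param x A `syn_unet` with a training or adaptation log.
#' @param ... Unused.
#' @return Tibble of per-epoch (or per-iteration) losses.
#' @export
tidy.syn_unet <- function(x, ...) {
  x$log %||% tibble::tibble()
}

#' One-row model summary
#'
#' @param x A `syn_unet`.
#' @param ... Unused.
#' @return Tibble: dimensionality, levels, parameter count, channels, and
#'   the best validation loss when trained.
#' @export
glance.syn_unet <- function(x, ...) {
  tibble::tibble(
    dimensionality = x$cfg$dimensionality,
    levels = x$cfg$levels,
    initial_features = x$cfg$initial_features,
    n_parameters = sum(vapply(x$params, length, 1L)),
    out_channels = paste(x$cfg$out_channels, collapse = ","),
    best_val_loss = if (!is.null(x$log) && "val_loss" %in% names(x$log))
      min(x$log$val_loss, na.rm = TRUE) else NA_real_
  )
}

#' @export
tidy.syn_match_result <- function(x, ...) x$matches

#' @export
glance.syn_match_result <- function(x, ...) {
  tibble::tibble(f1 = x$f1, tp = x$tp, fp = x$fp, fn = x$fn,
                 iou_threshold = x$iou_threshold)
}

#' Training-curve plot
#'
#' @param object A trained `syn_unet`.
#' @param ... Unused.
#' @return A ggplot of train/val loss per epoch.
#' @export
autoplot.syn_unet <- function(object, ...) {
  log <- tidy(object)
  if (!nrow(log)) abort("model has no training log")
  if ("val_loss" %in% names(log)) {
    df <- tidyr::pivot_longer(log, c("train_loss", "val_loss"),
                              names_to = "split", values_to = "loss")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$split)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "epoch", y = "negative Dice loss", colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(log, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::labs(x = "iteration", y = "masked negative Dice loss") +
      ggplot2::theme_minimal()
  }
}

#' Vesicle-table plot
#'
#' Diameter distribution, split by pool when pools are assigned.
#'
#' @param object A [vesicle_table()] result.
#' @param binwidth Histogram bin width in nm.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.syn_vesicle_table <- function(object, binwidth = 2, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$diameter_nm))
  if ("pool" %in% names(object)) {
    p <- p + ggplot2::geom_histogram(ggplot2::aes(fill = .data$pool),
                                     binwidth = binwidth)
  } else {
    p <- p + ggplot2::geom_histogram(binwidth = binwidth)
  }
  p + ggplot2::labs(x = "vesicle diameter (nm)", y = "count") +
    ggplot2::theme_minimal()
}

#' Cumulative distance-distribution plot
#'
#' The cumulative spatial distribution of vesicle distances to a structure
#' (non-decreasing, reaching 1 at the maximum distance).
#'
#' @param distances Numeric distances in nm.
#' @param max_nm Optional axis limit.
#' @return A ggplot object.
#' @export
plot_cumulative_distances <- function(distances, max_nm = NULL) {
  df <- tibble::tibble(distance_nm = sort(distances),
                       cumulative = seq_along(distances) / length(distances))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_nm,
                                        y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance to structure (nm)",
                  y = "cumulative fraction of vesicles") +
    ggplot2::theme_minimal()
  if (!is.null(max_nm)) p <- p + ggplot2::xlim(0, max_nm)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
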