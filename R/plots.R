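#' @importFrom ggplot2 ggplot aes autoplot geom_line geom_point geom_boxplot
#'   geom_jitter geom_raster geom_path labs theme_minimal scale_fill_gradient
#'   scale_y_continuous facet_wrap coord_fixed scale_color_brewer
NULL

#' Plot an annotated image with its instance outlines
#'
#' @param annotated an [annotated_image()] with pixel data.
#' @param predictions optional predictions tibble from
#'   [predict.crystal_model()]; detected instances are drawn on top.
#' @return a ggplot object.
#' @export
plot_annotated <- function(annotated, predictions = NULL) {
  stopifnot(inherits(annotated, "annotated_image"), !is.null(annotated$image))
  img <- as_gray(annotated$image)
  df <- tidyr::expand_grid(y = seq_len(nrow(img)) - 0.5,
                           x = seq_len(ncol(img)) - 0.5)
  df$value <- as.vector(t(img))
  poly_df <- purrr::imap(annotated$instances$polygon, function(p, i) {
    tibble(x = c(p[, 1], p[1, 1]), y = c(p[, 2], p[1, 2]),
           id = i, label = annotated$instances$label[i])
  }) |> bind_rows()
  g <- ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_raster(aes(fill = .data$value)) +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 1), guide = "none") +
    coord_fixed(expand = FALSE) +
    ggplot2::scale_y_reverse() +
    theme_minimal() +
    labs(x = NULL, y = NULL)
  if (nrow(poly_df) > 0L) {
    g <- g + geom_path(data = poly_df,
                       aes(group = .data$id, color = .data$label), linewidth = 0.4) +
      scale_color_brewer(palette = "Set1")
  }
  if (!is.null(predictions) && nrow(predictions) > 0L) {
    pred_df <- purrr::imap(predictions$mask, function(m, i) {
      p <- mask_to_polygon(m)
      tibble(x = c(p[, 1], p[1, 1]), y = c(p[, 2], p[1, 2]), id = paste0("pred", i))
    }) |> bind_rows()
    g <- g + geom_path(data = pred_df, aes(group = .data$id),
                       color = "yellow", linewidth = 0.5, linetype = "22")
  }
  g
}

#' @export
autoplot.metric_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_image,
                              cols = c("precision", "recall", "f_measure", "jaccard", "delta_on"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$metric, y = .data$value)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    scale_y_continuous(limits = c(0, 1)) +
    theme_minimal() +
    labs(x = NULL, y = "per-image value",
         title = sprintf("Segmentation quality over %d images", object$n))
}

#' @export
autoplot.training_log <- function(object, ...) {
  ggplot(object, aes(x = .data$epoch, y = .data$mean_loss)) +
    geom_line() + geom_point(size = 0.8) +
    theme_minimal() +
    labs(x = "epoch", y = "mean BCE loss", title = "Training loss")
}

#' @export
autoplot.experiment_result <- function(object, ...) {
  long <- tidy(object) |>
    filter(.data$status == "ok") |>
    tidyr::pivot_longer(cols = c("f_H", "f_G"),
                        names_to = "target", values_to = "f_measure") |>
    mutate(target = ifelse(.data$target == "f_H", "target H", "target G"))
  ggplot(long, aes(x = factor(.data$row_id), y = .data$f_measure,
                   color = .data$target, group = .data$target)) +
    geom_point() + geom_line(alpha = 0.4) +
    scale_y_continuous(limits = c(0, 1)) +
    theme_minimal() +
    labs(x = "strategy row", y = "mean F-measure",
         title = "Training strategies compared on both targets")
}
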