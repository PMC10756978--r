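#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gene embedding
#'
#' Scatter of the 2-D gene coordinates with gene labels.
#'
#' @param object A `gsn_embedding`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsn_embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene), vjust = -0.8, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "PaCMAP gene embedding",
                  x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' Plot training history curves
#'
#' Loss and accuracy per epoch, training and validation.
#'
#' @param object A trained `gsn_cnn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsn_cnn <- function(object, ...) {
  h <- tidy(object)
  long <- tibble::tibble(
    epoch = rep(h$epoch, 4L),
    metric = rep(c("loss", "accuracy", "val_loss", "val_accuracy"),
                 each = nrow(h)),
    value = c(h$loss, h$accuracy, h$val_loss, h$val_accuracy))
  long$panel <- ifelse(grepl("loss", long$metric), "loss", "accuracy")
  long$set <- ifelse(grepl("val", long$metric), "validation", "training")
  ggplot2::ggplot(long[!is.na(long$value), ],
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a rendered sample image
#'
#' @param object A `gsn_image`.
#' @param ... Unused.
#' @return A ggplot object showing the RGB raster.
#' @export
autoplot.gsn_image <- function(object, ...) {
  d <- dim(object)
  df <- expand.grid(row = seq_len(d[1L]), col = seq_len(d[2L]))
  df$fill <- grDevices::rgb(object[, , 1L] / 255, object[, , 2L] / 255,
                            object[, , 3L] / 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = I(.data$fill))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::theme_void()
}

#' @importFrom rlang .data
NULL
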