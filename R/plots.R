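#' Plot training history of a fitted network
#'
#' Loss and accuracy per epoch for the training and validation partitions.
#'
#' @param object A trained `rdcnn_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rdcnn_model
#' @export
autoplot.rdcnn_model <- function(object, ...) {
  h <- object$history
  if (is.null(h)) stop("model has no training history", call. = FALSE)
  long <- rbind(
    data.frame(epoch = h$epoch, value = h$train_loss, metric = "loss",
               partition = "train"),
    data.frame(epoch = h$epoch, value = h$val_loss, metric = "loss",
               partition = "validation"),
    data.frame(epoch = h$epoch, value = h$train_acc, metric = "accuracy",
               partition = "train"),
    data.frame(epoch = h$epoch, value = h$val_acc, metric = "accuracy",
               partition = "validation"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$partition)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion-matrix heatmap
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  cm <- object$confusion
  df <- as.data.frame(as.table(cm))
  names(df) <- c("true", "pred", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$true))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Plot beats by class
#'
#' Overlays a handful of beats per class, one facet per class — a quick
#' look at the synthetic morphologies or at real data.
#'
#' @param beats Beat matrix.
#' @param labels Integer class labels.
#' @param per_class Beats drawn per class (default 5).
#' @return A ggplot object.
#' @export
plot_beats <- function(beats, labels, per_class = 5) {
  stopifnot(nrow(beats) == length(labels))
  rows <- unlist(lapply(sort(unique(labels)), function(k) {
    utils::head(which(labels == k), per_class)
  }))
  code <- function(k) ifelse(k >= 0 & k <= 4, ecg_classes[k + 1], as.character(k))
  df <- do.call(rbind, lapply(rows, function(i) {
    data.frame(sample = seq_len(ncol(beats)), amplitude = beats[i, ],
               beat = i, class = code(labels[i]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$amplitude,
                                   group = .data$beat)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~class) +
    ggplot2::theme_minimal()
}
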