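# ggplot2 visualization helpers.

#' Plot curves from a curve tibble
#'
#' @param curves Curve tibble; one line per voxel, colored by tissue.
#' @param dt Sampling interval (seconds) for the time axis, default 1.7.
#' @param max_curves Cap on curves drawn (sampled deterministically).
#' @return A ggplot object.
#' @export
plot_curves <- function(curves, dt = 1.7, max_curves = 200) {
  if (nrow(curves) > max_curves) {
    curves <- curves[seq(1, nrow(curves), length.out = max_curves), ]
  }
  cols <- curve_cols(curves)
  long <- tidyr::pivot_longer(
    dplyr::mutate(curves, .curve = dplyr::row_number()),
    dplyr::all_of(cols), names_to = "t", values_to = "signal"
  )
  long$time <- (as.integer(sub("^t", "", long$t)) - 1) * dt
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$signal,
                                     group = .data$.curve)) +
    ggplot2::geom_line(ggplot2::aes(color = .data$tissue), alpha = 0.4) +
    ggplot2::labs(x = "time (s)", y = "signal")
}

#' @describeIn plot_curves Prototype temporal patterns of a cluster model.
#' @param object,x Model object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.dsc_kmeans <- function(object, dt = 1.7, ...) {
  if (is.null(object$prototype_curves)) {
    rlang::abort("cluster model has no decoded prototypes; run decode_cluster_prototypes()")
  }
  k <- nrow(object$prototype_curves)
  df <- tibble::tibble(
    cluster = factor(rep(seq_len(k) - 1L, each = ncol(object$prototype_curves))),
    time = rep((seq_len(ncol(object$prototype_curves)) - 1) * dt, times = k),
    signal = as.vector(t(object$prototype_curves))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$signal,
                                   color = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "normalized signal",
                  color = "temporal pattern")
}

#' @describeIn plot_curves Training-loss trajectory of an autoencoder.
#' @exportS3Method ggplot2::autoplot
autoplot.dsc_autoencoder <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "MSE loss")
}

#' @describeIn plot_curves Training-loss trajectory of the CNN.
#' @exportS3Method ggplot2::autoplot
autoplot.dsc_cnn <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "cross-entropy loss")
}

#' Heatmap of a cluster frequency table
#'
#' @param freq Tibble from [cluster_frequency_table()].
#' @param group Grouping column name, default `"tissue"`.
#' @return A ggplot object.
#' @export
plot_frequency_table <- function(freq, group = "tissue") {
  long <- tidyr::pivot_longer(freq, dplyr::starts_with("cluster_"),
                              names_to = "cluster", values_to = "percentage")
  long$cluster <- as.integer(sub("^cluster_", "", long$cluster))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$cluster),
                                     y = .data[[group]],
                                     fill = .data$percentage)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percentage)),
                       size = 2.7) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "temporal pattern", fill = "% of voxels")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data :=
NULL
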