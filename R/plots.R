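# ggplot2 displays for connectivity matrices, threshold sweeps and
# training curves.

#' Heatmap of a connectivity (or SPD) matrix
#'
#' @param M square matrix, e.g. from [connectivity_matrix()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_connectivity <- function(M, title = NULL) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(M)), times = ncol(M)),
    col = rep(seq_len(ncol(M)), each = nrow(M)),
    value = as.vector(M))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "channel", y = "channel", fill = attr(M, "kind"),
                  title = title) +
    ggplot2::theme_minimal()
}

#' Accuracy as a function of edge threshold
#'
#' @param sweep tibble from [threshold_sweep()].
#' @return a ggplot object.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$threshold,
                                      y = .data$mean_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "edge threshold", y = "mean test accuracy") +
    ggplot2::theme_minimal()
}

#' Training curve of an SPD network fit
#'
#' @param fit an `spdnet_fit`.
#' @return a ggplot object showing loss and training accuracy by epoch.
#' @export
plot_training_curve <- function(fit) {
  df <- tidyr_longer(fit$log)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape to avoid a tidyr dependency for one call
tidyr_longer <- function(log) {
  dplyr::bind_rows(
    tibble::tibble(epoch = log$epoch, metric = "loss", value = log$loss),
    tibble::tibble(epoch = log$epoch, metric = "train_accuracy",
                   value = log$train_accuracy))
}

#' @importFrom rlang .data
NULL
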