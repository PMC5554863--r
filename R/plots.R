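# ggplot2 views of the main result types. These are diagnostic figures, not
# publication layouts: heatmaps for matrices, tile plots for trajectories,
# curves for learning fits.

#' @export
autoplot.cohesion_matrix <- function(object, ...) {
  df <- tibble::tibble(
    from = rep(rownames(object), times = ncol(object)),
    to = rep(colnames(object), each = nrow(object)),
    rate = as.vector(object)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, max(object, 1e-12))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-switch\nrate",
                  title = "Cohesion matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.community_trajectory <- function(object, ...) {
  lab <- object$labels
  df <- tibble::tibble(
    node = factor(rep(object$node_ids, times = ncol(lab)),
                  levels = rev(object$node_ids)),
    layer = rep(seq_len(ncol(lab)), each = nrow(lab)),
    community = factor(as.integer(lab))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$node,
                                   fill = .data$community)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::labs(x = "layer (time window)", y = NULL, fill = "community",
                  title = "Community trajectory") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.learning_fit <- function(object, ...) {
  df <- tibble::tibble(trial = object$trials, mt = object$mt,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mt), alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick",
                       linewidth = 0.8) +
    ggplot2::labs(x = "trial", y = "movement time (s)",
                  title = sprintf("Double-exponential fit (kappa = %.3g)",
                                  object$kappa)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.comdyn_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            -dplyr::all_of("node"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "value", y = "nodes",
                  title = "Per-node dynamic community metrics") +
    ggplot2::theme_minimal()
}
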