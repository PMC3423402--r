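# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.distance_model <- function(x, ...) {
  tibble::tibble(term = c("intercept", "log_distance"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.distance_model <- function(x, ...) {
  tibble::tibble(residual_sd = x$residual_sd, n_pairs = x$n_pairs)
}

#' @exportS3Method generics::tidy
tidy.brain_partition <- function(x, ...) {
  tibble::tibble(
    node = seq_along(x$assignment),
    region = names(x$assignment) %||% as.character(seq_along(x$assignment)),
    module = as.integer(x$assignment))
}

#' @exportS3Method generics::glance
glance.brain_partition <- function(x, ...) {
  tibble::tibble(K = x$K, Q = x$Q)
}

#' @exportS3Method generics::tidy
tidy.group_test_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.group_test_result <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x),
    n_significant = sum(x$significant),
    n_down = sum(x$significant & x$direction == "down"),
    n_up = sum(x$significant & x$direction == "up"),
    q = attr(x, "q"), n_perm = attr(x, "n_perm"))
}

#' @exportS3Method generics::tidy
tidy.classification_report <- function(x, ...) {
  x$iterations
}

#' @exportS3Method generics::glance
glance.classification_report <- function(x, ...) {
  x$summary
}

#' @exportS3Method generics::tidy
tidy.sparse_graph <- function(x, ...) {
  w <- x$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  nm <- colnames(w) %||% as.character(seq_len(nrow(w)))
  tibble::tibble(node_i = nm[idx[, 1]], node_j = nm[idx[, 2]],
                 weight = w[idx])
}

#' @exportS3Method generics::glance
glance.sparse_graph <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$weights), n_edges = x$n_edges,
                 density = x$density, target_density = x$target_density,
                 min_connected = x$min_connected)
}

#' Plot correlation against inter-regional distance
#'
#' Scatter of pairwise correlations over log centroid distance with the
#' fitted background trend; the plotted quantity the distance penalty
#' removes.
#'
#' @param conn A raw-stage `connectivity_matrix`.
#' @param parcellation The matching parcellation.
#' @return A ggplot object.
#' @export
plot_distance_trend <- function(conn, parcellation) {
  d <- parcellation_distances(parcellation)
  ut <- upper.tri(d)
  df <- tibble::tibble(distance = d[ut], r = conn_weights(conn)[ut])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$r)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_smooth(method = "lm",
                         formula = y ~ log(x), se = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "inter-regional distance (mm)",
                  y = "Pearson correlation")
}

#' @exportS3Method ggplot2::autoplot
autoplot.metric_curve <- function(object, metrics = c("PL", "CC", "SWI"),
                                  ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = dplyr::any_of(metrics),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold,
                                   y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "edge density", y = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.group_test_result <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$p_adjusted)
  df$region <- factor(df$region, levels = rev(df$region))
  ggplot2::ggplot(
    utils::head(df, 30),
    ggplot2::aes(x = .data$t_statistic, y = .data$region,
                 fill = .data$direction, alpha = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::labs(x = "Welch t (patient - control, PI rank)", y = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.feature_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("test_selectivity",
                                     "test_sensitivity"),
                            names_to = "rate", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$rate)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of selected features", y = "mean rate")
}

#' Heatmap of a connectivity matrix
#'
#' @param conn A `connectivity_matrix` (raw or penalized).
#' @return A ggplot object.
#' @export
plot_connectivity <- function(conn) {
  w <- conn_weights(conn)
  nm <- colnames(w) %||% as.character(seq_len(nrow(w)))
  df <- expand.grid(i = seq_len(nrow(w)), j = seq_len(ncol(w)))
  df$value <- w[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0(attr(conn, "stage"), " r"))
}
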