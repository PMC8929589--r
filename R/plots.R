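# ggplot2 helpers for the main result types.

#' Plot paired index change per estuary
#'
#' The paired-comparison figure style: one line per estuary connecting the
#' index in the two conditions.
#'
#' @param x An `oyster_change` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oyster_change <- function(x, ...) {
  df <- tidy(x)
  if ("pre" %in% names(df)) {
    long <- tidyr::pivot_longer(df, c("pre", "post"), names_to = "condition",
                                values_to = "value")
    long$condition <- factor(long$condition, levels = c("pre", "post"))
  } else {
    long <- tidyr::pivot_longer(df, c("value_a", "value_b"),
                                names_to = "condition", values_to = "value")
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value,
                                     group = .data$estuary_id)) +
    ggplot2::geom_line(linetype = "dashed", alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::labs(title = paste("Paired change:", x$contrast),
                  subtitle = sprintf("n = %d estuaries, Wilcoxon p = %.3g",
                                     x$n_replicates, x$p_value),
                  x = NULL, y = "index") +
    ggplot2::theme_minimal()
}

#' Plot a habitat selection analysis
#'
#' Use proportions with simultaneous confidence intervals against
#' availability; habitats are annotated with the preference/avoidance call.
#'
#' @param x An `oyster_selection` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oyster_selection <- function(x, ...) {
  df <- tibble::as_tibble(x)
  df$habitat <- factor(df$habitat, levels = substrate_classes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$habitat)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$u_i, fill = .data$call),
                      alpha = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.25) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p_i), shape = 4, size = 3) +
    ggplot2::scale_fill_manual(values = c(preference = "#2166ac",
                                          avoidance = "#b2182b",
                                          proportional = "grey60")) +
    ggplot2::labs(y = "proportion (bars = use, x = availability)", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Map the water grid, records, and networks
#'
#' @param grid A `coast_grid`.
#' @param records Optional record tibble to overlay.
#' @param networks Optional `networks` tibble; reachable-zone outlines are
#'   drawn per network.
#' @return A ggplot.
#' @export
plot_coast <- function(grid, records = NULL, networks = NULL) {
  idx <- which(!grid$water)
  land_df <- if (length(idx) > 0) {
    ctr <- grid_cell_center(grid, idx)
    tibble::tibble(x = ctr[, "x"], y = ctr[, "y"])
  } else tibble::tibble(x = numeric(), y = numeric())
  p <- ggplot2::ggplot() +
    ggplot2::geom_tile(data = land_df,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       width = grid$cell_size, height = grid$cell_size,
                       fill = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
  if (!is.null(networks) && nrow(networks) > 0) {
    ring_df <- purrr::map_dfr(seq_len(nrow(networks)), function(i) {
      purrr::imap_dfr(networks$polygon[[i]], function(ring, j) {
        tibble::tibble(network_id = networks$network_id[i],
                       ring = paste(networks$network_id[i], j),
                       x = ring[, 1], y = ring[, 2])
      })
    })
    p <- p + ggplot2::geom_path(
      data = ring_df,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$ring,
                   color = .data$network_id))
  }
  if (!is.null(records) && nrow(records) > 0) {
    p <- p + ggplot2::geom_point(
      data = records,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$species),
      size = 1.5, alpha = 0.8)
  }
  p
}
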