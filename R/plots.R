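#' Heatmap of a mixing matrix
#'
#' Tile map of the edge-weight fractions between attribute categories; the
#' diagonal mass is what drives assortativity.
#'
#' @param object An [mixing_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot echo_mixing
#' @export
autoplot.echo_mixing <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$proportion)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::labs(x = "target category", y = "source category",
                  fill = "edge-weight\nfraction",
                  title = sprintf("Mixing matrix (%s)",
                                  object$attribute %||% "attribute")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Assortativity by layer and mode
#'
#' @param object An `echo_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object: bar chart of r per network, weighted vs
#'   unweighted.
#' @method autoplot echo_report
#' @export
autoplot.echo_report <- function(object, ...) {
  df <- object$assortativity |>
    mutate(network = paste(.data$layer, .data$mode, sep = "/"),
           weighting = if_else(.data$weighted, "weighted", "unweighted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network, y = .data$r,
                                   fill = .data$weighting)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "assortativity r",
                  title = "Echo chamber strength by network") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Distribution of structural-hole indices by behavior category
#'
#' @param sh_metrics The `metrics` tibble from [sh_table()].
#' @param roles A tibble from [user_roles()] (`user_id`, `behavior`).
#' @return A ggplot object: violin plots of constraint, effective size,
#'   efficiency, and hierarchy per behavior category.
#' @export
plot_structural_holes <- function(sh_metrics, roles) {
  df <- sh_metrics |>
    left_join(roles[c("user_id", "behavior")], by = c(node = "user_id")) |>
    tidyr::pivot_longer(c("effective_size", "efficiency", "constraint",
                          "hierarchy"),
                        names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$behavior, y = .data$value)) +
    ggplot2::geom_violin(fill = "#b2182b", alpha = 0.4, scale = "width") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Structural-hole indices by behavior category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
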