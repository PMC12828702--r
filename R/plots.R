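# ggplot2 views of the QC result types.

#' @export
autoplot.gg_length_histogram <- function(object, ...) {
  k <- attr(object, "k")
  df <- as_tibble(object) |>
    mutate(pct = 100 * .data$count / max(1L, sum(.data$count)),
           full = .data$n_units == k)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_units), y = .data$pct,
                                   fill = .data$full)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#2166ac")) +
    ggplot2::labs(x = "gRNA units assembled", y = "% of binned inserts",
                  title = sprintf("Assembly length distribution (k = %d)", k)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gg_length_histogram
#' @param object,x A `gg_length_histogram`.
#' @param ... Ignored.
#' @export
plot_length_histogram <- function(x, ...) autoplot(x, ...)

#' @export
autoplot.position_spacer_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position),
                                   y = .data$member, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "array position", y = "pool spacer",
                  fill = "inserts",
                  title = "Spacer abundance by array position") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.position_spacer_matrix
#' @param object,x A `position_spacer_matrix`.
#' @param ... Ignored.
#' @export
plot_spacer_matrix <- function(x, ...) autoplot(x, ...)
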