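# ggplot2 views of a run and of individual read clouds.

#' Plot a read cloud
#'
#' Draws each unique read as a horizontal segment over the precursor
#' (scaled by copy count), with the loop shaded and the guide and
#' expected star positions marked.
#'
#' @param predictions predictions tibble (or `mir_run`).
#' @param name locus name to plot; defaults to the first prediction.
#' @return a ggplot object.
#' @export
plot_read_cloud <- function(predictions, name = NULL) {
  if (inherits(predictions, "mir_run")) {
    predictions <- predictions$predictions
  }
  if (!nrow(predictions)) abort("no predictions to plot")
  p <- if (is.null(name)) predictions[1, ] else {
    filter(predictions, .data$name == !!name) |> dplyr::slice(1)
  }
  if (!nrow(p)) abort(paste0("no prediction named ", name))
  reads <- p$reads[[1]] |>
    arrange(.data$local_start) |>
    mutate(row = dplyr::row_number())
  gg <- ggplot2::ggplot(reads) +
    ggplot2::annotate("rect", xmin = p$loop_start, xmax = p$loop_end,
                      ymin = 0.5, ymax = nrow(reads) + 0.5,
                      fill = "grey85") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$local_start, xend = .data$local_end,
                   y = .data$row, yend = .data$row,
                   linewidth = .data$count, colour = .data$arm)
    ) +
    ggplot2::scale_linewidth(range = c(0.5, 4)) +
    ggplot2::labs(
      x = "precursor position (nt, 5'->3')", y = "unique read",
      title = p$name,
      subtitle = sprintf("score %d/6, %d reads (%d unique), MFEI %.2f",
                         p$score, p$total_reads, p$n_unique_reads, p$mfei)
    ) +
    ggplot2::theme_minimal()
  if (!is.na(p$guide_local_start)) {
    gg <- gg + ggplot2::geom_vline(xintercept = p$guide_local_start,
                                   linetype = "dashed")
  }
  if (!is.na(p$star_expected_start)) {
    gg <- gg + ggplot2::geom_vline(xintercept = p$star_expected_start,
                                   linetype = "dotted")
  }
  gg
}

#' Score distribution of a run
#'
#' @param object a `mir_run`.
#' @param ... unused.
#' @return a ggplot bar chart of prediction counts per quality score.
#' @export
autoplot.mir_run <- function(object, ...) {
  p <- object$predictions
  df <- tibble(score = factor(p$score, levels = 0:6))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "quality score (stars)", y = "predictions") +
    ggplot2::theme_minimal()
}
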