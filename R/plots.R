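#' Host-range heatmap
#'
#' Categorical phage x isolate heatmap of sensitivity grades, phages on the
#' x-axis and isolates on the y-axis, with the six-grade palette (dark blue =
#' no sensitivity through red = ultimate). Input ordering is preserved.
#'
#' @param records EOP-record tibble (from [eop_from_spots()]) with columns
#'   `phage_id`, `isolate_id`, `grade`.
#' @return A ggplot object.
#' @export
plot_host_range <- function(records) {
  if (nrow(records) == 0) abort("empty host-range matrix")
  stopifnot(all(c("phage_id", "isolate_id", "grade") %in% names(records)))
  pal <- c(no_sensitivity = "#1f3b73", moderately_low = "#8ecae6",
           low = "#9a9a9a", moderate = "#ffd59e", high = "#f4862c",
           ultimate = "#c1121f")
  records <- dplyr::mutate(
    records,
    phage_id = factor(.data$phage_id, levels = unique(.data$phage_id)),
    isolate_id = factor(.data$isolate_id, levels = rev(unique(.data$isolate_id))),
    grade = factor(.data$grade, levels = eop_grades())
  )
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$phage_id, y = .data$isolate_id,
                               fill = .data$grade)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE,
                               name = "Sensitivity") +
    ggplot2::labs(x = "Phage", y = "Bacterial isolate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Render and save the host-range heatmap
#'
#' @param records EOP-record tibble.
#' @param path Output file; format from extension (`.png`, `.pdf`, `.svg`).
#' @return Invisibly, `path`.
#' @export
render_heatmap <- function(records, path) {
  p <- plot_host_range(records)
  ggplot2::ggsave(path, p,
                  width = 2 + 0.35 * dplyr::n_distinct(records$phage_id),
                  height = 2 + 0.18 * dplyr::n_distinct(records$isolate_id),
                  limitsize = FALSE)
  invisible(path)
}

#' Plot growth curves of a killing assay
#'
#' OD600 against time, one panel per phage/MOI condition, replicate wells as
#' thin lines, the phage-free control overlaid in black.
#'
#' @param curves Long growth-curve tibble.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(curves) {
  ctrl <- dplyr::filter(curves, is.na(.data$phage_id))
  trt <- dplyr::filter(curves, !is.na(.data$phage_id)) |>
    dplyr::mutate(condition = paste0(.data$phage_id, " MOI ", .data$moi))
  p <- ggplot2::ggplot(trt, ggplot2::aes(x = .data$time_h, y = .data$od600,
                                         group = .data$well_id)) +
    ggplot2::geom_line(color = "#d1495b", alpha = 0.8) +
    ggplot2::labs(x = "Time (h)", y = expression(OD[600])) +
    ggplot2::theme_minimal()
  if (nrow(trt)) p <- p + ggplot2::facet_wrap(~condition)
  if (nrow(ctrl)) {
    p <- p + ggplot2::geom_line(
      data = dplyr::select(ctrl, -"phage_id", -"moi"),
      color = "black", alpha = 0.6
    )
  }
  p
}

#' @describeIn analyze_killing_assay Growth-curve panel plot of the analyzed
#'   assay, annotated with per-condition virulence indices.
#' @param object A `killing_assay` object.
#' @method autoplot killing_assay
#' @export
autoplot.killing_assay <- function(object, ...) {
  p <- plot_growth_curves(object$curves)
  lab <- object$results |>
    dplyr::mutate(condition = paste0(.data$phage_id, " MOI ", .data$moi),
                  label = sprintf("V = %.1f", .data$virulence_index))
  p + ggplot2::geom_text(
    data = lab,
    ggplot2::aes(x = -Inf, y = Inf, label = .data$label),
    inherit.aes = FALSE, hjust = -0.1, vjust = 1.5, size = 3
  )
}
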