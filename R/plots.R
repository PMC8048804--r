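# Basic figures: discrimination dot heat map and the COF-COM butterfly path.

#' Dot heat map of per-horse discrimination
#'
#' Horses on the x-axis, variables on the y-axis; sensitivity mapped to
#' colour and specificity to dot size.
#'
#' @param cells tibble from [discrimination_table()].
#' @param variables optional character vector restricting/ordering the rows.
#' @return a ggplot object.
#' @export
plot_heatmap <- function(cells, variables = NULL) {
  if (!is.null(variables)) {
    cells <- cells[cells$variable %in% variables, ]
    cells$variable <- factor(cells$variable, levels = rev(variables))
  }
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$horse_id, y = .data$variable,
                                      colour = .data$sensitivity,
                                      size = .data$specificity)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_size_continuous(limits = c(0, 1), range = c(0.5, 5)) +
    ggplot2::facet_wrap(~gait) +
    ggplot2::labs(x = "horse", y = NULL) +
    ggplot2::theme_minimal()
}

#' Butterfly plot of the COF-COM relative path
#'
#' @param path tibble from [cof_path()].
#' @return a ggplot object.
#' @export
plot_cof_path <- function(path) {
  ok <- stats::complete.cases(path)
  ggplot2::ggplot(path[ok, ], ggplot2::aes(x = .data$dx_m * 1000,
                                           y = .data$dy_m * 1000)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral displacement (mm, right +)",
                  y = "cranial displacement (mm)") +
    ggplot2::theme_minimal()
}
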