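#' Stacked-bar time course of seven-bin transcript fractions
#'
#' One stacked bar per timepoint showing the percentage of transcripts in
#' each length bin, faceted by condition (and TFS state when both are
#' present). Replicates are averaged before plotting.
#'
#' @param bin_table A `BinTable`.
#' @param scheme The [bin_scheme()] used, for bin labels.
#' @return A ggplot object.
#' @export
plot_bin_time_course <- function(bin_table, scheme = default_bin_scheme()) {
  validate_bin_scheme(scheme)
  labels <- c(sprintf("+%g (stalled)", scheme$upper[1]),
              sprintf("%g-%g", floor(scheme$lower[2:7]) + 1, scheme$upper[2:7]))
  long <- as_tibble(bin_table) |>
    tidyr::pivot_longer(dplyr::all_of(bin_column_names()),
                        names_to = "bin", values_to = "fraction") |>
    dplyr::group_by(.data$condition, .data$tfs, .data$time_s, .data$bin) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop") |>
    dplyr::mutate(
      bin = factor(.data$bin, levels = rev(bin_column_names()),
                   labels = rev(labels))
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$time_s), y = 100 * .data$fraction, fill = .data$bin
  )) +
    ggplot2::geom_col(position = "stack", width = 0.85) +
    ggplot2::scale_fill_viridis_d(name = "RNA length (nt)") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$tfs), cols = ggplot2::vars(.data$condition),
      labeller = ggplot2::labeller(
        tfs = c(`FALSE` = "-TFS", `TRUE` = "+TFS")
      )
    ) +
    ggplot2::labs(x = "Time after restart (s)", y = "Transcripts (%)") +
    ggplot2::theme_minimal()
}

#' Waterfall plot of normalized lane traces over time
#'
#' @param waterfall Output of [waterfall_normalize()] (with a `length`
#'   column, i.e. called with a calibration).
#' @return A ggplot object.
#' @export
plot_waterfall <- function(waterfall) {
  if (!"length" %in% names(waterfall)) {
    abort("waterfall table needs a length column; pass a calibration to waterfall_normalize()")
  }
  ggplot2::ggplot(waterfall, ggplot2::aes(
    x = .data$length, y = .data$rel_intensity, colour = .data$lane
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Transcript length (nt)",
                  y = "Intensity relative to SM total",
                  colour = "Lane") +
    ggplot2::theme_minimal()
}

#' Dot plot of elongation rates relative to the histone-free template
#'
#' Closed circles show reactions without TFS, open circles with TFS; error
#' bars are replicate standard errors.
#'
#' @param kin A [compute_kinetics()] result (or its `summary` tibble).
#' @return A ggplot object.
#' @export
plot_relative_rates <- function(kin) {
  summary <- if (inherits(kin, "tec_kinetics")) kin$summary else as_tibble(kin)
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$condition, y = .data$rel_rate, shape = .data$tfs
  )) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$rel_rate - .data$rel_rate_se,
      ymax = .data$rel_rate + .data$rel_rate_se
    ), width = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(size = 3, na.rm = TRUE) +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 1),
      labels = c(`FALSE` = "-TFS", `TRUE` = "+TFS"), name = NULL
    ) +
    ggplot2::labs(x = NULL, y = "Elongation rate relative to histone-free") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot tec_kinetics
#' @export
autoplot.tec_kinetics <- function(object, ...) plot_relative_rates(object)
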