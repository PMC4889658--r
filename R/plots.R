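#' Plot a sliding-window median series
#'
#' Line plot of each tracked variable's rolling median against the rolling
#' median of the ranking variable.
#'
#' @param object A [sliding_window_median()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sliding_window_series <- function(object, ...) {
  key <- attr(object, "sort_key")
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = -c("window_start", dplyr::all_of(key)),
                              names_to = "variable",
                              values_to = "median")
  ggplot2::ggplot(long, ggplot2::aes(.data[[key]], .data$median)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(
      x = paste0("rolling median ", key),
      y = "rolling median",
      title = sprintf("Sliding-window medians (window = %d, step = %d)",
                      attr(object, "window"), attr(object, "step")))
}

#' Bar chart of strand-asymmetry values by region class
#'
#' @param dsa_tbl Output of [dsa_profile()].
#' @return A ggplot object.
#' @export
plot_dsa_profile <- function(dsa_tbl) {
  dat <- dsa_tbl |>
    mutate(region = paste(.data$pos_class, .data$kind))
  ggplot2::ggplot(dat, ggplot2::aes(.data$region, .data$S,
                                    fill = .data$motif)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "strand asymmetry S",
                  title = "DNA strand asymmetry by region class") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' IpE unit sizes by positional class and donor strength quartile
#'
#' @param ipe_units IpE tibble with a `strength_class` column (see
#'   [run_pipeline()]).
#' @return A ggplot object (log-scaled sizes).
#' @export
plot_ipe_by_quartile <- function(ipe_units) {
  dat <- ipe_units |> filter(!is.na(.data$strength_class))
  ggplot2::ggplot(dat, ggplot2::aes(.data$strength_class, .data$size)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~pos_class) +
    ggplot2::labs(x = "upstream 5'ss strength quartile",
                  y = "IpE unit size (nt)",
                  title = "IpE unit size by 5'ss strength")
}
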