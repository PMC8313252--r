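# ggplot2 helpers for the main result types

#' Plot a chromatogram
#'
#' @param chrom Chromatogram tibble (`time_min`, `signal`).
#' @param peaks Optional assigned peak tibble to annotate.
#' @return A ggplot object.
#' @export
plot_chromatogram <- function(chrom, peaks = NULL) {
  p <- ggplot2::ggplot(chrom, ggplot2::aes(x = .data$time_min, y = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "retention time (min)", y = "detector response (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    lab <- peaks %>%
      mutate(class = ifelse(is.na(.data$class), "?", .data$class))
    p <- p +
      ggplot2::geom_point(data = lab,
        ggplot2::aes(x = .data$apex_time, y = .data$height), shape = 25) +
      ggplot2::geom_text(data = lab,
        ggplot2::aes(x = .data$apex_time, y = .data$height, label = .data$class),
        angle = 90, hjust = -0.1, size = 2.5)
  }
  p
}

#' Plot a class profile as a bar chart
#'
#' @param profile Profile tibble (`class`, `mole_fraction`).
#' @param min_fraction Hide classes below this fraction (default 0).
#' @return A ggplot object.
#' @export
plot_class_profile <- function(profile, min_fraction = 0) {
  dat <- profile %>%
    filter(.data$mole_fraction >= min_fraction) %>%
    mutate(class = factor(.data$class, levels = rev(chrom_class_universe())))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$mole_fraction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mole fraction") +
    ggplot2::theme_minimal()
}

#' Plot a degradation time course by chromatographic class
#'
#' @param tc A [simulate_timecourse()] result.
#' @param classes Classes to show (default: all with a visible amount).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc, classes = NULL) {
  days <- tc$abundance$time
  long <- bind_rows(map(days, function(d) {
    class_profile(tc, d) %>% mutate(time = d)
  }))
  if (is.null(classes)) {
    keep <- long %>%
      group_by(.data$class) %>%
      summarise(mx = max(.data$amount), .groups = "drop") %>%
      filter(.data$mx > 1e-4) %>%
      pull("class")
  } else keep <- classes
  long <- long %>% filter(.data$class %in% keep)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$amount,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "amount (a.u.)", colour = "class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for simulated time courses
#'
#' @param object A `phyt_timecourse`.
#' @param ... Passed to [plot_timecourse()].
#' @return A ggplot object.
#' @method autoplot phyt_timecourse
#' @export
autoplot.phyt_timecourse <- function(object, ...) plot_timecourse(object, ...)
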