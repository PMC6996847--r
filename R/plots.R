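#' Plot per-locus diversity statistics
#'
#' Dot plot of a chosen statistic from [locus_stats()] across loci, one
#' panel colour per population.
#'
#' @param stats Output of [locus_stats()].
#' @param statistic Column to plot (default `"he"`).
#' @return A ggplot object.
#' @export
plot_locus_stats <- function(stats, statistic = "he") {
  stopifnot(statistic %in% names(stats))
  ggplot2::ggplot(stats, ggplot2::aes(
    x = factor(.data$locus, levels = unique(.data$locus)),
    y = .data[[statistic]], colour = .data$population,
    group = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = NULL, y = statistic) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname call_events
#' @param object An `mhc_events` tibble.
#' @param ... Unused.
#' @export
autoplot.mhc_events <- function(object, ...) {
  ev <- object[object$type %in% c("recombination", "conversion",
                                  "insertion", "deletion"), ]
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$population,
                                   fill = .data$type)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(y = "meiotic events", fill = "event type") +
    ggplot2::theme_minimal()
}
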