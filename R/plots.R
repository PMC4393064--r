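#' Plot cumulative center-distance curves
#'
#' @param cdfs Named list of [distance_cdf()] tibbles (one per method), or a
#'   single such tibble.
#' @return A ggplot object.
#' @export
plot_distance_cdf <- function(cdfs) {
  if (is.data.frame(cdfs)) cdfs <- list(calls = cdfs)
  df <- dplyr::bind_rows(cdfs, .id = "method")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$cum_ratio,
                                   colour = .data$method)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "center distance to true nucleosome (bp)",
                  y = "cumulative frequency ratio", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of linker lengths
#'
#' @param lengths Integer vector from [linker_lengths()].
#' @param binwidth Histogram bin width, bp.
#' @param max_length Truncate the display at this linker length.
#' @return A ggplot object.
#' @export
plot_linker_lengths <- function(lengths, binwidth = 2, max_length = 400) {
  df <- tibble::tibble(length = lengths[lengths <= max_length])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "linker length (bp)", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot a TSS-aligned profile
#'
#' @param profile A [tss_profile()] tibble, or a named list of them (e.g.
#'   one per condition).
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(profile) {
  if (is.data.frame(profile)) profile <- list(profile = profile)
  df <- dplyr::bind_rows(profile, .id = "condition")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$value,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance from TSS (bp)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Overview plot of a consensus vote
#'
#' Shows member calls per area (voter on the y axis, interval on the x axis)
#' and the emitted consensus calls, for a genomic slice.
#'
#' @param object A [nuc_vote()] object.
#' @param xlim Optional length-2 numeric restricting the genomic range shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nuc_vote
#' @export
autoplot.nuc_vote <- function(object, xlim = NULL, ...) {
  members <- dplyr::mutate(object$members, track = .data$voter)
  consensus <- dplyr::mutate(object$consensus, track = "nucvoter")
  df <- dplyr::bind_rows(members, consensus)
  if (!is.null(xlim)) {
    df <- dplyr::filter(df, .data$center >= xlim[1], .data$center <= xlim[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$track, yend = .data$track,
                                   colour = .data$occupancy_norm)) +
    ggplot2::geom_segment(linewidth = 4) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "occupancy") +
    ggplot2::theme_minimal()
}
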