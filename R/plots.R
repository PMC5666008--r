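#' Depth profile plot for a genomic region
#'
#' Windowed read depth of the three trio members over a region; hemizygous
#' deletions show as stretches at roughly half an individual's mean depth.
#'
#' @param obs A `trio_obs`.
#' @param chrom Chromosome to plot.
#' @param start,end Region limits (defaults to the whole chromosome).
#' @param bin_bp Window size.
#' @return A ggplot object.
#' @export
plot_depth_tracks <- function(obs, chrom, start = NULL, end = NULL,
                              bin_bp = 1000) {
  tracks <- purrr::map_dfr(c("father", "mother", "offspring"), function(ind) {
    dplyr::mutate(depth_track(obs, ind, bin_bp), individual = ind)
  })
  tracks <- tracks[tracks$chrom == chrom, ]
  if (!is.null(start)) tracks <- tracks[tracks$end > start, ]
  if (!is.null(end)) tracks <- tracks[tracks$start < end, ]
  ggplot2::ggplot(tracks, ggplot2::aes(
    x = (.data$start + .data$end) / 2, y = .data$depth,
    colour = .data$individual
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0(chrom, " position (bp)"), y = "read depth",
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of MIE categories
#'
#' @param classified Output of [classify_mies()].
#' @return A ggplot object.
#' @export
plot_mie_categories <- function(classified) {
  counts <- dplyr::count(classified, .data$category, .drop = FALSE)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "MIE count") +
    ggplot2::theme_minimal()
}

#' Nearest-neighbour distance distribution of CNIVs
#'
#' Histogram of log10 nearest-neighbour distances with the clustering
#' threshold marked; tight clusters betray multi-site conversion events.
#'
#' @param cnivs Position table (`chrom`, `pos`) or numeric vector.
#' @param threshold Optional clustering threshold (bp) drawn as a line.
#' @return A ggplot object.
#' @export
plot_adjacency_distances <- function(cnivs, threshold = NULL) {
  nn <- nearest_neighbour_distances(as_position_table(cnivs))
  df <- tibble::tibble(distance = nn[is.finite(nn) & !is.na(nn)])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "nearest-neighbour distance (bp)", y = "CNIVs") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}

#' @describeIn plot_mie_categories autoplot method for a rate estimate:
#'   point estimate and count-range interval of the per-generation rate.
#' @param object A `rate_estimate`.
#' @param ... Unused.
#' @export
autoplot.rate_estimate <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term == "mu_per_generation", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$low, ymax = .data$high),
      width = 0.1) +
    ggplot2::labs(x = NULL, y = "rate per site per generation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
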