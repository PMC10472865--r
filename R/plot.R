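# ggplot2 visualizations for the main result types.

mcimage_df <- function(img, channels = NULL, max_px = 400L) {
  img <- max_project(img)
  if (is.null(channels)) {
    channels <- img$channel_names
  }
  d <- dim(img$data)
  stride <- max(1L, ceiling(max(d[1:2]) / max_px))
  rows <- seq(1L, d[1L], by = stride)
  cols <- seq(1L, d[2L], by = stride)
  out <- lapply(channels, function(ch) {
    m <- get_channel(img, ch)[rows, cols]
    tibble(
      x_um = rep((cols - 0.5) * img$pixel_size_um, each = length(rows)),
      y_um = rep((rows - 0.5) * img$pixel_size_um, times = length(cols)),
      channel = ch, intensity = as.vector(m)
    )
  })
  bind_rows(out)
}

#' Plot a multi-channel image
#'
#' Intensity rasters faceted by channel (z-stacks are max-projected; large
#' images are downsampled for display).
#'
#' @param object A `multichannel_image`.
#' @param channels Channels to show (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.multichannel_image <- function(object, channels = NULL, ...) {
  df <- mcimage_df(object, channels)
  ggplot(df, aes(x = .data$x_um, y = .data$y_um, fill = .data$intensity)) +
    geom_raster() +
    facet_wrap(~channel) +
    scale_fill_viridis_c() +
    coord_fixed() +
    ggplot2::scale_y_reverse() +
    labs(x = "x (µm)", y = "y (µm)", fill = "counts") +
    theme_minimal()
}

#' Plot a line profile
#'
#' @param object A tibble returned by [line_profile()].
#' @param ... Unused.
#' @return A ggplot of per-channel intensity against distance.
#' @export
autoplot.line_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$distance_um, y = .data$intensity,
                     colour = .data$channel)) +
    geom_line() +
    labs(x = "distance (µm)", y = "intensity (counts)",
         colour = NULL) +
    theme_minimal()
}

#' Stacked per-frame morphology fractions
#'
#' @param summaries Tibble of per-frame rows from [summarize_frame()] /
#'   [morphology_pipeline()].
#' @return A ggplot: stacked dot/rod/network fractions per frame.
#' @export
plot_morphology_summary <- function(summaries) {
  df <- tidyr::pivot_longer(
    summaries,
    cols = c("fraction_dot", "fraction_rod", "fraction_network"),
    names_to = "class", names_prefix = "fraction_", values_to = "fraction"
  )
  df$class <- factor(df$class, levels = c("network", "rod", "dot"))
  ggplot(df, aes(x = factor(.data$frame_id), y = .data$fraction,
                 fill = .data$class)) +
    geom_col() +
    labs(x = "frame", y = "fraction of mitochondria", fill = NULL) +
    theme_minimal()
}

#' Overlay detected spots on one channel
#'
#' @param img A `multichannel_image`.
#' @param spots Spot tibble from [detect_spots()].
#' @param channel Channel to show under the overlay (default `"mCherry"`).
#' @return A ggplot; retained spots are drawn as open circles,
#'   edge-excluded ones as crosses.
#' @export
plot_spots_overlay <- function(img, spots, channel = "mCherry") {
  p <- autoplot(img, channels = channel)
  if (nrow(spots) > 0L) {
    p <- p + geom_point(
      data = spots,
      aes(x = .data$x_um, y = .data$y_um, shape = .data$edge_excluded),
      colour = "red", size = 3, inherit.aes = FALSE
    ) +
      ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 4),
                                  name = "edge excluded")
  }
  p
}
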