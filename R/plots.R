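#' Plot group tract-proportion statistics
#'
#' Bar chart of the mean proportion of CSv streamlines per tract and
#' hemisphere with +/- 1 SEM error bars; untested (zero-variance) cells
#' are drawn without a significance mark.
#'
#' @param object a `csv_group_stats`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot csv_group_stats
#' @export
autoplot.csv_group_stats <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$tract <- factor(df$tract, levels = unique(df$tract))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tract, y = .data$mean_proportion,
                                   fill = .data$hemisphere)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_proportion - .data$sem,
                   ymax = .data$mean_proportion + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::geom_point(
      data = df[df$significant, , drop = FALSE],
      ggplot2::aes(y = .data$mean_proportion + .data$sem + 0.02),
      position = ggplot2::position_dodge(width = 0.8), shape = 8,
      show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "proportion of CSv streamlines",
                  fill = "hemisphere",
                  caption = "error bars: +/- 1 SEM across subjects; *: significant") +
    ggplot2::theme_minimal()
}

#' Plot classification counts
#'
#' @param object a `csv_classification`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot csv_classification
#' @export
autoplot.csv_classification <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$tract, y = .data$n,
                               fill = .data$hemisphere)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "CSv streamlines") +
    ggplot2::theme_minimal()
}

#' Render one slice of a PDD RGB map
#'
#' Axial slice of the colour-coded principal-diffusion-direction map
#' (red = left-right, green = anterior-posterior, blue = superior-inferior,
#' intensity = FA).
#'
#' @param rgb_map 4D [volume_grid()] from [pdd_rgb_map()]
#' @param k 0-based axial slice index
#' @return a ggplot object
#' @export
plot_pdd_slice <- function(rgb_map, k) {
  shp <- dim(rgb_map$data)
  stopifnot(length(shp) == 4, shp[4] == 3, k >= 0, k < shp[3])
  sl <- rgb_map$data[, , k + 1, ]
  df <- expand.grid(i = seq_len(shp[1]), j = seq_len(shp[2]))
  df$col <- grDevices::rgb(sl[cbind(df$i, df$j, 1)],
                           sl[cbind(df$i, df$j, 2)],
                           sl[cbind(df$i, df$j, 3)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$col)) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (voxels)", y = "y (voxels)",
                  title = paste0("PDD map, axial slice k = ", k)) +
    ggplot2::theme_void()
}
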