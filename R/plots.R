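#' Plot condition profiles as mean +/- s.e.m. bars
#'
#' @param object a `condition_profiles` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.condition_profiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region, y = .data$mean_percent,
                                       fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_percent - .data$sem,
                   ymax = .data$mean_percent + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "% of inputs (outside starter regions)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a condition correlation matrix as a heat map
#'
#' @param object a `correlation_matrix`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$condition_a, .data$condition_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.8,
                                  limits = c(min(df$r), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Plot section-wise centers of mass
#'
#' One panel per coordinate, center +/- s.e.m. against the AP bin midpoint.
#'
#' @param object a `com_series`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.com_series <- function(object, ...) {
  df <- object |>
    tidyr::pivot_longer(c("com_x_um", "com_y_um"), names_to = "axis",
                        values_to = "com") |>
    dplyr::mutate(
      sem = dplyr::if_else(.data$axis == "com_x_um", .data$sem_x_um, .data$sem_y_um),
      axis = dplyr::recode(.data$axis, com_x_um = "ML", com_y_um = "DV"),
      z_mid = (.data$z_min_um + .data$z_max_um) / 2)
  ggplot2::ggplot(df, ggplot2::aes(.data$z_mid, .data$com,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$com - .data$sem,
                                          ymax = .data$com + .data$sem),
                             fatten = 1.5) +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = "AP position (um, posterior ->)",
                  y = "centre of mass (um)") +
    ggplot2::theme_minimal()
}

#' Plot one coronal slice of a density volume with patch outlines
#'
#' @param density a `density_volume`.
#' @param z_um AP position of the slice (um); the nearest plane is shown.
#' @param patches optional `patch_set` whose member voxels are outlined.
#' @return A ggplot.
#' @export
plot_density_slice <- function(density, z_um, patches = NULL) {
  k <- um_to_voxel(c(density$origin[1], density$origin[2], z_um), density)[1, 3]
  k <- max(1L, min(dim(density$values)[3], k))
  sl <- density$values[, , k]
  df <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$x_um <- (df$i - 0.5) * density$spacing[1] + density$origin[1]
  df$y_um <- (df$j - 0.5) * density$spacing[2] + density$origin[2]
  df$density <- sl[cbind(df$i, df$j)]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                        fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ML (um)", y = "DV (um, ventral ->)") +
    ggplot2::theme_minimal()
  if (!is.null(patches)) {
    lab <- attr(patches, "labels")$values[, , k]
    sel <- which(lab > 0, arr.ind = TRUE)
    if (nrow(sel)) {
      pd <- tibble::tibble(
        x_um = (sel[, 1] - 0.5) * density$spacing[1] + density$origin[1],
        y_um = (sel[, 2] - 0.5) * density$spacing[2] + density$origin[2],
        patch = factor(lab[sel]))
      p <- p + ggplot2::geom_tile(
        data = pd,
        mapping = ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               colour = .data$patch),
        fill = NA, linewidth = 0.2, inherit.aes = FALSE)
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
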