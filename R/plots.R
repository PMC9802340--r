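#' @importFrom ggplot2 ggplot aes geom_raster geom_path geom_line geom_point
#'   geom_errorbar geom_segment geom_tile geom_crossbar scale_fill_viridis_c
#'   coord_equal labs theme_minimal arrow autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# downsample a frame matrix to at most `max_px` on a side for plotting
frame_to_tibble <- function(frame, pixel_size, max_px = 256) {
  k <- max(1L, ceiling(max(dim(frame)) / max_px))
  ri <- seq(1, nrow(frame), by = k); ci <- seq(1, ncol(frame), by = k)
  sub <- frame[ri, ci]
  tidyr::expand_grid(y_px = ri - 1, x_px = ci - 1) |>
    dplyr::mutate(intensity = as.vector(t(sub)))
}

#' Boundary-overlay montage
#'
#' Draws one frame of the stack with the detected boundaries of all (or
#' selected) frames overlaid — boundaries advancing outward at successive
#' times.
#'
#' @param stack an [image_stack()].
#' @param boundaries tibble `frame`, `x_px`, `y_px` (e.g. the pipeline's
#'   boundary table).
#' @param background_frame 0-based frame to show underneath.
#' @return A ggplot object.
#' @export
plot_boundary_overlay <- function(stack, boundaries, background_frame = 0L) {
  bg <- frame_to_tibble(stack$frames[[background_frame + 1L]],
                        stack$pixel_size)
  ggplot(bg, aes(.data$x_px, .data$y_px)) +
    geom_raster(aes(fill = .data$intensity), show.legend = FALSE) +
    scale_fill_viridis_c(option = "cividis") +
    geom_path(data = boundaries,
              aes(group = .data$frame, colour = .data$frame),
              linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    labs(x = "x (px)", y = "y (px)", colour = "frame",
         title = "Colony boundary over time") +
    theme_minimal()
}

#' Expansion-velocity curve with SEM bars
#'
#' @param summary output of [expansion_summary()].
#' @return A ggplot object.
#' @export
plot_expansion_curve <- function(summary) {
  ggplot(summary, aes(.data$time_min, .data$mean_velocity_mm_per_h)) +
    geom_errorbar(aes(ymin = .data$mean_velocity_mm_per_h -
                        .data$sem_velocity_mm_per_h,
                      ymax = .data$mean_velocity_mm_per_h +
                        .data$sem_velocity_mm_per_h),
                  width = 2) +
    geom_line() + geom_point() +
    labs(x = "time (min)", y = "expansion velocity (mm/h)",
         title = "Colony expansion velocity (mean ± SEM across windows)") +
    theme_minimal()
}

#' Displacement-field quiver plot
#'
#' @param field a `displacement_field` tibble (one frame; filter first if a
#'   `frame` column is present).
#' @param arrow_scale multiplier applied to the vectors for visibility.
#' @return A ggplot object.
#' @export
plot_displacement_field <- function(field, arrow_scale = 5) {
  fd <- dplyr::filter(as_tibble(field), !.data$masked)
  fd$mag <- sqrt(fd$ux_um^2 + fd$uy_um^2)
  ggplot(fd, aes(.data$x_um, .data$y_um)) +
    geom_segment(aes(xend = .data$x_um + arrow_scale * .data$ux_um,
                     yend = .data$y_um + arrow_scale * .data$uy_um,
                     colour = .data$mag),
                 arrow = arrow(length = ggplot2::unit(1.5, "pt"))) +
    scale_fill_viridis_c() +
    ggplot2::scale_colour_viridis_c(name = "|u| (um)") +
    ggplot2::scale_y_reverse() + coord_equal() +
    labs(x = "x (um)", y = "y (um)", title = "Substrate displacement") +
    theme_minimal()
}

#' @export
autoplot.displacement_field <- function(object, ...) {
  if ("frame" %in% names(object))
    object <- dplyr::filter(object, .data$frame == max(.data$frame))
  plot_displacement_field(object, ...)
}

#' Traction-magnitude heat map with direction arrows
#'
#' @param traction a `traction_field` tibble (one frame).
#' @param arrow_scale length scaling of the direction arrows, um/Pa.
#' @return A ggplot object.
#' @export
plot_traction_field <- function(traction, arrow_scale = NULL) {
  tr <- as_tibble(traction)
  if (is.null(arrow_scale)) {
    xs <- sort(unique(tr$x_um))
    sp <- if (length(xs) > 1) diff(xs[1:2]) else 1
    mx <- max(tr$tmag_pa, 1e-12)
    arrow_scale <- sp / mx
  }
  ggplot(tr, aes(.data$x_um, .data$y_um)) +
    geom_tile(aes(fill = .data$tmag_pa)) +
    scale_fill_viridis_c(name = "|tau| (Pa)") +
    geom_segment(aes(xend = .data$x_um + arrow_scale * .data$tx_pa,
                     yend = .data$y_um + arrow_scale * .data$ty_pa),
                 colour = "white", linewidth = 0.2,
                 arrow = arrow(length = ggplot2::unit(1, "pt"))) +
    ggplot2::scale_y_reverse() + coord_equal() +
    labs(x = "x (um)", y = "y (um)", title = "Reconstructed traction") +
    theme_minimal()
}

#' @export
autoplot.traction_field <- function(object, ...) {
  if ("frame" %in% names(object))
    object <- dplyr::filter(object, .data$frame == max(.data$frame))
  plot_traction_field(object, ...)
}

#' Divergence heat map
#' @param object a `divergence_field` tibble (one frame, or latest frame).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.divergence_field <- function(object, ...) {
  if ("frame" %in% names(object))
    object <- dplyr::filter(object, .data$frame == max(.data$frame))
  ggplot(object, aes(.data$x_um, .data$y_um)) +
    geom_tile(aes(fill = .data$div)) +
    ggplot2::scale_fill_gradient2(name = "div u") +
    ggplot2::scale_y_reverse() + coord_equal() +
    labs(x = "x (um)", y = "y (um)",
         title = "Divergence of the displacement field") +
    theme_minimal()
}

#' Stress box–whisker plot per timepoint
#'
#' @param summary output of [stress_summary()].
#' @return A ggplot object.
#' @export
plot_stress_summary <- function(summary) {
  ggplot(summary, aes(x = factor(.data$frame))) +
    geom_errorbar(aes(ymin = .data$whisker_lo_pa, ymax = .data$whisker_hi_pa),
                  width = 0.25) +
    geom_crossbar(aes(y = .data$median_pa, ymin = .data$q1_pa,
                      ymax = .data$q3_pa),
                  width = 0.5, fill = "grey85") +
    labs(x = "timepoint (frame)", y = "|tau| (Pa)",
         title = "Stress-map distribution per timepoint") +
    theme_minimal()
}

#' Render the standard figure panels of a pipeline run
#'
#' Writes one file per available panel type: boundary overlay, expansion
#' curve, displacement quiver, traction map, and stress boxes. Missing or
#' empty upstream results are skipped with a warning.
#'
#' @param results in-memory results list from [run_pipeline()].
#' @param out_dir directory for the figure files.
#' @param stack optional colony [image_stack()] for the boundary overlay.
#' @return Character vector of written figure paths.
#' @export
render_figures <- function(results, out_dir, stack = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  save_fig <- function(p, name) {
    f <- file.path(out_dir, name)
    ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120)
    paths[length(paths) + 1L] <<- f
  }
  if (!is.null(stack) && !is.null(results$boundaries) &&
      nrow(results$boundaries))
    save_fig(plot_boundary_overlay(stack, results$boundaries),
             "fig_boundaries.png")
  if (!is.null(results$expansion_summary) &&
      nrow(results$expansion_summary) > 0) {
    save_fig(plot_expansion_curve(results$expansion_summary),
             "fig_expansion.png")
  } else if (!is.null(results$expansion_summary)) {
    warn("empty velocity table; expansion figure skipped")
  }
  if (!is.null(results$displacement) && nrow(results$displacement))
    save_fig(autoplot(results$displacement), "fig_displacement.png")
  if (!is.null(results$traction) && nrow(results$traction))
    save_fig(autoplot(results$traction), "fig_traction.png")
  if (!is.null(results$stress_summary) && nrow(results$stress_summary))
    save_fig(plot_stress_summary(results$stress_summary), "fig_stress.png")
  paths
}
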