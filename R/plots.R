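#' Plot methods
#'
#' `autoplot()` methods render the package's main result types with ggplot2:
#' a `tissue_mesh` as filled cell polygons (coloured by area), a `vm_sim` as
#' its growth curve with the theoretical predictions overlaid, and a
#' `vm_sweep` as per-friction growth curves.
#'
#' @param object object to plot.
#' @param fill cell fill variable for meshes: `"area"`, `"neighbour_count"`
#'   or `"shape_index"`.
#' @param ... unused.
#' @return a ggplot object.
#' @name autoplot
NULL

#' @rdname autoplot
#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' @rdname autoplot
#' @export
autoplot.tissue_mesh <- function(object,
                                 fill = c("area", "neighbour_count",
                                          "shape_index"), ...) {
  fill <- match.arg(fill)
  geo <- cell_geometry(object)
  polys <- purrr::map2_dfr(seq_along(object$cells), object$cell_id,
    function(i, id) {
      xy <- object$vertices[object$cells[[i]], , drop = FALSE]
      tibble::tibble(cell_id = id, x = xy[, 1], y = xy[, 2])
    })
  polys <- dplyr::left_join(polys, geo, by = "cell_id")
  ggplot2::ggplot(polys, ggplot2::aes(.data$x, .data$y, group = .data$cell_id,
                                      fill = .data[[fill]])) +
    ggplot2::geom_polygon(colour = "grey20", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("tissue at t = %.4g (%d cells)",
                                  object$time, length(object$cells)),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot
#' @export
autoplot.vm_sim <- function(object, ...) {
  gr <- tryCatch(summarise_growth(object), error = function(e) NULL)
  m <- object$metrics
  n0 <- m$n_cells[1]
  if (is.null(gr)) {
    return(ggplot2::ggplot(m, ggplot2::aes(.data$time, .data$n_cells)) +
      ggplot2::geom_point(size = 0.8) + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "time", y = "cells") + ggplot2::theme_minimal())
  }
  preds <- gr |>
    dplyr::filter(is.finite(.data$k), .data$method != "fit") |>
    dplyr::mutate(curve = purrr::map(.data$k, function(k)
      tibble::tibble(time = m$time, n_cells = n0 * exp(k * m$time)))) |>
    tidyr::unnest("curve")
  ggplot2::ggplot(m, ggplot2::aes(.data$time, .data$n_cells)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = preds,
                       ggplot2::aes(colour = .data$method), linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "cells", colour = "prediction") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot
#' @export
autoplot.vm_sweep <- function(object, ...) {
  curves <- object$runs |>
    dplyr::select("gamma", "replicate", "metrics") |>
    tidyr::unnest("metrics")
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$time, .data$n_cells,
                               colour = factor(.data$gamma),
                               group = interaction(.data$gamma,
                                                   .data$replicate))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "cells", colour = "friction") +
    ggplot2::theme_minimal()
}

#' Lewis-law style morphology profile plot
#'
#' Relative mean area and mean shape index per neighbour class.
#'
#' @param mesh a [tissue_mesh()].
#' @return a ggplot object.
#' @export
plot_morphology <- function(mesh) {
  ms <- morphology_summary(mesh) |>
    tidyr::pivot_longer(c("rel_area", "mean_shape_index"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(ms, ggplot2::aes(.data$neighbour_count, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "neighbours n", y = NULL) +
    ggplot2::theme_minimal()
}
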