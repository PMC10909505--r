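#' Dimensionless cell shape index
#'
#' Perimeter over the square root of area, `P / sqrt(A)`: scale-invariant,
#' minimal for a disc (`2 sqrt(pi)` = 3.545), 3.722 for a regular hexagon,
#' 4 for a square; used as a morphology and tissue-rigidity indicator.
#'
#' @param area cell areas (> 0).
#' @param perimeter cell perimeters.
#' @return numeric vector.
#' @export
shape_index <- function(area, perimeter) {
  if (any(area <= 0)) stop("`area` must be positive")
  perimeter / sqrt(area)
}

#' Morphology summary by neighbour class
#'
#' Per polygon class `n` (number of neighbours): frequency, mean area `A_n`,
#' the mean area normalised by the tissue mean (`A_n / Abar`, the
#' Lewis-law-style profile), and the mean shape index `s_n = P_n / sqrt(A_n)`.
#'
#' @param mesh a [tissue_mesh()].
#' @return tibble with columns `neighbour_count`, `n_cells`, `freq`,
#'   `mean_area`, `rel_area`, `mean_shape_index`; tissue-wide mean and sd of
#'   area are attached as attributes `mean_area` and `sd_area`.
#' @export
morphology_summary <- function(mesh) {
  geo <- cell_geometry(mesh)
  abar <- mean(geo$area)
  out <- geo |>
    dplyr::group_by(neighbour_count) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_area = mean(.data$area),
      mean_shape_index = mean(.data$shape_index),
      .groups = "drop") |>
    dplyr::mutate(freq = .data$n_cells / sum(.data$n_cells),
                  rel_area = .data$mean_area / abar) |>
    dplyr::select("neighbour_count", "n_cells", "freq", "mean_area",
                  "rel_area", "mean_shape_index")
  attr(out, "mean_area") <- abar
  attr(out, "sd_area") <- sd(geo$area)
  out
}
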