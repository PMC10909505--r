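#' Turn package objects into tidy tibbles
#'
#' broom-style generics: `tidy()` gives one row per estimated quantity or
#' group, `glance()` a one-row model summary.
#'
#' @param x object to tidy.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.growth_estimate <- function(x, ...) {
  tibble::tibble(term = "k_sto", estimate = x$estimate, std.error = x$se,
                 method = x$method)
}

#' @rdname tidy
#' @export
glance.growth_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, std.error = x$se, method = x$method,
                 n = x$n, flag = x$flag)
}

#' @rdname tidy
#' @export
tidy.vm_sweep <- function(x, ...) {
  x$runs |>
    dplyr::group_by(gamma) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_area = mean(.data$mean_area),
      sd_area = mean(.data$sd_area),
      mean_shape_index = mean(.data$mean_shape_index),
      mean_division_age = mean(.data$mean_division_age, na.rm = TRUE),
      mean_division_area = mean(.data$mean_division_area, na.rm = TRUE),
      k_fit = mean(.data$k_fit, na.rm = TRUE),
      n_cells_final = mean(.data$n_cells),
      t2_per_run = mean(.data$n_t2),
      .groups = "drop")
}

#' @rdname tidy
#' @export
glance.vm_sweep <- function(x, ...) {
  tibble::tibble(
    n_gammas = length(x$gammas),
    n_replicates = x$n_replicates,
    area_reduction_pct = area_reduction_pct(x))
}

#' @rdname tidy
#' @export
tidy.vm_sim <- function(x, ...) summarise_growth(x)

#' @rdname tidy
#' @export
glance.vm_sim <- function(x, ...) {
  tibble::tibble(
    time = x$mesh$time,
    n_cells = length(x$mesh$cells),
    n_divisions = sum(x$events$kind == "division"),
    n_t1 = sum(x$events$kind == "T1"),
    n_t2 = sum(x$events$kind %in% c("T2", "peel")),
    gamma = x$config$mech$gamma)
}
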