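#' Tidy a movement baseline
#'
#' @param x A [build_baseline()] object.
#' @param ... Unused.
#' @return A long tibble with `joint`, `e_s`, `theta_deg`.
#' @method tidy movement_baseline
#' @export
tidy.movement_baseline <- function(x, ...) {
  tidyr::pivot_longer(x$means, -"e_s", names_to = "joint", values_to = "theta_deg") |>
    dplyr::arrange(factor(.data$joint, levels = x$joints), .data$e_s)
}

#' One-row summary of a movement baseline
#'
#' @param x A [build_baseline()] object.
#' @param ... Unused.
#' @return A one-row tibble: joints, mean length, grid, `mu`, `sigma`,
#'   `n_segments`, `degenerate`.
#' @method glance movement_baseline
#' @export
glance.movement_baseline <- function(x, ...) {
  tibble(
    joints = paste(x$joints, collapse = "+"),
    l_bar = x$l_bar, grid_step = x$grid_step, n_grid = nrow(x$means),
    mu = x$mu, sigma = x$sigma, n_segments = x$n_segments,
    degenerate = x$degenerate
  )
}

#' Tidy an experiment report
#'
#' @param x A [run_experiment()] object.
#' @param ... Unused.
#' @return The comparison grid: one row per exercise x variant x subset pair
#'   with group statistics and t / U p-values.
#' @method tidy dtw_experiment
#' @export
tidy.dtw_experiment <- function(x, ...) {
  x$comparisons
}

#' One-row overview of an experiment report
#'
#' @param x A [run_experiment()] object.
#' @param ... Unused.
#' @return A one-row tibble with grid dimensions and degeneracy flags.
#' @method glance dtw_experiment
#' @export
glance.dtw_experiment <- function(x, ...) {
  tibble(
    n_segments = length(unique(x$distances$segment_id)),
    n_exercises = length(unique(x$comparisons$exercise)),
    n_variants = length(unique(x$comparisons$variant)),
    n_comparisons = nrow(x$comparisons),
    n_degenerate = sum(x$degenerate$degenerate),
    seed = x$seed
  )
}
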