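#' Plot a baseline's mean trajectories
#'
#' One panel per joint, angle against elapsed time on the baseline grid.
#'
#' @param object A [build_baseline()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot movement_baseline
#' @export
autoplot.movement_baseline <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$e_s, y = .data$theta_deg)) +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(~ factor(joint, levels = object$joints), scales = "free_y") +
    ggplot2::labs(x = "elapsed time (s)", y = "angle (deg)",
                  title = "Mean normal trajectories") +
    ggplot2::theme_minimal()
}

#' Spaghetti plot of segment trajectories over a baseline
#'
#' Overlays every segment's per-joint trajectory (coloured by label when
#' present) with the baseline mean in black.
#'
#' @param segments A segment tibble with a `trajectory` list column.
#' @param baseline Optional [build_baseline()] object to overlay.
#' @param max_segments Cap on the number of segments drawn.
#' @return A ggplot object.
#' @export
plot_segments <- function(segments, baseline = NULL, max_segments = 200L) {
  take <- head(seq_len(nrow(segments)), max_segments)
  df <- purrr::map_dfr(take, function(i) {
    tr <- tidyr::pivot_longer(segments$trajectory[[i]], -"e_s",
                              names_to = "joint", values_to = "theta_deg")
    tr$segment <- i
    tr$label <- if ("label" %in% names(segments)) segments$label[[i]] else NA_character_
    tr
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$e_s, y = .data$theta_deg,
                                        group = .data$segment,
                                        colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.3) +
    ggplot2::facet_wrap(~joint, scales = "free_y") +
    ggplot2::labs(x = "elapsed time (s)", y = "angle (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_line(
      data = dplyr::mutate(tidy(baseline), segment = -1L, label = NA_character_),
      colour = "black", linewidth = 0.9
    )
  }
  p
}

#' Boxplots of distances, Z-scores and scores by subset
#'
#' Mirrors the distance / Z / score triptych of the evaluation: one row per
#' exercise, columns for the three quantities, boxes per subset, for a chosen
#' feature-set variant.
#'
#' @param object A [run_experiment()] object.
#' @param variant Feature-set variant to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dtw_experiment
#' @export
autoplot.dtw_experiment <- function(object, variant = "single", ...) {
  df <- object$distances[object$distances$variant == variant, ]
  long <- tidyr::pivot_longer(
    df[c("exercise", "subset", "distance", "z", "score")],
    c("distance", "z", "score"),
    names_to = "quantity", values_to = "value"
  )
  long$quantity <- factor(long$quantity, levels = c("distance", "z", "score"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subset, y = .data$value,
                                     fill = .data$subset)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::facet_grid(exercise ~ quantity, scales = "free_y") +
    ggplot2::labs(x = "subset", y = NULL,
                  title = sprintf("%s-angle distances, Z-scores and scores", variant)) +
    ggplot2::theme_minimal()
}

#' Score distribution densities by subset
#'
#' @param experiment A [run_experiment()] object.
#' @param variant Feature-set variant to display.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(experiment, variant = "single") {
  df <- experiment$distances[experiment$distances$variant == variant, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$subset)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::facet_wrap(~exercise, ncol = 1L) +
    ggplot2::labs(x = "score", y = "density") +
    ggplot2::theme_minimal()
}
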