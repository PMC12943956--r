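#' DTW configuration
#'
#' Controls the multi-dimensional DTW used for baseline comparison.
#'
#' @param multivariate_mode `"dependent"` (one DTW over vector-valued
#'   samples, per-step cost aggregated across joints) or `"independent"`
#'   (mean of per-joint DTW distances).
#' @param local_cost Per-step cost: `"euclidean"` (Euclidean norm of the
#'   per-joint angle differences; reduces to absolute difference for one
#'   joint), `"abs"` (sum of absolute differences) or `"squared"` (sum of
#'   squared differences).
#' @param path_normalization `"path_length"` divides the accumulated cost by
#'   the optimal warping-path length, putting distances on the scale of a
#'   per-step angular error in degrees; `"none"` returns the raw accumulated
#'   cost.
#' @param window_band Optional Sakoe-Chiba band half-width (samples);
#'   `NULL` = unconstrained.
#' @param joint_weights Optional named numeric vector of per-joint weights;
#'   default equal weighting.
#' @return A `dtw_config` list.
#' @export
dtw_config <- function(multivariate_mode = c("dependent", "independent"),
                       local_cost = c("euclidean", "abs", "squared"),
                       path_normalization = c("path_length", "none"),
                       window_band = NULL,
                       joint_weights = NULL) {
  multivariate_mode <- rlang::arg_match(multivariate_mode)
  local_cost <- rlang::arg_match(local_cost)
  path_normalization <- rlang::arg_match(path_normalization)
  if (!is.null(window_band)) check_count(window_band, "window_band", min = 0L)
  if (!is.null(joint_weights)) {
    if (!is.numeric(joint_weights) || is.null(names(joint_weights)) ||
        any(joint_weights < 0)) {
      abort_validation("`joint_weights` must be a named non-negative numeric vector.")
    }
  }
  structure(
    list(
      multivariate_mode = multivariate_mode,
      local_cost = local_cost,
      path_normalization = path_normalization,
      window_band = window_band,
      joint_weights = joint_weights
    ),
    class = "dtw_config"
  )
}

cost_type_code <- function(local_cost) {
  match(local_cost, c("euclidean", "abs", "squared")) - 1L
}

dtw_run <- function(a, b, config) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 1L)
  if (!is.matrix(b)) b <- matrix(b, ncol = 1L)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    abort_validation("DTW requires two nonempty sequences.")
  }
  if (ncol(a) != ncol(b)) {
    abort_validation("DTW sequences must have the same number of joints.")
  }
  weights <- rep(1, ncol(a))
  if (!is.null(config$joint_weights) && !is.null(colnames(a))) {
    w <- config$joint_weights[colnames(a)]
    if (anyNA(w)) {
      abort_validation("`joint_weights` must name every joint in the sequences.")
    }
    weights <- as.numeric(w)
  }
  band <- if (is.null(config$window_band)) -1L else as.integer(config$window_band)
  res <- dtw_core(a, b, cost_type_code(config$local_cost), weights, band)
  if (config$path_normalization == "path_length") {
    res$total / res$path_length
  } else {
    res$total
  }
}

#' Dynamic time warping distance between two sequences
#'
#' Classic dynamic-programming DTW with symmetric steps (diagonal, left, up)
#' and accumulated local cost. With `path_normalization = "path_length"` the
#' accumulated cost is divided by the optimal warping-path length (the
#' shortest among cost-optimal paths), giving a per-step angular error.
#'
#' @param a,b Numeric vectors (or single-column matrices).
#' @param config A [dtw_config()].
#' @return Non-negative distance.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 2, 3)) # 0: an exact alignment exists
#' @export
dtw_distance <- function(a, b, config = dtw_config()) {
  dtw_run(as.numeric(a), as.numeric(b), config)
}

segment_matrix <- function(trajectory, joints) {
  missing <- setdiff(joints, names(trajectory))
  if (length(missing) > 0L) {
    abort_validation(sprintf(
      "Segment lacks joint column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  m <- as.matrix(trajectory[joints])
  colnames(m) <- joints
  m
}

#' Multi-dimensional DTW distance of a segment to the baseline
#'
#' In dependent mode a single DTW runs over vector-valued samples whose
#' per-step cost aggregates the per-joint angle differences (equally weighted
#' unless `joint_weights` is set); in independent mode each joint is aligned
#' separately and the per-joint distances are averaged. For a single joint
#' both modes reduce exactly to [dtw_distance()]. The segment is compared at
#' its native sampling against the baseline grid: DTW absorbs tempo, so no
#' pre-resampling is applied.
#'
#' @param segment A segment's wide trajectory tibble (`e_s` + one column per
#'   joint), or a one-row segment tibble with a `trajectory` list column.
#' @param baseline A [build_baseline()] object.
#' @param config A [dtw_config()].
#' @return The distance `d_alpha` (degrees per warping step under the default
#'   normalization).
#' @export
multi_dtw_distance <- function(segment, baseline, config = dtw_config()) {
  trajectory <- segment_trajectory(segment)
  joints <- baseline$joints
  if (!setequal(setdiff(names(trajectory), "e_s"), joints)) {
    abort_validation(sprintf(
      "Segment joints (%s) do not match baseline joints (%s).",
      paste(setdiff(names(trajectory), "e_s"), collapse = ","),
      paste(joints, collapse = ",")
    ))
  }
  a <- segment_matrix(trajectory, joints)
  b <- segment_matrix(baseline$means, joints)
  if (config$multivariate_mode == "dependent" || length(joints) == 1L) {
    dtw_run(a, b, config)
  } else {
    mean(vapply(joints, function(j) {
      dtw_run(a[, j, drop = FALSE], b[, j, drop = FALSE], config)
    }, numeric(1)))
  }
}

segment_trajectory <- function(segment) {
  if (is.data.frame(segment) && "trajectory" %in% names(segment)) {
    if (nrow(segment) != 1L) {
      abort_validation("Pass a single segment (one row) or its trajectory tibble.")
    }
    segment$trajectory[[1L]]
  } else {
    segment
  }
}

#' Z-score of a DTW distance against the normal sample
#'
#' Standardizes a segment's distance by the mean and standard deviation of
#' the normal-sample distances: `z = (d - mu) / sigma`.
#'
#' @param d_alpha Distance(s) to standardize.
#' @param mu A [build_baseline()] object, or the numeric mean distance of the
#'   normal sample.
#' @param sigma Standard deviation of the normal-sample distances (ignored
#'   when `mu` is a baseline object).
#' @return Z-score(s).
#' @examples
#' z_score(1.9940, 2.0120, 1.4640)
#' @export
z_score <- function(d_alpha, mu, sigma = NULL) {
  if (inherits(mu, "movement_baseline")) {
    baseline <- mu
    if (baseline$degenerate) {
      abort_degenerate("Baseline is degenerate (sigma = 0); Z-scores are undefined.")
    }
    mu <- baseline$mu
    sigma <- baseline$sigma
  }
  if (is.null(sigma) || !is.finite(sigma) || sigma <= 0) {
    abort_degenerate("`sigma` must be positive to standardize distances.")
  }
  (d_alpha - mu) / sigma
}

#' Map a Z-score to a 0-100 movement-quality score
#'
#' `S = 100 / max(z, 1)`: a perfect 100 whenever the segment's distance is
#' within one standard deviation of the normal mean (z <= 1), decaying
#' hyperbolically beyond. Continuous at z = 1; range (0, 100].
#'
#' @param z_alpha Z-score(s).
#' @return Score(s) in (0, 100].
#' @examples
#' score_from_z(c(0, 1, 2, 4)) # 100 100 50 25
#' @export
score_from_z <- function(z_alpha) {
  if (any(!is.finite(z_alpha))) {
    abort_validation("`z_alpha` must be finite.")
  }
  100 / pmax(z_alpha, 1)
}

#' Assess one motion segment against a baseline
#'
#' Composes [multi_dtw_distance()], [z_score()] and [score_from_z()].
#'
#' @param segment A segment trajectory tibble or one-row segment tibble.
#' @param baseline A non-degenerate [build_baseline()] object.
#' @param config A [dtw_config()].
#' @return A one-row tibble with `d_alpha`, `z_alpha`, `s_alpha`.
#' @export
assess_segment <- function(segment, baseline, config = dtw_config()) {
  d <- multi_dtw_distance(segment, baseline, config)
  z <- z_score(d, baseline)
  tibble(d_alpha = d, z_alpha = z, s_alpha = score_from_z(z))
}

#' Assess a table of motion segments
#'
#' Adds `d_alpha`, `z_alpha` and `s_alpha` columns to a segment tibble.
#'
#' @param segments A segment tibble with a `trajectory` list column.
#' @param baseline A non-degenerate [build_baseline()] object.
#' @param config A [dtw_config()].
#' @return `segments` with assessment columns appended.
#' @export
assess_segments <- function(segments, baseline, config = dtw_config()) {
  d <- vapply(segments$trajectory, function(tr) {
    multi_dtw_distance(tr, baseline, config)
  }, numeric(1))
  z <- z_score(d, baseline)
  segments$d_alpha <- d
  segments$z_alpha <- z
  segments$s_alpha <- score_from_z(z)
  segments
}
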