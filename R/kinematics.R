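#' Interior joint angle at a vertex point
#'
#' Law-of-cosines angle, in degrees, at `vertex` between the vectors to `p1`
#' and `p2`: with dot product `D` and magnitudes `M1`, `M2`,
#' `J = arccos(D / (M1 * M2)) * 180 / pi`. The cosine argument is clamped to
#' `[-1, 1]` so floating-point collinearity never yields `NaN`. The result is
#' an unsigned interior angle in `[0, 180]`, invariant under translation,
#' rotation and uniform scaling — in particular it does not depend on the
#' image y-axis pointing downward.
#'
#' @param vertex,p1,p2 Numeric length-2 `(x, y)` points, or matrices with two
#'   columns for vectorized evaluation over rows.
#' @return Angle(s) in degrees, in `[0, 180]`.
#' @examples
#' joint_angle(c(0, 0), c(1, 0), c(0, 1)) # 90
#' @export
joint_angle <- function(vertex, p1, p2) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 2L)
  v <- as_mat(vertex); a <- as_mat(p1); b <- as_mat(p2)
  u1 <- a - v
  u2 <- b - v
  m1 <- sqrt(rowSums(u1^2))
  m2 <- sqrt(rowSums(u2^2))
  bad <- which(m1 == 0 | m2 == 0)
  if (length(bad) > 0L) {
    abort_data(sprintf(
      "Degenerate geometry: reference point coincides with the vertex at row %d.", bad[1L]
    ))
  }
  d <- rowSums(u1 * u2)
  acos(pmin(1, pmax(-1, d / (m1 * m2)))) * 180 / pi
}

landmark_xy <- function(stream, name) {
  i <- landmark_index(name)
  cbind(stream[[paste0("x", i)]], stream[[paste0("y", i)]])
}

#' Joint-angle trajectory from a landmark stream
#'
#' Computes the angle of `angle` (an [angle_definition()] row) at every frame.
#' Elapsed time `e_s` is measured from the first frame of the stream.
#'
#' @param stream A landmark stream tibble.
#' @param angle A one-row angle-definition tibble.
#' @return A tibble with columns `e_s` (seconds, starting at 0) and
#'   `theta_deg`.
#' @export
angle_trajectory <- function(stream, angle) {
  stream <- validate_landmark_stream(stream)
  if (nrow(stream) == 0L) {
    abort_data("Cannot compute an angle trajectory from an empty stream.")
  }
  theta <- withCallingHandlers(
    joint_angle(
      landmark_xy(stream, angle$vertex),
      landmark_xy(stream, angle$ref1),
      landmark_xy(stream, angle$ref2)
    ),
    rehabdtw_data_error = function(e) {
      abort_data(sprintf("%s (angle '%s')", conditionMessage(e), angle$label))
    }
  )
  tibble(e_s = stream$time_s - stream$time_s[[1L]], theta_deg = theta)
}

#' Multi-joint angle trajectories from a landmark stream
#'
#' Computes every angle in the exercise specification's feature set, sharing
#' the stream's frame grid.
#'
#' @param stream A landmark stream tibble.
#' @param spec An [default_exercise_spec()] object.
#' @return A wide tibble: `e_s` plus one angle column per joint label,
#'   ordered as in the feature set.
#' @export
angle_trajectories <- function(stream, spec) {
  out <- NULL
  for (i in seq_len(nrow(spec$angles))) {
    def <- spec$angles[i, ]
    traj <- angle_trajectory(stream, def)
    if (is.null(out)) out <- tibble(e_s = traj$e_s)
    out[[def$label]] <- traj$theta_deg
  }
  out
}

moving_average <- function(x, window) {
  # centered moving average; the window shrinks at the edges so the output
  # keeps the input length and time grid
  n <- length(x)
  if (n == 0L || window == 1L) return(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth an angle trajectory with a centered moving average
#'
#' Window size 5 is the operating default. At the boundaries the window is
#' truncated to the available samples, so the output has the same length and
#' elapsed-time grid as the input.
#'
#' @param traj A tibble with `e_s` plus one or more angle columns (e.g.
#'   `theta_deg`, or the wide output of [angle_trajectories()]).
#' @param window Odd positive integer window size.
#' @return The trajectory with every angle column smoothed.
#' @export
smooth_trajectory <- function(traj, window = 5L) {
  window <- check_count(window, "window", min = 1L)
  if (window %% 2L == 0L) {
    abort_validation("`window` must be an odd positive integer.")
  }
  cols <- setdiff(names(traj), "e_s")
  for (col in cols) {
    traj[[col]] <- moving_average(traj[[col]], window)
  }
  traj
}
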