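#' Segmentation parameters
#'
#' Calibration knobs for repetition detection on a smoothed primary-joint
#' angle trajectory. All values are in degrees or seconds and are deliberately
#' config-exposed: the right onset threshold depends on the exercise and the
#' noise level of the pose estimator.
#'
#' @param rest_window_s Duration of the initial window used to estimate the
#'   rest angle (median over the window).
#' @param onset_threshold_deg Deviation from rest that marks the start of a
#'   motion (after the angle has re-armed by coming back below the threshold).
#' @param return_tolerance_deg Closeness to the segment's start angle that
#'   closes a segment on the way down.
#' @param min_segment_s Minimum segment duration; shorter detections are
#'   discarded.
#' @param min_peak_prominence_deg Deviation swing required to confirm a
#'   movement peak (and to confirm a new repetition rising before the previous
#'   one returned). Keeps tremor-scale oscillations from splitting segments.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(rest_window_s = 0.5,
                                onset_threshold_deg = 10,
                                return_tolerance_deg = 5,
                                min_segment_s = 0.3,
                                min_peak_prominence_deg = 15) {
  check_number(rest_window_s, "rest_window_s", min = 0, strict_min = TRUE)
  check_number(onset_threshold_deg, "onset_threshold_deg", min = 0, strict_min = TRUE)
  check_number(return_tolerance_deg, "return_tolerance_deg", min = 0, strict_min = TRUE)
  check_number(min_segment_s, "min_segment_s", min = 0, strict_min = TRUE)
  check_number(min_peak_prominence_deg, "min_peak_prominence_deg", min = 0, strict_min = TRUE)
  structure(
    list(
      rest_window_s = rest_window_s,
      onset_threshold_deg = onset_threshold_deg,
      return_tolerance_deg = return_tolerance_deg,
      min_segment_s = min_segment_s,
      min_peak_prominence_deg = min_peak_prominence_deg
    ),
    class = "segmentation_params"
  )
}

#' Estimate the rest angle of a trajectory
#'
#' Median angle over the initial `rest_window_s` seconds, which the recording
#' protocol guarantees to be quiet (the participant holds the rest pose
#' through the lead-in count).
#'
#' @param traj A tibble with `e_s` and `theta_deg`.
#' @param params A [segmentation_params()] list.
#' @return Rest angle in degrees.
#' @export
estimate_rest_angle <- function(traj, params = segmentation_params()) {
  if (nrow(traj) == 0L || max(traj$e_s) < params$rest_window_s) {
    abort_validation(sprintf(
      "Trajectory spans %.3f s, shorter than rest_window_s = %.3f s.",
      if (nrow(traj) > 0L) max(traj$e_s) else 0, params$rest_window_s
    ))
  }
  median(traj$theta_deg[traj$e_s <= traj$e_s[[1L]] + params$rest_window_s])
}

#' Segment a smoothed angle trajectory into repetitions
#'
#' Detects repetitions on a single (already smoothed) primary-joint angle
#' trajectory. The movement direction — angle increasing (abduction, shoulder
#' flexion raise the shoulder angle) or decreasing (elbow flexion shrinks the
#' elbow angle) — is inferred from the first crossing of the onset threshold.
#' For each repetition:
#' * the start is the first sample whose deviation from rest exceeds
#'   `onset_threshold_deg` after the angle has been back below it;
#' * the trigger is the first sample after the movement peak, where the angle
#'   begins returning toward rest;
#' * the end is the first sample after the trigger whose angle is within
#'   `return_tolerance_deg` of the start angle; if the next repetition begins
#'   before the angle returns, the local extremum between the two (the
#'   reversal point) closes the segment and opens the next one.
#'
#' Segments shorter than `min_segment_s` are discarded. A flat trajectory
#' yields an empty marker table.
#'
#' @param traj A tibble with `e_s` and `theta_deg` (smoothed).
#' @param params A [segmentation_params()] list.
#' @return A tibble of markers: `segment_id`, `start_index`, `trigger_index`,
#'   `end_index` (1-based, segment spans start..end inclusive), `start_s`,
#'   `end_s`, `duration_s`.
#' @export
segment_stream <- function(traj, params = segmentation_params()) {
  rest <- estimate_rest_angle(traj, params)
  theta <- traj$theta_deg
  e <- traj$e_s
  n <- length(theta)
  onset <- params$onset_threshold_deg
  prom <- params$min_peak_prominence_deg
  rtol <- params$return_tolerance_deg

  dev0 <- theta - rest
  first_cross <- which(abs(dev0) > onset)
  empty <- tibble(
    segment_id = integer(0), start_index = integer(0), trigger_index = integer(0),
    end_index = integer(0), start_s = numeric(0), end_s = numeric(0),
    duration_s = numeric(0)
  )
  if (length(first_cross) == 0L) return(empty)
  dir <- sign(dev0[first_cross[[1L]]])
  dev <- dir * dev0

  segs <- list()
  close_segment <- function(start, peak, end) {
    trigger <- min(peak + 1L, end)
    if (start < trigger && trigger <= end && e[end] - e[start] >= params$min_segment_s) {
      segs[[length(segs) + 1L]] <<- c(start = start, trigger = trigger, end = end)
    }
  }

  moving <- FALSE
  armed <- dev[[1L]] <= onset
  start <- peak <- min_idx <- NA_integer_
  peak_dev <- min_after <- NA_real_
  descending <- FALSE

  for (i in seq_len(n)) {
    if (!moving) {
      if (!armed) {
        if (dev[[i]] <= onset) armed <- TRUE
      } else if (dev[[i]] > onset) {
        moving <- TRUE; armed <- FALSE
        start <- i; peak <- i; peak_dev <- dev[[i]]; descending <- FALSE
      }
    } else if (!descending) {
      if (dev[[i]] >= peak_dev) {
        peak <- i; peak_dev <- dev[[i]]
      } else if (peak_dev - dev[[i]] > prom) {
        descending <- TRUE
        min_after <- dev[[i]]; min_idx <- i
      }
    } else {
      if (dev[[i]] < min_after) {
        min_after <- dev[[i]]; min_idx <- i
      }
      if (abs(theta[[i]] - theta[[start]]) <= rtol) {
        close_segment(start, peak, i)
        moving <- FALSE
      } else if (dev[[i]] - min_after > prom) {
        # next repetition rising before the angle returned: split at the
        # reversal point (shared boundary frame)
        close_segment(start, peak, min_idx)
        start <- min_idx; peak <- i; peak_dev <- dev[[i]]; descending <- FALSE
      }
    }
  }
  if (moving && descending) {
    close_segment(start, peak, min_idx)
  }

  if (length(segs) == 0L) return(empty)
  m <- do.call(rbind, segs)
  tibble(
    segment_id = seq_len(nrow(m)),
    start_index = as.integer(m[, "start"]),
    trigger_index = as.integer(m[, "trigger"]),
    end_index = as.integer(m[, "end"]),
    start_s = e[m[, "start"]],
    end_s = e[m[, "end"]],
    duration_s = e[m[, "end"]] - e[m[, "start"]]
  )
}

#' Cut multi-joint angle trajectories into motion segments
#'
#' Markers are computed on the (smoothed) primary angle only; the same frame
#' ranges are then applied to every angle in the feature set, so compensation
#' angles are sliced, not re-segmented.
#'
#' @param angles Wide tibble: `e_s` plus one angle column per joint label;
#'   the primary joint must be the first angle column (as produced by
#'   [angle_trajectories()] or [generate_clip()]).
#' @param spec An [default_exercise_spec()] object (or `NULL` to take the
#'   first angle column as primary).
#' @param params A [segmentation_params()] list.
#' @param smooth Smooth all angle columns (window-`window` centered moving
#'   average) before segmentation and slicing.
#' @param window Smoothing window (odd).
#' @return A tibble with one row per segment: the marker columns of
#'   [segment_stream()], `label` (`NA`), and `trajectory`, a list column of
#'   wide tibbles re-based to `e_s = 0` at the segment start.
#' @export
cut_segments <- function(angles, spec = NULL, params = segmentation_params(),
                         smooth = TRUE, window = 5L) {
  check_flag(smooth, "smooth")
  joint_cols <- setdiff(names(angles), "e_s")
  if (length(joint_cols) == 0L) {
    abort_validation("`angles` has no angle columns.")
  }
  primary <- if (is.null(spec)) joint_cols[[1L]] else primary_joint(spec)
  if (!primary %in% joint_cols) {
    abort_validation(sprintf("Primary joint '%s' not found among angle columns.", primary))
  }
  if (smooth) angles <- smooth_trajectory(angles, window)
  markers <- segment_stream(
    tibble(e_s = angles$e_s, theta_deg = angles[[primary]]), params
  )
  markers$label <- rep(NA_character_, nrow(markers))
  markers$trajectory <- purrr::map2(
    markers$start_index, markers$end_index,
    function(s, t2) {
      sl <- angles[s:t2, c("e_s", joint_cols)]
      sl$e_s <- sl$e_s - sl$e_s[[1L]]
      sl
    }
  )
  markers
}

#' Extract motion segments from a landmark stream
#'
#' Convenience composition: compute the feature-set angle trajectories,
#' smooth, segment on the primary angle and slice all angles.
#'
#' @inheritParams cut_segments
#' @param stream A landmark stream tibble.
#' @param spec An [default_exercise_spec()] object.
#' @return See [cut_segments()].
#' @export
extract_segments <- function(stream, spec, params = segmentation_params(),
                             smooth = TRUE, window = 5L) {
  stream <- validate_landmark_stream(stream)
  if (nrow(stream) == 0L) {
    out <- tibble(
      segment_id = integer(0), start_index = integer(0), trigger_index = integer(0),
      end_index = integer(0), start_s = numeric(0), end_s = numeric(0),
      duration_s = numeric(0), label = character(0), trajectory = list()
    )
    return(out)
  }
  angles <- angle_trajectories(stream, spec)
  cut_segments(angles, spec, params, smooth = smooth, window = window)
}
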