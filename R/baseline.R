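#' Mean trajectory length
#'
#' The length of a trajectory is its maximum elapsed time; the mean length
#' `l_bar` is the arithmetic mean of the input lengths.
#'
#' @param lengths Numeric vector of positive trajectory lengths (seconds).
#' @return Mean length in seconds.
#' @export
mean_length <- function(lengths) {
  if (length(lengths) == 0L) {
    abort_validation("`lengths` must contain at least one trajectory length.")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort_validation("All trajectory lengths must be positive and finite.")
  }
  sum(lengths) / length(lengths)
}

#' Normalize an elapsed time to the mean trajectory length
#'
#' Linearly stretches or compresses a trajectory's time axis so that its end
#' maps to the mean length: `e' = e * l_bar / e_max`. The origin stays fixed.
#'
#' @param e_t Elapsed time(s) in seconds, within `[0, e_max]`.
#' @param e_max Length (maximum elapsed time) of the trajectory of interest.
#' @param l_bar Mean trajectory length.
#' @return Normalized elapsed time(s).
#' @export
normalize_time <- function(e_t, e_max, l_bar) {
  if (!is.finite(e_max) || e_max <= 0) {
    abort_data("Degenerate trajectory: `e_max` must be positive.")
  }
  e_t * l_bar / e_max
}

#' Linearly interpolate an angle on a normalized trajectory
#'
#' Exact at the knots; linear between the bracketing knots.
#'
#' @param t Elapsed time(s) at which to interpolate.
#' @param knots A tibble (or data frame) with columns `e_s` (sorted,
#'   non-decreasing) and `theta_deg`.
#' @return Interpolated angle(s) in degrees.
#' @export
interpolate_angle <- function(t, knots) {
  if (any(t < knots$e_s[[1L]] - 1e-9) || any(t > knots$e_s[[length(knots$e_s)]] + 1e-9)) {
    abort_validation("Interpolation time outside the trajectory's elapsed-time range.")
  }
  if (nrow(knots) == 1L) {
    return(rep(knots$theta_deg[[1L]], length(t)))
  }
  approx(knots$e_s, knots$theta_deg, xout = pmin(pmax(t, knots$e_s[[1L]]), max(knots$e_s)),
         method = "linear", ties = "ordered")$y
}

#' Mean normal trajectory of one joint
#'
#' Each input trajectory is stretched to the mean length `l_bar`, resampled by
#' linear interpolation on a uniform grid spanning `[0, l_bar]`, and the
#' resampled angles are averaged pointwise.
#'
#' @param trajs A list of tibbles, each with columns `e_s` (starting at 0)
#'   and `theta_deg`.
#' @param grid_step Grid spacing in seconds; defaults to the median
#'   inter-sample interval of the inputs.
#' @return A `mean_trajectory` tibble with columns `e_s`, `theta_deg` and
#'   attributes `l_bar` and `grid_step`.
#' @export
mean_trajectory <- function(trajs, grid_step = NULL) {
  if (length(trajs) == 0L) {
    abort_validation("`trajs` must contain at least one trajectory.")
  }
  lengths <- vapply(trajs, function(tr) max(tr$e_s), numeric(1))
  l_bar <- mean_length(lengths)
  if (is.null(grid_step)) {
    steps <- unlist(lapply(trajs, function(tr) diff(tr$e_s)))
    grid_step <- if (length(steps) > 0L) median(steps) else l_bar
  }
  check_number(grid_step, "grid_step", min = 0, strict_min = TRUE)
  grid <- seq(0, l_bar, by = grid_step)
  if (tail(grid, 1L) < l_bar - 1e-12) grid <- c(grid, l_bar)

  resampled <- vapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    normalized <- tibble(
      e_s = normalize_time(tr$e_s, lengths[[i]], l_bar),
      theta_deg = tr$theta_deg
    )
    interpolate_angle(grid, normalized)
  }, numeric(length(grid)))
  resampled <- matrix(resampled, nrow = length(grid))

  structure(
    tibble(e_s = grid, theta_deg = rowMeans(resampled)),
    l_bar = l_bar, grid_step = grid_step,
    class = c("mean_trajectory", class(tibble()))
  )
}

#' Build a normal-movement baseline from motion segments
#'
#' Constructs the per-joint mean normal trajectories (the baseline `B`) from
#' a sample of normal motion segments, then computes the multi-DTW distance of
#' every input segment to `B`; `mu` and `sigma` are the sample mean and
#' sample standard deviation (n-1) of those distances. A baseline whose
#' `sigma` is (numerically) zero is flagged degenerate and cannot standardize
#' new distances.
#'
#' @param segments A segment tibble (see [cut_segments()]) whose `trajectory`
#'   list column holds wide per-joint angle tibbles; all segments must share
#'   the same joint columns.
#' @param grid_step Baseline grid spacing in seconds; default: median
#'   inter-frame interval across the input segments.
#' @param config A [dtw_config()] used for the distance statistics.
#' @param stats_segments Optional held-out segment tibble from which `mu` and
#'   `sigma` are computed instead of the in-sample segments (probes the
#'   in-sample optimism of the distance statistics).
#' @return A `movement_baseline` object: list with `joints`, `means` (wide
#'   tibble `e_s` + one column per joint), `l_bar`, `grid_step`, `mu`,
#'   `sigma`, `n_segments`, `degenerate`, `config`.
#' @export
build_baseline <- function(segments, grid_step = NULL, config = dtw_config(),
                           stats_segments = NULL) {
  if (nrow(segments) == 0L) {
    abort_validation("`segments` must contain at least one motion segment.")
  }
  joints <- setdiff(names(segments$trajectory[[1L]]), "e_s")
  same <- vapply(segments$trajectory, function(tr) {
    identical(setdiff(names(tr), "e_s"), joints)
  }, logical(1))
  if (!all(same)) {
    abort_validation("All segments must share the same feature set (joint columns).")
  }
  if (is.null(grid_step)) {
    steps <- unlist(lapply(segments$trajectory, function(tr) diff(tr$e_s)))
    grid_step <- median(steps)
  }

  means <- NULL
  l_bar <- NA_real_
  for (joint in joints) {
    trajs <- lapply(segments$trajectory, function(tr) {
      tibble(e_s = tr$e_s, theta_deg = tr[[joint]])
    })
    mt <- mean_trajectory(trajs, grid_step = grid_step)
    if (is.null(means)) {
      means <- tibble(e_s = mt$e_s)
      l_bar <- attr(mt, "l_bar")
    }
    means[[joint]] <- mt$theta_deg
  }

  baseline <- structure(
    list(
      joints = joints, means = means, l_bar = l_bar, grid_step = grid_step,
      mu = NA_real_, sigma = NA_real_, n_segments = nrow(segments),
      degenerate = TRUE, config = config
    ),
    class = "movement_baseline"
  )

  stats_from <- if (is.null(stats_segments)) segments else stats_segments
  d <- vapply(stats_from$trajectory, function(tr) {
    multi_dtw_distance(tr, baseline, config)
  }, numeric(1))
  baseline$mu <- mean(d)
  baseline$sigma <- if (length(d) >= 2L) sd(d) else 0
  baseline$degenerate <- !is.finite(baseline$sigma) || baseline$sigma <= 1e-12
  baseline
}

#' @export
print.movement_baseline <- function(x, ...) {
  cat(sprintf(
    "<movement_baseline> %s | l_bar = %.3f s, grid %.4f s (%d points)\n",
    paste(x$joints, collapse = " + "), x$l_bar, x$grid_step, nrow(x$means)
  ))
  cat(sprintf("  distance stats over %d segments: mu = %.4f, sigma = %.4f%s\n",
              x$n_segments, x$mu, x$sigma,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
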