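#' Movement generator parameters
#'
#' Shape and noise parameters for one exercise's synthetic movement. Normal
#' repetitions are smooth raised-cosine pulses spanning the full range of
#' motion in about one second; abnormal repetitions are slow (uniform 2-3 s),
#' reach a reduced fraction of the range, and carry a tremor component, as
#' when moving against an elastic resistance band. The primary joint spans
#' `rest_angle_deg` to `peak_angle_deg` (decreasing for elbow flexion); the
#' secondary and wrist joints move synchronously with smaller excursions.
#'
#' @param exercise Exercise whose joint geometry the defaults describe.
#' @param rest_angle_deg,peak_angle_deg Primary-joint rest and peak angles.
#' @param rep_duration_s Mean normal repetition duration (seconds).
#' @param abnormal_duration_range_s Abnormal repetition duration bounds;
#'   drawn uniformly per repetition.
#' @param rom_fraction Fraction of the normal range of motion reached by
#'   abnormal repetitions.
#' @param tremor_amplitude_deg Tremor sinusoid amplitude on the primary joint
#'   (abnormal repetitions only; other joints scale with their excursion).
#' @param tremor_freq_hz Tremor frequency.
#' @param noise_sd_deg Gaussian sample noise on every angle sample.
#' @param fps Sampling rate (frames per second).
#' @param inter_rep_rest_s Rest plateau between repetitions.
#' @param lead_in_s Lead-in rest before the first repetition (the recording
#'   protocol counts down from three before movement starts).
#' @param hold_s Hold at the final position after the last repetition.
#' @param duration_jitter Relative per-repetition jitter on normal durations
#'   (uniform +/- fraction).
#' @param peak_jitter Relative per-repetition jitter on the peak excursion.
#' @param secondary_rest_deg,secondary_rom_deg Rest angle and signed
#'   excursion of the secondary joint (elbow for shoulder exercises, shoulder
#'   for elbow flexion).
#' @param wrist_rest_deg,wrist_rom_deg Rest angle and signed excursion of the
#'   wrist angle (small relative to the main joints).
#' @param participant_sd_deg Standard deviation of per-participant Gaussian
#'   offsets on rest and peak angles (inter-subject variability).
#' @param posture_lean_sd_deg Standard deviation of a per-clip offset added to
#'   the shoulder rest angle; models sitting-posture lean, which blurs the
#'   normal/abnormal separation for shoulder flexion. Default off.
#' @return A `movement_params` list.
#' @export
movement_params <- function(exercise = c("abduction", "shoulder_flexion", "elbow_flexion"),
                            rest_angle_deg = NULL,
                            peak_angle_deg = NULL,
                            rep_duration_s = 1.0,
                            abnormal_duration_range_s = c(2.0, 3.0),
                            rom_fraction = 0.7,
                            tremor_amplitude_deg = 3.0,
                            tremor_freq_hz = 6,
                            noise_sd_deg = 0.5,
                            fps = 60,
                            inter_rep_rest_s = 0.4,
                            lead_in_s = 3.0,
                            hold_s = 2.0,
                            duration_jitter = 0.10,
                            peak_jitter = 0.05,
                            secondary_rest_deg = NULL,
                            secondary_rom_deg = NULL,
                            wrist_rest_deg = 160,
                            wrist_rom_deg = 10,
                            participant_sd_deg = 5,
                            posture_lean_sd_deg = 0) {
  exercise <- rlang::arg_match(exercise)
  if (exercise == "elbow_flexion") {
    if (is.null(rest_angle_deg)) rest_angle_deg <- 170
    if (is.null(peak_angle_deg)) peak_angle_deg <- 40
    if (is.null(secondary_rest_deg)) secondary_rest_deg <- 15
    if (is.null(secondary_rom_deg)) secondary_rom_deg <- 12
  } else {
    if (is.null(rest_angle_deg)) rest_angle_deg <- 15
    if (is.null(peak_angle_deg)) peak_angle_deg <- 165
    if (is.null(secondary_rest_deg)) secondary_rest_deg <- 170
    if (is.null(secondary_rom_deg)) secondary_rom_deg <- -18
  }
  check_number(rep_duration_s, "rep_duration_s", min = 0, strict_min = TRUE)
  check_number(rom_fraction, "rom_fraction", min = 0, strict_min = TRUE, max = 1)
  check_number(tremor_amplitude_deg, "tremor_amplitude_deg", min = 0)
  check_number(tremor_freq_hz, "tremor_freq_hz", min = 0, strict_min = TRUE)
  check_number(noise_sd_deg, "noise_sd_deg", min = 0)
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  check_number(inter_rep_rest_s, "inter_rep_rest_s", min = 0, strict_min = TRUE)
  if (length(abnormal_duration_range_s) != 2L ||
      abnormal_duration_range_s[[1L]] <= 0 ||
      diff(abnormal_duration_range_s) < 0) {
    abort_validation("`abnormal_duration_range_s` must be increasing positive bounds.")
  }
  structure(
    list(
      exercise = exercise,
      rest_angle_deg = rest_angle_deg, peak_angle_deg = peak_angle_deg,
      rep_duration_s = rep_duration_s,
      abnormal_duration_range_s = abnormal_duration_range_s,
      rom_fraction = rom_fraction,
      tremor_amplitude_deg = tremor_amplitude_deg,
      tremor_freq_hz = tremor_freq_hz,
      noise_sd_deg = noise_sd_deg, fps = fps,
      inter_rep_rest_s = inter_rep_rest_s,
      lead_in_s = lead_in_s, hold_s = hold_s,
      duration_jitter = duration_jitter, peak_jitter = peak_jitter,
      secondary_rest_deg = secondary_rest_deg,
      secondary_rom_deg = secondary_rom_deg,
      wrist_rest_deg = wrist_rest_deg, wrist_rom_deg = wrist_rom_deg,
      participant_sd_deg = participant_sd_deg,
      posture_lean_sd_deg = posture_lean_sd_deg
    ),
    class = "movement_params"
  )
}

#' Study protocol plan
#'
#' Bookkeeping of the recording protocol: participants x exercises x sides,
#' with two normal rounds and one abnormal round per condition and ten
#' repetitions per round. The defaults reproduce the full protocol: 216
#' clips, 2160 segments, 720 per exercise (480 normal + 240 abnormal), 180
#' per participant.
#'
#' @param n_participants Number of participants.
#' @param exercises Character vector of exercises.
#' @param sides Character vector of sides.
#' @param rounds_normal,rounds_abnormal Rounds per exercise x side.
#' @param reps_per_round Repetitions per round (clip).
#' @return A `protocol_plan` list.
#' @export
protocol_plan <- function(n_participants = 12,
                          exercises = c("abduction", "shoulder_flexion", "elbow_flexion"),
                          sides = c("left", "right"),
                          rounds_normal = 2,
                          rounds_abnormal = 1,
                          reps_per_round = 10) {
  structure(
    list(
      n_participants = check_count(n_participants, "n_participants"),
      exercises = exercises, sides = sides,
      rounds_normal = check_count(rounds_normal, "rounds_normal"),
      rounds_abnormal = check_count(rounds_abnormal, "rounds_abnormal"),
      reps_per_round = check_count(reps_per_round, "reps_per_round", min = 0L)
    ),
    class = "protocol_plan"
  )
}

joint_layout <- function(params) {
  primary <- if (params$exercise == "elbow_flexion") "elbow" else "shoulder"
  secondary <- if (primary == "shoulder") "elbow" else "shoulder"
  list(
    labels = c(primary, secondary, "wrist"),
    rest = c(params$rest_angle_deg, params$secondary_rest_deg, params$wrist_rest_deg),
    rom = c(params$peak_angle_deg - params$rest_angle_deg,
            params$secondary_rom_deg, params$wrist_rom_deg)
  )
}

draw_rep_schedule <- function(params, condition, n_reps) {
  if (condition == "normal") {
    dur <- params$rep_duration_s *
      (1 + runif(n_reps, -params$duration_jitter, params$duration_jitter))
  } else {
    dur <- runif(n_reps, params$abnormal_duration_range_s[[1L]],
                 params$abnormal_duration_range_s[[2L]])
  }
  tibble(
    rep = seq_len(n_reps),
    duration_s = dur,
    peak_scale = 1 + runif(n_reps, -params$peak_jitter, params$peak_jitter),
    tremor_phase = runif(n_reps, 0, 2 * pi)
  )
}

pulse_shape <- function(s) (1 - cos(2 * pi * s)) / 2

#' Generate one synthetic repetition profile (primary joint)
#'
#' A raised-cosine angle pulse from rest to peak and back over the repetition
#' duration, with per-repetition jitter on duration and peak, a tremor
#' sinusoid gated by the pulse envelope (abnormal condition only), and
#' Gaussian sample noise. Abnormal repetitions reach `rom_fraction` of the
#' normal excursion and last 2-3 s.
#'
#' @param params A [movement_params()] list.
#' @param condition `"normal"` or `"abnormal"`.
#' @param seed Optional integer seed (otherwise the current RNG state is
#'   consumed).
#' @return A tibble with `e_s` and `theta_deg` spanning one repetition.
#' @export
generate_rep_profile <- function(params, condition = c("normal", "abnormal"),
                                 seed = NULL) {
  condition <- rlang::arg_match(condition)
  run <- function() {
    sched <- draw_rep_schedule(params, condition, 1L)
    dur <- sched$duration_s[[1L]]
    t <- seq(0, dur, by = 1 / params$fps)
    s <- t / dur
    rom <- (params$peak_angle_deg - params$rest_angle_deg) * sched$peak_scale[[1L]]
    if (condition == "abnormal") rom <- rom * params$rom_fraction
    theta <- params$rest_angle_deg + rom * pulse_shape(s)
    if (condition == "abnormal" && params$tremor_amplitude_deg > 0) {
      theta <- theta + params$tremor_amplitude_deg *
        sin(2 * pi * params$tremor_freq_hz * t + sched$tremor_phase[[1L]]) * pulse_shape(s)
    }
    if (params$noise_sd_deg > 0) {
      theta <- theta + rnorm(length(t), 0, params$noise_sd_deg)
    }
    tibble(e_s = t, theta_deg = theta)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

build_clip <- function(params, condition, n_reps, joints) {
  layout <- joint_layout(params)
  use <- switch(joints, primary = 1L, all = seq_along(layout$labels))
  sched <- draw_rep_schedule(params, condition, n_reps)
  rep_starts <- params$lead_in_s +
    cumsum(c(0, head(sched$duration_s, -1L) + params$inter_rep_rest_s))
  total <- if (n_reps > 0L) {
    tail(rep_starts, 1L) + tail(sched$duration_s, 1L) + params$hold_s
  } else {
    params$lead_in_s + params$hold_s
  }
  t <- seq(0, total, by = 1 / params$fps)

  rom_frac <- if (condition == "abnormal") params$rom_fraction else 1
  primary_rom <- abs(layout$rom[[1L]])
  out <- tibble(e_s = t)
  for (j in use) {
    dev <- numeric(length(t))
    for (r in seq_len(n_reps)) {
      inside <- t >= rep_starts[[r]] & t <= rep_starts[[r]] + sched$duration_s[[r]]
      if (!any(inside)) next
      s <- (t[inside] - rep_starts[[r]]) / sched$duration_s[[r]]
      amp <- layout$rom[[j]] * rom_frac * sched$peak_scale[[r]]
      env <- pulse_shape(s)
      dev[inside] <- dev[inside] + amp * env
      if (condition == "abnormal" && params$tremor_amplitude_deg > 0) {
        tremor_amp <- params$tremor_amplitude_deg * abs(layout$rom[[j]]) / primary_rom
        dev[inside] <- dev[inside] + tremor_amp * env *
          sin(2 * pi * params$tremor_freq_hz * t[inside] + sched$tremor_phase[[r]])
      }
    }
    theta <- layout$rest[[j]] + dev
    if (params$noise_sd_deg > 0) {
      theta <- theta + rnorm(length(t), 0, params$noise_sd_deg)
    }
    out[[layout$labels[[j]]]] <- theta
  }
  out
}

#' Generate a synthetic exercise clip
#'
#' Concatenates `n_reps` repetitions separated by rest plateaus, preceded by
#' the lead-in rest and followed by a hold at the final (rest) position —
#' mirroring one recorded round of the study protocol. With
#' `joints = "all"`, the secondary and wrist angles move synchronously with
#' the primary joint at their smaller excursions.
#'
#' @inheritParams generate_rep_profile
#' @param n_reps Number of repetitions.
#' @param joints `"primary"` (one angle column) or `"all"` (primary,
#'   secondary, wrist).
#' @return A wide tibble: `e_s` plus one angle column per generated joint
#'   (primary first).
#' @export
generate_clip <- function(params, condition = c("normal", "abnormal"),
                          n_reps = 10, joints = c("primary", "all"),
                          seed = NULL) {
  condition <- rlang::arg_match(condition)
  joints <- rlang::arg_match(joints)
  n_reps <- check_count(n_reps, "n_reps", min = 0L)
  if (is.null(seed)) {
    build_clip(params, condition, n_reps, joints)
  } else {
    withr::with_seed(seed, build_clip(params, condition, n_reps, joints))
  }
}

default_static_pose <- function() {
  # plausible seated pose for the landmarks the method does not animate
  pose <- matrix(NA_real_, nrow = n_landmarks(), ncol = 2L,
                 dimnames = list(landmark_names, c("x", "y")))
  pose["nose", ] <- c(0.50, 0.18)
  face <- c("left_eye_inner", "left_eye", "left_eye_outer",
            "right_eye_inner", "right_eye", "right_eye_outer",
            "left_ear", "right_ear", "mouth_left", "mouth_right")
  face_x <- c(0.52, 0.54, 0.56, 0.48, 0.46, 0.44, 0.58, 0.42, 0.52, 0.48)
  face_y <- c(0.16, 0.16, 0.16, 0.16, 0.16, 0.16, 0.18, 0.18, 0.21, 0.21)
  pose[face, ] <- cbind(face_x, face_y)
  pose["left_shoulder", ] <- c(0.60, 0.35)
  pose["right_shoulder", ] <- c(0.40, 0.35)
  pose["left_hip", ] <- c(0.58, 0.62)
  pose["right_hip", ] <- c(0.42, 0.62)
  pose["left_elbow", ] <- c(0.64, 0.48)
  pose["right_elbow", ] <- c(0.36, 0.48)
  pose["left_wrist", ] <- c(0.66, 0.58)
  pose["right_wrist", ] <- c(0.34, 0.58)
  pose["left_pinky", ] <- c(0.67, 0.61)
  pose["right_pinky", ] <- c(0.33, 0.61)
  pose["left_index", ] <- c(0.665, 0.615)
  pose["right_index", ] <- c(0.335, 0.615)
  pose["left_thumb", ] <- c(0.655, 0.605)
  pose["right_thumb", ] <- c(0.345, 0.605)
  pose["left_knee", ] <- c(0.60, 0.80)
  pose["right_knee", ] <- c(0.40, 0.80)
  pose["left_ankle", ] <- c(0.60, 0.95)
  pose["right_ankle", ] <- c(0.40, 0.95)
  pose["left_heel", ] <- c(0.60, 0.97)
  pose["right_heel", ] <- c(0.40, 0.97)
  pose["left_foot_index", ] <- c(0.63, 0.97)
  pose["right_foot_index", ] <- c(0.37, 0.97)
  pose
}

rotate_deg <- function(v, deg) {
  rad <- deg * pi / 180
  cbind(v[, 1L] * cos(rad) - v[, 2L] * sin(rad),
        v[, 1L] * sin(rad) + v[, 2L] * cos(rad))
}

#' Forward kinematics: angle trajectories to a landmark stream
#'
#' Drives a planar two-link arm (shoulder anchored above a fixed hip) with
#' the given shoulder/elbow/wrist angle trajectories and emits a full
#' 33-point landmark stream; the remaining landmarks stay static. Joints
#' missing from `traj` are held at their default rest angles. The
#' construction inverts exactly: recomputing the angles from the emitted
#' stream recovers `traj` to floating-point precision.
#'
#' @param traj A wide tibble: `e_s` plus any of `shoulder`, `elbow`, `wrist`
#'   angle columns (degrees).
#' @param spec An [default_exercise_spec()] object (used for the side).
#' @return A landmark stream tibble.
#' @export
angles_to_landmarks <- function(traj, spec) {
  n <- nrow(traj)
  if (n == 0L) abort_validation("`traj` must contain at least one sample.")
  side <- spec$side
  sgn <- if (side == "left") 1 else -1
  get_angle <- function(joint, default) {
    if (joint %in% names(traj)) traj[[joint]] else rep(default, n)
  }
  theta_sh <- get_angle("shoulder", 15)
  theta_el <- get_angle("elbow", 170)
  theta_wr <- get_angle("wrist", 160)

  shoulder <- matrix(rep(c(0.5 + sgn * 0.08, 0.35), each = n), ncol = 2L)
  hip <- matrix(rep(c(0.5 + sgn * 0.08, 0.62), each = n), ncol = 2L)
  upper_len <- 0.13
  fore_len <- 0.11
  hand_len <- 0.04

  u_hip <- (hip - shoulder) / 0.27
  dir_sh <- rotate_deg(u_hip, sgn * theta_sh)
  elbow <- shoulder + upper_len * dir_sh
  u_back <- -dir_sh
  dir_el <- rotate_deg(u_back, sgn * theta_el)
  wrist <- elbow + fore_len * dir_el
  u_elbow <- (elbow - wrist) / fore_len
  dir_wr <- rotate_deg(u_elbow, sgn * theta_wr)
  index <- wrist + hand_len * dir_wr

  pose <- default_static_pose()
  xs <- matrix(rep(pose[, "x"], each = n), nrow = n)
  ys <- matrix(rep(pose[, "y"], each = n), nrow = n)
  set_point <- function(name, pts) {
    j <- landmark_index(name) + 1L
    xs[, j] <<- pts[, 1L]
    ys[, j] <<- pts[, 2L]
  }
  p <- function(lm) paste0(side, "_", lm)
  set_point(p("shoulder"), shoulder)
  set_point(p("hip"), hip)
  set_point(p("elbow"), elbow)
  set_point(p("wrist"), wrist)
  set_point(p("index"), index)

  stream <- tibble(frame = seq_len(n) - 1L, time_s = traj$e_s)
  for (j in seq_len(n_landmarks())) {
    stream[[paste0("x", j - 1L)]] <- xs[, j]
    stream[[paste0("y", j - 1L)]] <- ys[, j]
  }
  validate_landmark_stream(stream)
}

#' Generate the full synthetic study dataset
#'
#' Emulates the recording protocol: every participant performs every exercise
#' on both sides, two normal rounds and one abnormal round, ten repetitions
#' per round. Per-participant Gaussian offsets on rest and peak angles model
#' inter-subject variability; an optional per-clip posture-lean offset on the
#' shoulder rest angle models sitting-posture variation. A single seed makes
#' the whole collection reproducible.
#'
#' @param plan A [protocol_plan()].
#' @param params A named list of [movement_params()], one per exercise in the
#'   plan; defaults to `movement_params(<exercise>)` for each.
#' @param seed Integer seed for the whole dataset.
#' @return A tibble with one row per clip: `participant`, `exercise`,
#'   `side`, `round`, `condition` and `clip` (list column of wide angle
#'   tibbles, all three joints).
#' @export
generate_protocol_dataset <- function(plan = protocol_plan(), params = NULL,
                                      seed = 1L) {
  if (is.null(params)) {
    params <- lapply(stats::setNames(plan$exercises, plan$exercises), movement_params)
  }
  withr::with_seed(seed, {
    offsets <- tibble(
      participant = seq_len(plan$n_participants),
      rest_offset = rnorm(plan$n_participants, 0,
                          params[[1L]]$participant_sd_deg),
      peak_offset = rnorm(plan$n_participants, 0,
                          params[[1L]]$participant_sd_deg)
    )
    rounds <- c(rep("normal", plan$rounds_normal), rep("abnormal", plan$rounds_abnormal))
    grid <- tidyr::expand_grid(
      participant = seq_len(plan$n_participants),
      exercise = plan$exercises,
      side = plan$sides,
      round = seq_along(rounds)
    )
    grid$condition <- rounds[grid$round]
    grid$clip <- purrr::pmap(
      list(grid$participant, grid$exercise, grid$condition),
      function(pid, ex, cond) {
        p <- params[[ex]]
        p$rest_angle_deg <- p$rest_angle_deg + offsets$rest_offset[[pid]]
        p$peak_angle_deg <- p$peak_angle_deg + offsets$peak_offset[[pid]]
        p$secondary_rest_deg <- p$secondary_rest_deg + offsets$rest_offset[[pid]]
        if (p$posture_lean_sd_deg > 0) {
          lean <- rnorm(1, 0, p$posture_lean_sd_deg)
          if (p$exercise == "elbow_flexion") {
            p$secondary_rest_deg <- p$secondary_rest_deg + lean
          } else {
            p$rest_angle_deg <- p$rest_angle_deg + lean
          }
        }
        build_clip(p, cond, plan$reps_per_round, "all")
      }
    )
    grid
  })
}

#' Segment every clip of a synthetic dataset
#'
#' Applies [cut_segments()] to each clip (markers on the primary angle, which
#' is the clip's first angle column) and carries the clip metadata and
#' condition label onto each segment.
#'
#' @param dataset Output of [generate_protocol_dataset()].
#' @param params A [segmentation_params()] list.
#' @param smooth,window Smoothing applied before segmentation.
#' @return A segment tibble: clip metadata columns, `segment_id` (unique
#'   across the dataset), marker columns, `label` and `trajectory`.
#' @export
segment_dataset <- function(dataset, params = segmentation_params(),
                            smooth = TRUE, window = 5L) {
  pieces <- purrr::map(seq_len(nrow(dataset)), function(i) {
    segs <- cut_segments(dataset$clip[[i]], spec = NULL, params = params,
                         smooth = smooth, window = window)
    if (nrow(segs) == 0L) return(NULL)
    segs$label <- dataset$condition[[i]]
    dplyr::bind_cols(
      dataset[rep(i, nrow(segs)), c("participant", "exercise", "side", "round", "condition")],
      segs
    )
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) > 0L) out$segment_id <- seq_len(nrow(out))
  out
}
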