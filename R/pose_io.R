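#' The 33-point whole-body landmark schema
#'
#' Names of the 33 pose landmarks emitted by common webcam pose estimators,
#' in schema order (index 0 to 32). The assessment method uses only the
#' shoulder, elbow, wrist, hip and index-finger points of each side; the
#' remaining points are carried through untouched.
#'
#' @format A character vector of length 33; `landmark_index()` maps a name to
#'   its 0-based position.
#' @export
landmark_names <- c(
  "nose",
  "left_eye_inner", "left_eye", "left_eye_outer",
  "right_eye_inner", "right_eye", "right_eye_outer",
  "left_ear", "right_ear",
  "mouth_left", "mouth_right",
  "left_shoulder", "right_shoulder",
  "left_elbow", "right_elbow",
  "left_wrist", "right_wrist",
  "left_pinky", "right_pinky",
  "left_index", "right_index",
  "left_thumb", "right_thumb",
  "left_hip", "right_hip",
  "left_knee", "right_knee",
  "left_ankle", "right_ankle",
  "left_heel", "right_heel",
  "left_foot_index", "right_foot_index"
)

#' Map a landmark name to its 0-based schema index
#'
#' @param name Character vector of landmark names (see [landmark_names]).
#' @return Integer vector of 0-based indices into the 33-point schema.
#' @examples
#' landmark_index("left_shoulder")
#' @export
landmark_index <- function(name) {
  idx <- match(name, landmark_names)
  if (anyNA(idx)) {
    abort_validation(sprintf(
      "Unknown landmark name(s): %s",
      paste(name[is.na(idx)], collapse = ", ")
    ))
  }
  idx - 1L
}

n_landmarks <- function() length(landmark_names)

stream_coord_cols <- function(visibility = FALSE) {
  i <- seq_len(n_landmarks()) - 1L
  xy <- as.vector(rbind(paste0("x", i), paste0("y", i)))
  if (visibility) c(xy, paste0("v", i)) else xy
}

#' Validate a landmark stream
#'
#' A landmark stream is a tibble with one row per frame: columns `frame`,
#' `time_s`, then interleaved `x0,y0,...,x32,y32` image-normalized coordinates
#' and optional visibilities `v0...v32`. Coordinates slightly outside `[0, 1]`
#' are permitted (estimators emit out-of-frame points).
#'
#' @param stream A data frame of frames.
#' @return The validated stream as a tibble (invisibly classed).
#' @export
validate_landmark_stream <- function(stream) {
  stream <- as_tibble(stream)
  need <- c("frame", "time_s", stream_coord_cols())
  missing <- setdiff(need, names(stream))
  if (length(missing) > 0L) {
    abort_validation(sprintf(
      "Landmark stream is missing %d required column(s), e.g. %s (expected 33 x/y pairs).",
      length(missing), paste(head(missing, 4L), collapse = ", ")
    ))
  }
  coord <- as.matrix(stream[stream_coord_cols()])
  if (nrow(stream) > 0L && !all(is.finite(coord))) {
    abort_data("Landmark stream contains non-finite coordinates.")
  }
  if (nrow(stream) > 1L && any(diff(stream$time_s) <= 0)) {
    abort_data("`time_s` must be strictly increasing across a landmark stream.")
  }
  stream
}

#' Read a landmark stream from CSV or JSON-lines
#'
#' CSV dialect: header `frame,time_s,x0,y0,...,x32,y32` with optional trailing
#' `v0...v32` visibility columns. JSON-lines dialect: one object per line with
#' fields `frame`, `time_s` and `points` (a list of 33 `[x, y]` pairs),
#' optionally `visibility`.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"jsonl"`.
#' @return A tibble landmark stream (see [validate_landmark_stream()]).
#' @export
read_landmark_stream <- function(path, dialect = c("csv", "jsonl")) {
  dialect <- rlang::arg_match(dialect)
  if (!file.exists(path)) {
    abort_data(sprintf("File does not exist: %s", path))
  }
  if (dialect == "csv") {
    stream <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                              progress = FALSE)
    prob <- readr::problems(stream)
    if (nrow(prob) > 0L) {
      abort_data(sprintf("Malformed CSV row at line %d of %s.", prob$row[1L] + 1L, path))
    }
    if (!setequal(names(stream), c("frame", "time_s", stream_coord_cols())) &&
        !setequal(names(stream), c("frame", "time_s", stream_coord_cols(visibility = TRUE)))) {
      abort_validation(sprintf(
        "CSV header of %s does not match the 33-landmark schema (frame,time_s,x0,y0,...,x32,y32[,v0...v32]).",
        path
      ))
    }
    stream <- stream[c("frame", "time_s", intersect(stream_coord_cols(visibility = TRUE), names(stream)))]
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) abort_data(sprintf("Malformed JSON at line %d of %s.", i, path)))
      pts <- obj$points
      if (is.null(pts)) abort_data(sprintf("Missing `points` at line %d of %s.", i, path))
      pts <- as.matrix(pts)
      if (nrow(pts) != n_landmarks() || ncol(pts) != 2L) {
        abort_validation(sprintf("Expected 33 [x, y] points at line %d of %s, got %d x %d.",
                                 i, path, nrow(pts), ncol(pts)))
      }
      row <- c(frame = obj$frame, time_s = obj$time_s,
               stats::setNames(as.vector(t(pts)), stream_coord_cols()))
      if (!is.null(obj$visibility)) {
        row <- c(row, stats::setNames(as.numeric(obj$visibility),
                                      paste0("v", seq_len(n_landmarks()) - 1L)))
      }
      rows[[i]] <- row
    }
    stream <- as_tibble(do.call(rbind, rows))
    if (length(rows) == 0L) {
      stream <- empty_landmark_stream()
    }
  }
  validate_landmark_stream(stream)
}

empty_landmark_stream <- function(visibility = FALSE) {
  cols <- c("frame", "time_s", stream_coord_cols(visibility))
  as_tibble(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
}

#' Write a landmark stream to CSV or JSON-lines
#'
#' Inverse of [read_landmark_stream()]; a write/read round trip reproduces the
#' stream (coordinates to at least six decimal places).
#'
#' @param stream A landmark stream tibble.
#' @param path Output path.
#' @param dialect `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_landmark_stream <- function(stream, path, dialect = c("csv", "jsonl")) {
  dialect <- rlang::arg_match(dialect)
  stream <- validate_landmark_stream(stream)
  if (dialect == "csv") {
    readr::write_csv(stream, path, progress = FALSE)
  } else {
    has_vis <- all(paste0("v", seq_len(n_landmarks()) - 1L) %in% names(stream))
    xs <- as.matrix(stream[paste0("x", seq_len(n_landmarks()) - 1L)])
    ys <- as.matrix(stream[paste0("y", seq_len(n_landmarks()) - 1L)])
    lines <- vapply(seq_len(nrow(stream)), function(i) {
      obj <- list(
        frame = stream$frame[[i]],
        time_s = stream$time_s[[i]],
        points = lapply(seq_len(n_landmarks()), function(j) c(xs[i, j], ys[i, j]))
      )
      if (has_vis) {
        obj$visibility <- as.numeric(stream[i, paste0("v", seq_len(n_landmarks()) - 1L)])
      }
      jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Define a joint angle by vertex and two reference landmarks
#'
#' The angle is measured at `vertex` between the vectors pointing to `ref1`
#' and `ref2` (law of cosines; see [joint_angle()]).
#'
#' @param vertex,ref1,ref2 Landmark names (see [landmark_names]).
#' @param label Short joint label, one of `"shoulder"`, `"elbow"`, `"wrist"`.
#' @return A one-row tibble with columns `label`, `vertex`, `ref1`, `ref2`.
#' @export
angle_definition <- function(vertex, ref1, ref2, label = c("shoulder", "elbow", "wrist")) {
  label <- rlang::arg_match(label)
  landmark_index(c(vertex, ref1, ref2))
  if (vertex == ref1 || vertex == ref2 || ref1 == ref2) {
    abort_validation("`vertex`, `ref1` and `ref2` must be three distinct landmarks.")
  }
  tibble(label = label, vertex = vertex, ref1 = ref1, ref2 = ref2)
}

#' Default exercise specification
#'
#' Builds the exercise configuration used throughout the pipeline. The primary
#' angle drives motion detection and segmentation; the feature set lists the
#' angles used for assessment:
#' * abduction / shoulder flexion: primary = shoulder angle (vertex shoulder,
#'   references elbow and hip);
#' * elbow flexion: primary = elbow angle (vertex elbow, references shoulder
#'   and wrist);
#' * `dual` adds the other of shoulder/elbow; `triple` adds the wrist angle
#'   (vertex wrist, references index finger and elbow).
#'
#' @param exercise `"abduction"`, `"shoulder_flexion"` or `"elbow_flexion"`.
#' @param side `"left"` or `"right"`.
#' @param feature_set_kind `"single"`, `"dual"` or `"triple"`.
#' @return An `exercise_spec` object: a list with `exercise`, `side`,
#'   `feature_set_kind`, `camera_orientation`, and `angles` (a tibble of
#'   angle definitions, primary first).
#' @examples
#' default_exercise_spec("elbow_flexion", "left", "single")
#' @export
default_exercise_spec <- function(exercise = c("abduction", "shoulder_flexion", "elbow_flexion"),
                                  side = c("left", "right"),
                                  feature_set_kind = c("single", "dual", "triple")) {
  exercise <- rlang::arg_match(exercise)
  side <- rlang::arg_match(side)
  feature_set_kind <- rlang::arg_match(feature_set_kind)
  p <- function(lm) paste0(side, "_", lm)

  shoulder <- angle_definition(p("shoulder"), p("elbow"), p("hip"), label = "shoulder")
  elbow <- angle_definition(p("elbow"), p("shoulder"), p("wrist"), label = "elbow")
  wrist <- angle_definition(p("wrist"), p("index"), p("elbow"), label = "wrist")

  angles <- if (exercise == "elbow_flexion") {
    switch(feature_set_kind,
      single = elbow,
      dual = dplyr::bind_rows(elbow, shoulder),
      triple = dplyr::bind_rows(elbow, shoulder, wrist)
    )
  } else {
    switch(feature_set_kind,
      single = shoulder,
      dual = dplyr::bind_rows(shoulder, elbow),
      triple = dplyr::bind_rows(shoulder, elbow, wrist)
    )
  }

  structure(
    list(
      exercise = exercise,
      side = side,
      feature_set_kind = feature_set_kind,
      camera_orientation = if (exercise == "abduction") "front" else "side",
      angles = angles
    ),
    class = "exercise_spec"
  )
}

#' @export
print.exercise_spec <- function(x, ...) {
  cat(sprintf("<exercise_spec> %s, %s side, %s-angle (%s camera)\n",
              x$exercise, x$side, x$feature_set_kind, x$camera_orientation))
  cat(sprintf("  feature set: %s\n", paste(x$angles$label, collapse = " + ")))
  invisible(x)
}

primary_joint <- function(spec) spec$angles$label[[1L]]
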