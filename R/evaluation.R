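#' Split labeled segments into Baseline / Normal-test / Abnormal subsets
#'
#' Normal segments are split half/half into subsets B (baseline construction)
#' and N (normal test) at random, stratified per participant and exercise so
#' every participant contributes equally to both; all abnormal segments go to
#' subset A. Deterministic for a given seed.
#'
#' @param segments A segment tibble with `participant`, `exercise` and
#'   `label` (`"normal"` / `"abnormal"`) columns (see [segment_dataset()]).
#' @param seed Integer seed.
#' @return `segments` with a `subset` column (`"B"`, `"N"` or `"A"`).
#' @export
split_subsets <- function(segments, seed = 0L) {
  need <- c("participant", "exercise", "label")
  missing <- setdiff(need, names(segments))
  if (length(missing) > 0L) {
    abort_validation(sprintf("`segments` lacks column(s): %s.",
                             paste(missing, collapse = ", ")))
  }
  subset <- rep(NA_character_, nrow(segments))
  subset[segments$label == "abnormal"] <- "A"
  withr::with_seed(seed, {
    strata <- split(
      which(segments$label == "normal"),
      interaction(segments$participant[segments$label == "normal"],
                  segments$exercise[segments$label == "normal"], drop = TRUE)
    )
    for (idx in strata) {
      n <- length(idx)
      if (n %% 2L != 0L) {
        abort_validation(
          "Each participant must contribute an even number of normal segments per exercise."
        )
      }
      b <- sample(idx, n %/% 2L)
      subset[b] <- "B"
      subset[setdiff(idx, b)] <- "N"
    }
  })
  segments$subset <- subset
  segments
}

#' Joints used by a feature-set variant
#'
#' @param exercise Exercise name.
#' @param variant One of `"triple"`, `"dual"`, `"single"`, `"shoulder"`,
#'   `"elbow"`, `"wrist"` (the last three are single individual angles).
#' @return Character vector of joint labels, primary joint first where
#'   applicable.
#' @export
variant_joints <- function(exercise,
                           variant = c("triple", "dual", "single",
                                       "shoulder", "elbow", "wrist")) {
  variant <- rlang::arg_match(variant)
  primary <- if (exercise == "elbow_flexion") "elbow" else "shoulder"
  other <- if (primary == "shoulder") "elbow" else "shoulder"
  switch(variant,
    single = primary,
    dual = c(primary, other),
    triple = c(primary, other, "wrist"),
    shoulder = "shoulder",
    elbow = "elbow",
    wrist = "wrist"
  )
}

select_joints <- function(trajectory, joints) {
  trajectory[c("e_s", joints)]
}

#' Per-segment distances to a subset-B baseline
#'
#' Builds the baseline from the subset-B segments of one exercise using the
#' requested feature-set variant, then computes the multi-DTW distance of
#' every segment (B, N and A) to it, along with Z-scores and scores when the
#' baseline is not degenerate.
#'
#' @param segments Segment tibble for a single exercise, with a `subset`
#'   column (see [split_subsets()]).
#' @param variant Feature-set variant (see [variant_joints()]).
#' @param config A [dtw_config()].
#' @param grid_step Optional baseline grid step (seconds).
#' @return A tibble with one row per segment: metadata, `subset`,
#'   `distance`, `z`, `score`, plus attributes `baseline` and `degenerate`.
#' @export
distance_table <- function(segments, variant = "single", config = dtw_config(),
                           grid_step = NULL) {
  exercise <- unique(segments$exercise)
  if (length(exercise) != 1L) {
    abort_validation("`segments` must contain exactly one exercise.")
  }
  if (!"subset" %in% names(segments)) {
    abort_validation("`segments` must carry a `subset` column; see split_subsets().")
  }
  joints <- variant_joints(exercise, variant)
  seg <- segments
  seg$trajectory <- lapply(seg$trajectory, select_joints, joints = joints)
  b_seg <- seg[seg$subset == "B", ]
  if (nrow(b_seg) == 0L) {
    abort_validation("Subset B is empty; cannot build a baseline.")
  }
  baseline <- build_baseline(b_seg, grid_step = grid_step, config = config)
  d <- vapply(seg$trajectory, function(tr) {
    multi_dtw_distance(tr, baseline, config)
  }, numeric(1))
  keep <- intersect(
    c("segment_id", "participant", "exercise", "side", "round", "label", "subset"),
    names(seg)
  )
  out <- seg[keep]
  out$variant <- variant
  out$distance <- d
  if (!baseline$degenerate) {
    out$z <- z_score(d, baseline)
    out$score <- score_from_z(out$z)
  } else {
    out$z <- NA_real_
    out$score <- NA_real_
  }
  attr(out, "baseline") <- baseline
  attr(out, "degenerate") <- baseline$degenerate
  out
}

#' Compare distance distributions between two subsets
#'
#' Two-sided independent-samples t-test (pooled variance by default, Welch
#' behind the `welch` flag) and two-sided Mann-Whitney U-test (exact p-value
#' for small tie-free samples, normal approximation with tie correction
#' otherwise), applied to the per-segment distances of two subsets.
#'
#' @param distances A [distance_table()] tibble (columns `subset`,
#'   `distance`).
#' @param pair Length-2 character vector of subset codes, e.g. `c("N", "B")`.
#' @param welch Use the Welch (unequal-variance) t-test.
#' @return A one-row tibble: `group1`, `group2`, sizes, means, SDs,
#'   `t_stat`, `t_p`, `u_stat`, `u_p`.
#' @export
compare_subsets <- function(distances, pair = c("N", "B"), welch = FALSE) {
  check_flag(welch, "welch")
  x <- distances$distance[distances$subset == pair[[1L]]]
  y <- distances$distance[distances$subset == pair[[2L]]]
  if (length(x) < 2L || length(y) < 2L) {
    abort_validation("Both groups must contain at least two segments.")
  }
  tt <- tryCatch(t.test(x, y, var.equal = !welch),
                 error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  ut <- tryCatch(suppressWarnings(wilcox.test(x, y)),
                 error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  tibble(
    group1 = pair[[1L]], group2 = pair[[2L]],
    n1 = length(x), n2 = length(y),
    mean1 = mean(x), sd1 = sd(x),
    mean2 = mean(y), sd2 = sd(y),
    t_stat = unname(tt$statistic), t_p = tt$p.value,
    u_stat = unname(ut$statistic), u_p = ut$p.value
  )
}

#' Run the full evaluation experiment
#'
#' Reproduces the analysis pipeline on a labeled segment dataset: a
#' per-participant subset split, distance tables for every exercise and
#' feature-set variant, t- and U-test comparisons for the three subset pairs,
#' Z-score / score summaries per subset, and the closest-k abnormal analysis
#' (the k abnormal segments nearest the baseline under the single-angle
#' variant).
#'
#' @param segments Labeled segment tibble for all exercises (see
#'   [segment_dataset()]).
#' @param config A [dtw_config()].
#' @param seed Seed for the subset split.
#' @param variants Feature-set variants to evaluate.
#' @param k_closest k for the closest-abnormal analysis.
#' @param welch Use Welch t-tests.
#' @param grid_step Optional baseline grid step.
#' @return A `dtw_experiment` object: list with `comparisons`, `distances`,
#'   `score_summary`, `closest_abnormal`, `degenerate` flags and the
#'   configuration. `tidy()` returns the comparison grid; `glance()` a
#'   one-row overview; `autoplot()` distance boxplots.
#' @export
run_experiment <- function(segments, config = dtw_config(), seed = 0L,
                           variants = c("triple", "dual", "single",
                                        "shoulder", "elbow", "wrist"),
                           k_closest = 10L, welch = FALSE, grid_step = NULL) {
  assigned <- split_subsets(segments, seed = seed)
  exercises <- unique(assigned$exercise)
  pairs <- list(c("N", "B"), c("N", "A"), c("B", "A"))

  distances <- list()
  comparisons <- list()
  degenerate <- list()
  for (ex in exercises) {
    seg_ex <- assigned[assigned$exercise == ex, ]
    for (v in variants) {
      dt <- distance_table(seg_ex, variant = v, config = config,
                           grid_step = grid_step)
      distances[[paste(ex, v)]] <- dt
      degenerate[[paste(ex, v)]] <- tibble(
        exercise = ex, variant = v, degenerate = attr(dt, "degenerate")
      )
      for (pr in pairs) {
        cmp <- compare_subsets(dt, pr, welch = welch)
        cmp <- dplyr::bind_cols(tibble(exercise = ex, variant = v), cmp)
        comparisons[[paste(ex, v, paste(pr, collapse = "-"))]] <- cmp
      }
    }
  }
  distances <- dplyr::bind_rows(distances)
  comparisons <- dplyr::bind_rows(comparisons)
  degenerate <- dplyr::bind_rows(degenerate)

  score_summary <- distances |>
    dplyr::group_by(.data$exercise, .data$variant, .data$subset) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_distance = mean(.data$distance), sd_distance = sd(.data$distance),
      mean_z = mean(.data$z), sd_z = sd(.data$z),
      mean_score = mean(.data$score), sd_score = sd(.data$score),
      q1_score = quantile(.data$score, 0.25, names = FALSE, na.rm = TRUE),
      median_score = median(.data$score, na.rm = TRUE),
      q3_score = quantile(.data$score, 0.75, names = FALSE, na.rm = TRUE),
      .groups = "drop"
    )

  closest_abnormal <- distances |>
    dplyr::filter(.data$variant == "single", .data$subset == "A") |>
    dplyr::group_by(.data$exercise) |>
    dplyr::slice_min(.data$distance, n = k_closest, with_ties = FALSE) |>
    dplyr::summarise(
      k = dplyr::n(),
      mean_distance = mean(.data$distance), sd_distance = sd(.data$distance),
      mean_z = mean(.data$z), sd_z = sd(.data$z),
      mean_score = mean(.data$score), sd_score = sd(.data$score),
      .groups = "drop"
    )

  structure(
    list(
      comparisons = comparisons,
      distances = distances,
      score_summary = score_summary,
      closest_abnormal = closest_abnormal,
      degenerate = degenerate,
      seed = seed, config = config, k_closest = k_closest
    ),
    class = "dtw_experiment"
  )
}

#' @export
print.dtw_experiment <- function(x, ...) {
  cat(sprintf(
    "<dtw_experiment> %d segments | %d exercises x %d variants x 3 subset pairs\n",
    length(unique(x$distances$segment_id)),
    length(unique(x$comparisons$exercise)),
    length(unique(x$comparisons$variant))
  ))
  if (any(x$degenerate$degenerate)) {
    cat("  note: degenerate baseline(s) flagged; Z-scores unavailable there\n")
  }
  single <- x$comparisons[x$comparisons$variant == "single", ]
  cat("  single-angle p-values (t / U):\n")
  for (i in seq_len(nrow(single))) {
    cat(sprintf("    %-16s %s-%s: %.4f / %.4f\n", single$exercise[[i]],
                single$group1[[i]], single$group2[[i]],
                single$t_p[[i]], single$u_p[[i]]))
  }
  invisible(x)
}
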