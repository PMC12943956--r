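# A small labeled segment table with controllable trajectories; distances to
# the baseline are then fully predictable.
fake_segments <- function(n_participants = 4, normal_per = 6, abnormal_per = 3,
                          exercise = "abduction", jitter = 0, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    base <- tibble::tibble(e_s = seq(0, 1, by = 0.1))
    for (pid in seq_len(n_participants)) {
      for (i in seq_len(normal_per + abnormal_per)) {
        label <- if (i <= normal_per) "normal" else "abnormal"
        shift <- if (label == "normal") 0 else 25
        tr <- base
        tr$shoulder <- 15 + 70 * (1 - cos(2 * pi * base$e_s)) / 2 + shift +
          rnorm(nrow(base), 0, jitter)
        tr$elbow <- 170 - 10 * (1 - cos(2 * pi * base$e_s)) / 2 +
          rnorm(nrow(base), 0, jitter)
        tr$wrist <- 160 + rnorm(nrow(base), 0, jitter)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          participant = pid, exercise = exercise, side = "left",
          round = 1L, label = label, trajectory = list(tr)
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    out$segment_id <- seq_len(nrow(out))
    out
  })
}

test_that("subset splits are balanced, stratified and seed-deterministic", {
  segs <- fake_segments(n_participants = 4, normal_per = 6, abnormal_per = 3)
  a1 <- split_subsets(segs, seed = 3)
  expect_equal(sum(a1$subset == "B"), sum(a1$subset == "N"))
  expect_equal(sum(a1$subset == "A"), sum(segs$label == "abnormal"))
  expect_true(all(a1$subset[a1$label == "abnormal"] == "A"))
  per <- table(a1$participant, a1$subset)
  expect_true(all(per[, "B"] == per[, "N"]))

  expect_identical(split_subsets(segs, seed = 3)$subset, a1$subset)
  different <- vapply(1:10, function(s) {
    !identical(split_subsets(segs, seed = 100 + s)$subset,
               split_subsets(segs, seed = 200 + s)$subset)
  }, logical(1))
  expect_true(all(different))

  odd <- segs[-1, ]
  expect_error(split_subsets(odd, seed = 1), class = "rehabdtw_validation_error")
})

test_that("identical baseline segments give zero distances and a degenerate flag", {
  segs <- split_subsets(fake_segments(jitter = 0), seed = 1)
  dt <- distance_table(segs, "single")
  expect_true(all(dt$distance[dt$subset == "B"] < 1e-9))
  expect_true(attr(dt, "degenerate"))
  expect_true(all(is.na(dt$z)))
})

test_that("one-joint variants coincide across single and multivariate paths", {
  segs <- split_subsets(fake_segments(jitter = 0.8, seed = 5), seed = 2)
  d_single <- distance_table(segs, "single")$distance
  d_named <- distance_table(segs, "shoulder")$distance # same joint for abduction
  expect_identical(d_single, d_named)
  d_indep <- distance_table(segs, "single",
                            config = dtw_config(multivariate_mode = "independent"))
  expect_identical(d_single, d_indep$distance)
})

test_that("variant joints follow the feature-set definitions", {
  expect_equal(variant_joints("abduction", "single"), "shoulder")
  expect_equal(variant_joints("elbow_flexion", "single"), "elbow")
  expect_equal(variant_joints("elbow_flexion", "dual"), c("elbow", "shoulder"))
  expect_equal(variant_joints("shoulder_flexion", "triple"),
               c("shoulder", "elbow", "wrist"))
  expect_equal(variant_joints("abduction", "wrist"), "wrist")
})

test_that("identical groups give a null t-test and same-distribution p-values are calibrated", {
  withr::with_seed(13, {
    vals <- rnorm(30, 5, 1)
    distances <- tibble::tibble(
      subset = rep(c("N", "B"), each = 30),
      distance = c(vals, vals)
    )
    cmp <- compare_subsets(distances, c("N", "B"))
    expect_equal(cmp$t_stat, 0)
    expect_equal(cmp$t_p, 1)

    # groups drawn from one distribution rarely reject
    rejections <- vapply(1:50, function(s) {
      withr::with_seed(s, {
        d <- tibble::tibble(subset = rep(c("N", "B"), each = 240),
                            distance = rnorm(480, 2, 0.5))
        compare_subsets(d, c("N", "B"))$t_p < 0.05
      })
    }, logical(1))
    expect_gte(mean(!rejections), 0.9)

    # clearly separated groups always reject
    d2 <- tibble::tibble(subset = rep(c("N", "A"), each = 240),
                         distance = c(rnorm(240, 1, 0.4), rnorm(240, 8, 3)))
    cmp2 <- compare_subsets(d2, c("N", "A"))
    expect_lt(cmp2$t_p, 0.001)
    expect_lt(cmp2$u_p, 0.001)
  })
  small <- tibble::tibble(subset = c("N", "B"), distance = c(1, 2))
  expect_error(compare_subsets(small, c("N", "B")),
               class = "rehabdtw_validation_error")
})

test_that("the U-test agrees with exhaustive permutation enumeration", {
  withr::with_seed(29, {
    for (case in 1:25) {
      n1 <- sample(3:7, 1)
      n2 <- sample(3:7, 1)
      x <- runif(n1, 0, 10)
      y <- runif(n2, 0, 10)
      d <- tibble::tibble(subset = c(rep("N", n1), rep("B", n2)),
                          distance = c(x, y))
      cmp <- compare_subsets(d, c("N", "B"))
      expect_equal(cmp$u_p, u_perm_p(x, y), tolerance = 1e-12)
    }
  })
})

test_that("the experiment grid is complete with sane Z-score identities", {
  plan <- protocol_plan(n_participants = 2, reps_per_round = 5)
  ds <- generate_protocol_dataset(plan, seed = 11)
  segs <- segment_dataset(ds)
  exp <- run_experiment(segs, seed = 1, k_closest = 5)
  expect_equal(nrow(exp$comparisons), 3 * 6 * 3)
  expect_true(all(!is.na(exp$comparisons$t_p)))
  expect_true(all(exp$comparisons$t_p >= 0 & exp$comparisons$t_p <= 1))
  expect_true(all(exp$comparisons$u_p >= 0 & exp$comparisons$u_p <= 1))
  # in-sample standardization: subset B has mean 0, SD 1 per exercise/variant
  bz <- exp$distances[exp$distances$subset == "B", ]
  stats <- dplyr::summarise(dplyr::group_by(bz, exercise, variant),
                            mz = mean(z), sz = sd(z), .groups = "drop")
  expect_true(all(abs(stats$mz) < 1e-9))
  expect_true(all(abs(stats$sz - 1) < 1e-9))
  # closest-k abnormal summary layout
  expect_equal(nrow(exp$closest_abnormal), 3L)
  expect_named(exp$closest_abnormal,
               c("exercise", "k", "mean_distance", "sd_distance",
                 "mean_z", "sd_z", "mean_score", "sd_score"))
  expect_true(all(exp$closest_abnormal$k == 5))
  # tidy/glance accessors
  expect_equal(nrow(tidy(exp)), 54L)
  expect_equal(glance(exp)$n_degenerate, 0L)
})

test_that("a dataset of identical segments is reported, not crashed on", {
  segs <- fake_segments(jitter = 0)
  exp <- run_experiment(segs, seed = 1, variants = "single", k_closest = 3)
  expect_true(any(exp$degenerate$degenerate))
  expect_true(all(is.na(exp$distances$z[exp$distances$subset == "B"])))
})
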