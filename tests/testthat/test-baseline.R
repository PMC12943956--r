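test_that("mean length is plain arithmetic over positive lengths", {
  expect_equal(mean_length(c(1, 2, 3)), 2)
  expect_equal(mean_length(0.8), 0.8)
  withr::with_seed(41, {
    lens <- runif(100, 0.1, 5)
    expect_equal(mean_length(lens), sum(lens) / 100, tolerance = 1e-12)
  })
  expect_error(mean_length(numeric(0)), class = "rehabdtw_validation_error")
  expect_error(mean_length(c(1, -1)), class = "rehabdtw_validation_error")
})

test_that("time normalization maps endpoints to 0 and the mean length", {
  expect_equal(normalize_time(0, 2, 3), 0)
  expect_equal(normalize_time(2, 2, 3), 3)
  expect_equal(normalize_time(1, 2, 3), 1.5)
  expect_error(normalize_time(1, 0, 3), class = "rehabdtw_data_error")
})

test_that("interpolation is exact at knots and linear in between", {
  knots <- tibble::tibble(e_s = c(0, 2), theta_deg = c(10, 20))
  expect_equal(interpolate_angle(0, knots), 10)
  expect_equal(interpolate_angle(1, knots), 15)
  expect_equal(interpolate_angle(2, knots), 20)
  expect_error(interpolate_angle(3, knots), class = "rehabdtw_validation_error")
})

test_that("the mean of identical trajectories is the trajectory itself", {
  traj <- tibble::tibble(e_s = seq(0, 1, by = 0.1),
                         theta_deg = 15 + 50 * sin(seq(0, pi, length.out = 11)))
  mt <- mean_trajectory(rep(list(traj), 5), grid_step = 0.1)
  expect_equal(mt$e_s, traj$e_s, tolerance = 1e-12)
  expect_equal(mt$theta_deg, traj$theta_deg, tolerance = 1e-9)
})

test_that("two constant trajectories average to the closed-form mean", {
  a <- tibble::tibble(e_s = seq(0, 2, by = 0.5), theta_deg = 10)
  b <- tibble::tibble(e_s = seq(0, 4, by = 0.5), theta_deg = 20)
  mt <- mean_trajectory(list(a, b), grid_step = 0.5)
  expect_equal(attr(mt, "l_bar"), 3)
  expect_equal(max(mt$e_s), 3)
  expect_equal(mt$theta_deg, rep(15, nrow(mt)))
})

test_that("mean trajectory is permutation-invariant and within input bounds", {
  withr::with_seed(17, {
    trajs <- lapply(1:6, function(i) {
      n <- sample(8:20, 1)
      tibble::tibble(e_s = seq(0, runif(1, 0.5, 2), length.out = n),
                     theta_deg = runif(n, 10, 160))
    })
    mt <- mean_trajectory(trajs, grid_step = 0.05)
    perm <- mean_trajectory(sample(trajs), grid_step = 0.05)
    expect_equal(mt, perm)
    expect_equal(attr(mt, "l_bar"),
                 mean(vapply(trajs, function(tr) max(tr$e_s), numeric(1))))
    # pointwise within [min, max] of normalized inputs at each grid point
    l_bar <- attr(mt, "l_bar")
    vals <- sapply(trajs, function(tr) {
      interpolate_angle(mt$e_s, tibble::tibble(
        e_s = normalize_time(tr$e_s, max(tr$e_s), l_bar), theta_deg = tr$theta_deg
      ))
    })
    expect_true(all(mt$theta_deg >= apply(vals, 1, min) - 1e-9))
    expect_true(all(mt$theta_deg <= apply(vals, 1, max) + 1e-9))
  })
})

make_segments <- function(trajs) {
  tibble::tibble(
    segment_id = seq_along(trajs),
    label = "normal",
    trajectory = trajs
  )
}

test_that("identical segments give a degenerate baseline with zero distances", {
  tr <- tibble::tibble(e_s = seq(0, 1, by = 0.05),
                       theta_deg = 15 + 70 * (1 - cos(2 * pi * seq(0, 1, by = 0.05))) / 2)
  tr <- tibble::tibble(e_s = tr$e_s, shoulder = tr$theta_deg)
  b <- build_baseline(make_segments(rep(list(tr), 10)))
  expect_equal(b$mu, 0, tolerance = 1e-9)
  expect_equal(b$sigma, 0, tolerance = 1e-9)
  expect_true(b$degenerate)
  expect_error(z_score(1, b), class = "rehabdtw_degenerate_baseline_error")
})

test_that("baseline sigma uses the sample (n-1) convention", {
  p <- movement_params("abduction")
  segs <- cut_segments(generate_clip(p, "normal", 10, "all", seed = 3))
  b <- build_baseline(segs)
  d <- vapply(segs$trajectory, function(tr) multi_dtw_distance(tr, b), numeric(1))
  # brute-force two-pass standard deviation
  expect_equal(b$mu, sum(d) / length(d), tolerance = 1e-12)
  expect_equal(b$sigma, sqrt(sum((d - mean(d))^2) / (length(d) - 1)),
               tolerance = 1e-12)
  expect_false(b$degenerate)
})

test_that("baseline distance statistics are stable across seeds", {
  p <- movement_params("abduction")
  mus <- vapply(1:5, function(s) {
    segs <- dplyr::bind_rows(lapply(1:3, function(k) {
      cut_segments(generate_clip(p, "normal", 8, "all", seed = s * 100 + k))
    }))
    build_baseline(segs)$mu
  }, numeric(1))
  expect_true(all(is.finite(mus)))
  expect_lt(sd(mus), mean(mus)) # replication noise well below the signal
})

test_that("a single-angle feature set yields exactly one mean trajectory", {
  p <- movement_params("elbow_flexion")
  segs <- cut_segments(generate_clip(p, "normal", 6, "primary", seed = 9))
  b <- build_baseline(segs)
  expect_equal(b$joints, "elbow")
  expect_named(b$means, c("e_s", "elbow"))
  expect_s3_class(glance(b), "tbl_df")
  expect_equal(nrow(tidy(b)), nrow(b$means))
})

test_that("a held-out split can supply the distance statistics", {
  p <- movement_params("abduction")
  train <- cut_segments(generate_clip(p, "normal", 8, "primary", seed = 51))
  held <- cut_segments(generate_clip(p, "normal", 8, "primary", seed = 52))
  b_in <- build_baseline(train)
  b_out <- build_baseline(train, stats_segments = held)
  expect_equal(b_in$means, b_out$means)
  expect_false(isTRUE(all.equal(b_in$mu, b_out$mu)))
})
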