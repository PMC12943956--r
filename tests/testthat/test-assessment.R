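toy_baseline <- function(means, mu = 1, sigma = 0.5, config = dtw_config()) {
  structure(
    list(
      joints = setdiff(names(means), "e_s"), means = means,
      l_bar = max(means$e_s), grid_step = NA_real_,
      mu = mu, sigma = sigma, n_segments = NA_integer_,
      degenerate = FALSE, config = config
    ),
    class = "movement_baseline"
  )
}

test_that("DTW is zero on identical and exactly warpable sequences", {
  expect_equal(dtw_distance(c(1, 5, 3), c(1, 5, 3)), 0)
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 2, 3)), 0)
  cfg <- dtw_config(path_normalization = "none")
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 2, 3), cfg), 0)
  expect_error(dtw_distance(numeric(0), 1:3), class = "rehabdtw_validation_error")
})

test_that("DTW matches the exhaustive warping-path oracle on small instances", {
  withr::with_seed(123, {
    for (case in 1:60) {
      k <- sample(1:3, 1)
      n <- sample(2:6, 1)
      m <- sample(2:6, 1)
      a <- matrix(runif(n * k, 0, 100), n, k)
      b <- matrix(runif(m * k, 0, 100), m, k)
      colnames(a) <- colnames(b) <- paste0("j", seq_len(k))
      oracle <- dtw_brute(a, b, "euclidean")
      cfg_raw <- dtw_config(path_normalization = "none")
      cfg_norm <- dtw_config(path_normalization = "path_length")
      bl <- toy_baseline(dplyr::bind_cols(tibble::tibble(e_s = seq_len(m) - 1),
                                          tibble::as_tibble(b)))
      seg <- dplyr::bind_cols(tibble::tibble(e_s = seq_len(n) - 1),
                              tibble::as_tibble(a))
      expect_equal(multi_dtw_distance(seg, bl, cfg_raw), oracle$total,
                   tolerance = 1e-12)
      expect_equal(multi_dtw_distance(seg, bl, cfg_norm), oracle$normalized,
                   tolerance = 1e-12)
    }
  })
})

test_that("unnormalized DTW is symmetric and bounded below sensibly", {
  cfg <- dtw_config(path_normalization = "none")
  withr::with_seed(321, {
    for (case in 1:30) {
      a <- runif(sample(2:6, 1), 0, 50)
      b <- runif(sample(2:6, 1), 0, 50)
      d <- dtw_distance(a, b, cfg)
      expect_equal(dtw_distance(b, a, cfg), d, tolerance = 1e-12)
      expect_gte(d, 0)
      # never below the longer sequence's best single-step alignment cost
      best_step <- if (length(a) >= length(b)) {
        sum(apply(abs(outer(a, b, "-")), 1, min))
      } else {
        sum(apply(abs(outer(a, b, "-")), 2, min))
      }
      expect_gte(d + 1e-12, best_step)
    }
  })
})

test_that("single-joint multi-DTW reduces bitwise to plain DTW in both modes", {
  p <- movement_params("abduction")
  segs <- cut_segments(generate_clip(p, "normal", 4, "primary", seed = 61))
  b <- build_baseline(segs)
  for (mode in c("dependent", "independent")) {
    cfg <- dtw_config(multivariate_mode = mode)
    for (i in seq_len(nrow(segs))) {
      tr <- segs$trajectory[[i]]
      expect_identical(
        multi_dtw_distance(tr, b, cfg),
        dtw_distance(tr$shoulder, b$means$shoulder, cfg)
      )
    }
  }
})

test_that("independent mode averages the per-joint alignments", {
  p <- movement_params("abduction")
  segs <- cut_segments(generate_clip(p, "normal", 5, "all", seed = 62))
  b <- build_baseline(segs)
  cfg <- dtw_config(multivariate_mode = "independent")
  tr <- segs$trajectory[[2]]
  per_joint <- vapply(b$joints, function(j) {
    dtw_distance(tr[[j]], b$means[[j]], cfg)
  }, numeric(1))
  expect_equal(multi_dtw_distance(tr, b, cfg), mean(per_joint), tolerance = 1e-12)
  # joint mismatch is a configuration error
  expect_error(multi_dtw_distance(tr[c("e_s", "shoulder")], b, cfg),
               class = "rehabdtw_validation_error")
})

test_that("Z-scores standardize distances against the normal sample", {
  expect_equal(z_score(2.0120, 2.0120, 1.4640), 0)
  expect_equal(z_score(2.0120 + 1.4640, 2.0120, 1.4640), 1)
  expect_equal(round(z_score(1.9940, 2.0120, 1.4640), 4), -0.0123)
  expect_error(z_score(1, 0, 0), class = "rehabdtw_degenerate_baseline_error")
})

test_that("the score map is 100 up to one SD and hyperbolic beyond", {
  expect_equal(score_from_z(-0.0123), 100)
  expect_equal(score_from_z(1), 100)
  expect_equal(score_from_z(2), 50)
  expect_equal(score_from_z(4), 25)
  z <- seq(-5, 40, by = 0.01)
  s <- score_from_z(z)
  expect_true(all(diff(s) <= 1e-12))      # monotone non-increasing
  expect_true(all(s > 0 & s <= 100))      # range (0, 100]
  expect_equal(max(s), 100)
  # continuous at z = 1
  expect_equal(score_from_z(1 + 1e-9), 100, tolerance = 1e-6)
})

test_that("assessment composes distance, Z-score and score", {
  p <- movement_params("abduction")
  segs <- cut_segments(generate_clip(p, "normal", 10, "all", seed = 63))
  b <- build_baseline(segs)
  # a segment equal to the baseline means scores a perfect 100 at d = 0
  mean_seg <- b$means
  res <- assess_segment(mean_seg, b)
  expect_equal(res$d_alpha, 0, tolerance = 1e-9)
  expect_equal(res$z_alpha, -b$mu / b$sigma, tolerance = 1e-9)
  expect_equal(res$s_alpha, 100)
})

test_that("abnormal movements score below 100 in nearly every draw", {
  p <- movement_params("abduction")
  base_segs <- dplyr::bind_rows(lapply(1:3, function(k) {
    cut_segments(generate_clip(p, "normal", 8, "all", seed = 400 + k))
  }))
  b <- build_baseline(base_segs)
  scores <- unlist(lapply(1:20, function(s) {
    segs <- cut_segments(generate_clip(p, "abnormal", 10, "all", seed = 500 + s))
    assess_segments(segs, b)$s_alpha
  }))
  expect_equal(length(scores), 200L)
  expect_gte(mean(scores < 100), 0.95)
})

test_that("amplifying deviations from the baseline grows the distance", {
  # Strict per-step monotonicity is not a DTW theorem (a slightly larger
  # residual can occasionally find a cheaper off-diagonal alignment), so the
  # check is empirical: amplification by 4 must always dominate, and the
  # intermediate steps must be monotone in the large majority of instances.
  p <- movement_params("abduction")
  segs <- cut_segments(generate_clip(p, "normal", 6, "all", seed = 71))
  b <- build_baseline(segs)
  grid <- b$means$e_s
  steps <- c(1, 1.5, 2, 4)
  monotone <- logical(0)
  for (i in seq_len(nrow(segs))) {
    # resample the segment onto the baseline grid so residuals are defined
    tr <- segs$trajectory[[i]]
    resampled <- tibble::tibble(e_s = grid)
    for (j in b$joints) {
      resampled[[j]] <- interpolate_angle(
        pmin(grid, max(tr$e_s)), tibble::tibble(e_s = tr$e_s, theta_deg = tr[[j]])
      )
    }
    ds <- vapply(steps, function(k) {
      scaled <- resampled
      for (j in b$joints) {
        scaled[[j]] <- b$means[[j]] + k * (resampled[[j]] - b$means[[j]])
      }
      multi_dtw_distance(scaled, b)
    }, numeric(1))
    expect_gt(ds[length(ds)], ds[1])
    monotone <- c(monotone, diff(ds) >= -1e-9)
  }
  expect_gte(mean(monotone), 0.8)
})
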