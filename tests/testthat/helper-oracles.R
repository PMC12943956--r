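# Independent oracles used against the package implementation.

# Exhaustive enumeration of every monotone warping path (diagonal / down /
# right steps), accumulating the local cost in path order. Returns the
# minimum total cost and, among cost-optimal paths, the minimum path length.
dtw_brute <- function(a, b, local_cost = "euclidean", weights = NULL) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 1L)
  if (!is.matrix(b)) b <- matrix(b, ncol = 1L)
  n <- nrow(a); m <- nrow(b); k <- ncol(a)
  if (is.null(weights)) weights <- rep(1, k)
  cost <- function(i, j) {
    d <- weights * (a[i, ] - b[j, ])
    switch(local_cost,
      euclidean = sqrt(sum(d^2)),
      abs = sum(abs(d)),
      squared = sum(d^2)
    )
  }
  best <- Inf
  best_len <- Inf
  rec <- function(i, j, acc, len) {
    acc <- acc + cost(i, j)
    len <- len + 1L
    if (i == n && j == m) {
      if (acc < best || (acc == best && len < best_len)) {
        best <<- acc
        best_len <<- len
      }
      return(invisible(NULL))
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, acc, len)
    if (i < n) rec(i + 1L, j, acc, len)
    if (j < m) rec(i, j + 1L, acc, len)
  }
  rec(1L, 1L, 0, 0L)
  list(total = best, path_length = best_len, normalized = best / best_len)
}

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# group relabelings (mirrors the exact-distribution definition; independent
# of stats::wilcox.test's recursion).
u_stat_rank <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

u_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n2 <- length(y)
  w_obs <- u_stat_rank(x, y)
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2L, function(idx) u_stat_rank(pooled[idx], pooled[-idx]))
  p <- if (w_obs > n1 * n2 / 2) mean(ws >= w_obs) else mean(ws <= w_obs)
  min(2 * p, 1)
}

# Small random landmark stream for IO round trips.
random_stream <- function(n_frames, seed, visibility = FALSE, fps = 30) {
  withr::with_seed(seed, {
    stream <- tibble::tibble(
      frame = seq_len(n_frames) - 1L,
      time_s = (seq_len(n_frames) - 1L) / fps + cumsum(runif(n_frames, 0, 1e-3))
    )
    for (i in seq_len(33L) - 1L) {
      stream[[paste0("x", i)]] <- runif(n_frames, -0.05, 1.05)
      stream[[paste0("y", i)]] <- runif(n_frames, -0.05, 1.05)
    }
    if (visibility) {
      for (i in seq_len(33L) - 1L) {
        stream[[paste0("v", i)]] <- runif(n_frames)
      }
    }
    stream
  })
}

# Piecewise raised-cosine pulse trajectory used by segmentation tests:
# rest plateau, pulse rest -> peak -> rest, trailing plateau.
pulse_trajectory <- function(rest = 15, peak = 90, pulse_s = 1, lead_s = 0.6,
                             tail_s = 0.6, fps = 60) {
  t <- seq(0, lead_s + pulse_s + tail_s, by = 1 / fps)
  theta <- rep(rest, length(t))
  inside <- t >= lead_s & t <= lead_s + pulse_s
  s <- (t[inside] - lead_s) / pulse_s
  theta[inside] <- rest + (peak - rest) * (1 - cos(2 * pi * s)) / 2
  tibble::tibble(e_s = t, theta_deg = theta)
}
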