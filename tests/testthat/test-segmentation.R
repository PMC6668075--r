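test_that("pooled histogram conserves voxel counts and bins correctly", {
  v <- array(c(0, 0, 100, 100), c(2, 2, 1))
  h <- pooled_histogram(v, n_bins = 2)
  expect_equal(h$counts, c(2L, 2L))
  expect_equal(sum(h$counts), 4L)

  hconst <- pooled_histogram(array(7, c(3, 3, 3)), n_bins = 16)
  expect_equal(sum(hconst$counts > 0), 1L)
  expect_equal(sum(hconst$counts), 27L)

  set.seed(1)
  v3 <- array(sample(0:65535, 32^3, TRUE), c(32, 32, 32))
  expect_equal(sum(pooled_histogram(v3, 256)$counts), 32768L)

  expect_error(pooled_histogram(v, n_bins = 1), class = "graintomo_argument")
})

# trimodal mixture histogram used below: modes at 50 / 120 / 200 with
# masses 60/20/20 % and sd 8 on each, over 256 unit-width bins
trimodal_hist <- function(mirror = FALSE) {
  mids <- 0:255 + 0.5
  dens <- 0.6 * dnorm(mids, 50, 8) + 0.2 * dnorm(mids, 120, 8) +
    0.2 * dnorm(mids, 200, 8)
  counts <- round(1e6 * dens)
  if (mirror) counts <- rev(counts)
  structure(list(bin_edges = 0:256, mids = mids, counts = counts,
                 n_bins = 256L), class = "intensity_histogram")
}

test_that("threshold lands in the paraffin-grain valley of a trimodal histogram", {
  h <- trimodal_hist()
  t <- select_threshold(h, smoothing_window = 5)
  expect_gt(as.numeric(t), 140)
  expect_lt(as.numeric(t), 185)
  # oracle: global minimum of the smoothed histogram restricted to (120, 200)
  sm <- as.numeric(stats::filter(h$counts, rep(1 / 5, 5), sides = 2))
  idx <- which(h$mids > 120 & h$mids < 200)
  oracle <- h$mids[idx[which.min(sm[idx])]]
  expect_lt(abs(as.numeric(t) - oracle), 3)
})

test_that("valley detection is symmetric under intensity mirroring", {
  vals <- attr(select_threshold(trimodal_hist()), "valleys")
  vals_m <- attr(select_threshold(trimodal_hist(mirror = TRUE)), "valleys")
  expect_equal(sort(256 - vals_m), sort(vals), tolerance = 0.02)
})

test_that("histograms without two valleys raise a degenerate-histogram error", {
  counts <- integer(256)
  counts[101] <- 1000L; counts[201] <- 1000L   # two deltas, one valley
  h <- structure(list(bin_edges = 0:256, mids = 0:255 + 0.5, counts = counts,
                      n_bins = 256L), class = "intensity_histogram")
  err <- tryCatch(select_threshold(h), graintomo_degenerate_histogram = identity)
  expect_s3_class(err, "graintomo_degenerate_histogram")
  expect_equal(err$n_valleys, 1L)
})

test_that("thresholding is strict and monotone", {
  v <- array(c(10, 20, 30), c(3, 1, 1))
  expect_equal(as.vector(apply_threshold(v, 20)$data), c(FALSE, FALSE, TRUE))
  expect_false(any(apply_threshold(v, 30)$data))
  expect_true(all(apply_threshold(v, 5)$data))
  set.seed(2)
  vr <- array(runif(16^3, 0, 100), c(16, 16, 16))
  m1 <- apply_threshold(vr, 30)$data
  m2 <- apply_threshold(vr, 60)$data
  expect_true(all(m2 <= m1))   # raising t never grows the mask
})

test_that("largest component selection honours connectivity semantics", {
  m <- array(FALSE, c(12, 6, 6))
  m[1:10, 1:1, 1:1] <- TRUE          # 10 voxels
  m[1:5, 4, 4] <- TRUE               # 5 voxels
  out <- largest_component(m)
  expect_equal(sum(out$data), 10)
  expect_equal(attr(out, "n_components"), 2L)

  diag2 <- array(FALSE, c(4, 4, 4))
  diag2[2, 2, 2] <- TRUE; diag2[3, 3, 3] <- TRUE
  expect_equal(sum(largest_component(diag2, 26)$data), 2)
  expect_equal(sum(largest_component(diag2, 6)$data), 1)

  expect_error(largest_component(array(FALSE, c(3, 3, 3))),
               class = "graintomo_empty_mask")
})

test_that("largest component size matches brute-force flood fill on random blobs", {
  set.seed(3)
  for (rep in 1:3) {
    m <- array(FALSE, c(36, 36, 36))
    for (b in 1:12) {
      c0 <- runif(3, 6, 30); r <- runif(1, 2, 5)
      xs <- matrix(1:36, 36, 36)
      for (z in 1:36) {
        m[, , z] <- m[, , z] |
          ((xs - c0[1])^2 + (t(xs) - c0[2])^2 + (z - c0[3])^2 <= r^2)
      }
    }
    out <- largest_component(m, 26)
    bf <- bf_component_sizes(m, 26)
    expect_equal(sum(out$data), max(bf$sizes))
    expect_true(all(out$data <= m))   # output is a subset of the input
  }
})

test_that("ball median filtering equals the brute-force majority vote", {
  lone <- array(FALSE, c(9, 9, 9)); lone[5, 5, 5] <- TRUE
  expect_false(any(median_smooth(lone, 2)$data))

  cube <- array(FALSE, c(28, 28, 28)); cube[5:24, 5:24, 5:24] <- TRUE
  sm <- median_smooth(cube, 2)$data
  expect_true(all(sm[8:21, 8:21, 8:21]))   # interior retained

  set.seed(4)
  m <- array(runif(24^3) < 0.5, c(24, 24, 24))
  expect_identical(median_smooth(m, 2)$data, bf_ball_majority(m, 2))
})

test_that("median filtering is near-idempotent on already-smooth masks", {
  ball <- array(FALSE, c(56, 56, 56))
  xs <- matrix(1:56, 56, 56)
  ctr <- 28.25   # off-lattice centre avoids the worst staircase planes
  for (z in 1:56) {
    ball[, , z] <- (xs - ctr)^2 + (t(xs) - ctr)^2 + (z - ctr)^2 <= 24^2
  }
  # two passes produce a median-smooth mask; another pass barely moves it
  s2 <- median_smooth(median_smooth(ball, 2), 2)$data
  s3 <- median_smooth(s2, 2)$data
  expect_lt(sum(s2 != s3) / sum(s2), 0.001)
})

test_that("grain segmentation recovers the phantom grain as one component", {
  ph <- generate_phantom(mini_phantom_params(seed = 2))
  g <- segment_grain(ph$volume)
  truth <- phantom_grain_mask(ph)
  expect_gt(jaccard(g$data, truth$data), 0.95)
  # exactly one 26-connected component (flood-fill assertion)
  bf <- bf_component_sizes(g$data[seq(1, 96, 2), seq(1, 96, 2), seq(1, 112, 2)], 26)
  expect_equal(length(bf$sizes), 1L)
  log <- attr(g, "log")
  expect_true(is.numeric(log$threshold))
  expect_gt(log$threshold, ph$truth$params$intensities["paraffin"])

  expect_error(segment_grain(vol_image(array(100, c(8, 8, 8)), 0.01)),
               class = "graintomo_degenerate_histogram")
})
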