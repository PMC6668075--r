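test_that("concavity extraction: convex, notched and annular sections", {
  expect_false(any(concavity_region(raster_circle(30))))

  sl <- disc_with_notch(R = 40, depth = 20, halfw = 12)
  reg <- concavity_region(sl)
  expect_true(any(reg))
  # oracle: hull (gift-wrapping, half-plane rasterization) minus filled
  bf_reg <- bf_hull_mask(sl) & !sl
  expect_lt(sum(reg != bf_reg) / sum(bf_reg), 0.05)
  expect_lt(abs(sum(reg) - sum(bf_reg)), 0.03 * sum(bf_reg) + 5)

  ring <- matrix(FALSE, 31, 31)
  xs <- matrix(1:31, 31, 31)
  r2 <- (xs - 16)^2 + (t(xs) - 16)^2
  ring[r2 <= 144 & r2 >= 64] <- TRUE
  expect_false(any(concavity_region(ring)))   # hole removed by filling
})

test_that("boundary tracing returns an ordered closed 8-connected curve", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  cv <- trace_boundary(sq)
  expect_true(isTRUE(attr(cv, "closed")))
  expect_equal(nrow(cv), 36)
  steps <- sqrt(rowSums((cv - rbind(cv[-1, , drop = FALSE], cv[1, , drop = FALSE]))^2))
  expect_true(all(steps <= sqrt(2) + 1e-9))
  perim <- sum(steps)
  expect_lt(abs(perim - 36) / 36, 0.10)

  tiny <- matrix(FALSE, 5, 5); tiny[3, 3] <- TRUE
  expect_error(trace_boundary(tiny), class = "graintomo_detector_failed")
})

test_that("CPDA finds 4 / 3 / 0 corners on square, triangle and circle", {
  sq <- raster_square(40)
  co <- cpda_corners(trace_boundary(sq))
  expect_equal(nrow(co), 4)
  verts <- rbind(c(21, 21), c(21, 60), c(60, 21), c(60, 60))
  for (i in seq_len(4)) {
    d <- sqrt((co$x - verts[i, 1])^2 + (co$y - verts[i, 2])^2)
    expect_lte(min(d), 2)
  }

  tri <- raster_triangle()
  expect_equal(nrow(cpda_corners(trace_boundary(tri))), 3)

  expect_equal(nrow(cpda_corners(trace_boundary(raster_circle(40)))), 0)
  short <- trace_boundary(raster_circle(3, pad = 3))
  expect_error(cpda_corners(short), class = "graintomo_detector_failed")
})

test_that("corner responses track brute-force circumradius curvature", {
  # oracle: discrete curvature 1/R of the circle through p[i-k], p[i], p[i+k]
  sq <- raster_square(40)
  cv <- trace_boundary(sq)
  n <- nrow(cv)
  k <- 6
  curv <- vapply(seq_len(n), function(i) {
    a <- cv[((i - k - 1) %% n) + 1, ]; b <- cv[i, ]; c <- cv[((i + k - 1) %% n) + 1, ]
    ab <- sqrt(sum((b - a)^2)); bc <- sqrt(sum((c - b)^2)); ca <- sqrt(sum((a - c)^2))
    ar <- abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
    if (ar < 1e-9) 0 else 4 * ar / (ab * bc * ca)
  }, numeric(1))
  peaks <- order(-curv)[1:4]
  co <- cpda_corners(cv)
  for (i in peaks) {
    d <- sqrt((co$x - cv[i, 1])^2 + (co$y - cv[i, 2])^2)
    expect_lte(min(d), 2)   # CPDA corners coincide with curvature maxima
  }
})

test_that("detector sanity: no corners on constant-curvature curves", {
  for (r in c(20, 35, 60, 100)) {
    expect_equal(nrow(cpda_corners(trace_boundary(raster_circle(r)))), 0)
  }
})

test_that("constructed notch depths are recovered", {
  for (dep in c(10, 15, 30)) {
    m <- crease_depth(disc_with_notch(depth = dep))
    expect_true(m$valid)
    expect_lte(abs(m$depth_vox - dep), 2)
    # oracle: max distance of concavity pixels to the horizontal mouth chord
    reg <- concavity_region(disc_with_notch(depth = dep))
    oracle <- diff(range(which(reg, arr.ind = TRUE)[, 2]))
    expect_lte(abs(m$depth_vox - oracle), 1)
  }
  mr <- crease_depth(rect_with_notch(15, 6))
  expect_true(mr$valid)
  expect_lte(abs(mr$depth_vox - 15), 1.5)

  conv <- crease_depth(raster_circle(30))
  expect_false(conv$valid)
  expect_equal(conv$failure_code, "no-concavity")
  expect_true(is.na(conv$depth_vox))
})

test_that("depth is invariant under translation and scales with the section", {
  base <- disc_with_notch(R = 40, depth = 16, halfw = 14)
  d0 <- crease_depth(base)$depth_vox
  shifted <- matrix(FALSE, nrow(base) + 14, ncol(base) + 9)
  shifted[15 + seq_len(nrow(base)) - 1, 10 + seq_len(ncol(base)) - 1] <- base
  expect_equal(crease_depth(shifted)$depth_vox, d0)

  big <- disc_with_notch(R = 80, depth = 32, halfw = 28)
  d2 <- crease_depth(big)$depth_vox
  expect_lt(abs(d2 - 2 * d0) / (2 * d0), 0.10)
  # depth never exceeds the slice Y extent
  expect_lte(d0, ncol(base))
})

test_that("profile recovery follows the generated depth function", {
  p <- mini_phantom_params(seed = 10, depth_peak = 10)
  ph <- generate_phantom(p)
  prof <- crease_profile(phantom_grain_mask(ph))
  meas <- prof$measurements
  zr <- range(meas$slice_index)
  u <- (meas$slice_index - zr[1]) / diff(zr)
  d_true <- phantom_depth_truth(p, u)
  ok <- meas$valid & u >= 0.1 & u <= 0.9
  expect_gt(mean(meas$valid), 0.5)
  expect_lte(sqrt(mean((meas$depth_vox[ok] - d_true[ok])^2)), 3)
})

test_that("a creaseless phantom yields profile-failed", {
  p <- mini_phantom_params(seed = 10, depth_peak = 0)
  ph <- generate_phantom(p)
  expect_error(crease_profile(phantom_grain_mask(ph)),
               class = "graintomo_profile_failed")
})

test_that("two-bulge profiles recover both bulge positions", {
  p <- mini_phantom_params(seed = 11,
                           bumps = list(c(0.45, 0.3, 10), c(0.85, 0.15, 6)))
  ph <- generate_phantom(p)
  prof <- crease_profile(phantom_grain_mask(ph))
  nd <- prof$normalized$depth_vox
  pos <- prof$normalized$position
  u1 <- profile_peak_position(nd, pos, 0, 0.65)
  u2 <- profile_peak_position(nd, pos, 0.65, 1.01)
  expect_lte(abs(u1 - 0.45), 0.05)
  expect_lte(abs(u2 - 0.85), 0.05)
})

test_that("mean profiles aggregate pointwise with sample deviation", {
  p <- mini_phantom_params(seed = 10, depth_peak = 10)
  prof <- crease_profile(phantom_grain_mask(generate_phantom(p)))
  m5 <- mean_profile(list(prof, prof, prof, prof, prof))
  expect_equal(m5$mean_depth_mm, prof$normalized$depth_mm)
  expect_true(all(m5$sd_depth_mm[m5$n > 0] == 0))

  const_prof <- function(v) {
    structure(list(normalized = data.frame(position = seq(0, 1, length.out = 5),
                                           depth_vox = v, depth_mm = v)),
              class = "crease_profile")
  }
  m2 <- mean_profile(list(const_prof(10), const_prof(20)))
  expect_true(all(m2$mean_depth_mm == 15))
  expect_equal(m2$sd_depth_mm, rep(sd(c(10, 20)), 5))

  set.seed(5)
  vals <- replicate(3, runif(5, 0, 10), simplify = FALSE)
  mr <- mean_profile(lapply(vals, const_prof))
  bf <- colMeans(do.call(rbind, vals))
  expect_equal(mr$mean_depth_mm, bf)
})
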