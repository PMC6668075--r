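test_that("spherical elements enumerate the discrete ball", {
  se1 <- spherical_element(1)
  expect_equal(sum(se1), 7)                       # 6-neighbourhood plus centre
  se2 <- spherical_element(2)
  expect_equal(sum(se2), nrow(bf_ball_offsets(2)))  # = 33
  expect_equal(sum(se2), 33)
  # reflection symmetry in every axis and under axis permutation
  expect_true(all(se2 == se2[dim(se2)[1]:1, , ]))
  expect_true(all(se2 == se2[, dim(se2)[2]:1, ]))
  expect_true(all(se2 == aperm(se2, c(2, 1, 3))))
  expect_error(spherical_element(0.5), class = "graintomo_argument")
})

test_that("opening matches the brute-force min/max sweep voxel-for-voxel", {
  set.seed(11)
  for (rep in 1:4) {
    r <- sample(2:3, 1)
    m <- array(runif(20^3) < 0.5, c(20, 20, 20))
    expect_identical(opening(m, spherical_element(r))$data, bf_opening(m, r))
  }
})

test_that("erosion and dilation agree with the sweep kernels for balls", {
  set.seed(12)
  m <- array(runif(18^3) < 0.4, c(18, 18, 18))
  offs <- bf_ball_offsets(2)
  expect_identical(erode_mask(m, spherical_element(2))$data, bf_erode(m, offs))
  expect_identical(dilate_mask(m, spherical_element(2))$data, bf_dilate(m, offs))
})

test_that("opening is anti-extensive and idempotent", {
  set.seed(13)
  se <- spherical_element(2)
  for (rep in 1:3) {
    m <- array(runif(24^3) < 0.6, c(24, 24, 24))
    op <- opening(m, se)$data
    expect_true(all(op <= m))
    expect_identical(opening(op, se)$data, op)
  }
})

test_that("opening preserves thick shapes and removes thin ones", {
  ball <- array(FALSE, c(32, 32, 32))
  xs <- matrix(1:32, 32, 32)
  ctr <- 16.25   # off-lattice centre avoids the worst staircase planes
  for (z in 1:32) {
    ball[, , z] <- (xs - ctr)^2 + (t(xs) - ctr)^2 + (z - ctr)^2 <= 12^2
  }
  op <- opening(ball, spherical_element(3))$data
  expect_identical(op, bf_opening(ball, 3))
  expect_lt(sum(ball != op) / sum(ball), 0.02)

  plate <- array(FALSE, c(24, 24, 24))
  plate[, , 11:13] <- TRUE                       # thickness 3
  expect_false(any(opening(plate, spherical_element(3))$data))
})

test_that("void detection keeps enclosed cavities and drops open channels", {
  shell <- array(FALSE, c(13, 13, 13))
  shell[3:11, 3:11, 3:11] <- TRUE
  shell[5:9, 5:9, 5:9] <- FALSE                  # enclosed 5^3 cavity
  v <- detect_voids(binary_mask(shell, 0.01))
  expect_equal(sum(v$data), 125)
  expect_equal(attr(v, "n_voids"), 1L)
  expect_false(any(v$data & shell))              # disjoint from the mask

  drilled <- shell
  drilled[7, 7, 1:5] <- FALSE                    # channel to the border
  expect_equal(sum(detect_voids(binary_mask(drilled, 0.01))$data), 0)
})

test_that("no detected void component touches the image border", {
  ph <- generate_phantom(mini_phantom_params(seed = 3))
  v <- detect_voids(phantom_grain_mask(ph))$data
  d <- dim(v)
  expect_false(any(v[1, , ]) || any(v[d[1], , ]) ||
                 any(v[, 1, ]) || any(v[, d[2], ]) ||
                 any(v[, , 1]) || any(v[, , d[3]]))
})

test_that("void recovery is exact on the noiseless phantom", {
  ph <- generate_phantom(mini_phantom_params(seed = 3))
  v <- detect_voids(phantom_grain_mask(ph))
  expect_equal(sum(v$data), unname(ph$truth$counts["void"]))
  expect_identical(unname(v$data), unname(ph$truth$labels == 5L))
})

test_that("2D hole filling fills internal holes only", {
  ring <- matrix(FALSE, 15, 15)
  xs <- matrix(1:15, 15, 15)
  r2 <- (xs - 8)^2 + (t(xs) - 8)^2
  ring[r2 <= 36 & r2 >= 16] <- TRUE
  filled <- graintomo:::fill_holes_2d(ring)
  expect_true(all(filled[r2 <= 36]))
  expect_false(any(filled[r2 > 49]))
})
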