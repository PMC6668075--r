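cuboid_mask <- function(nx, ny, nz, pad = 4, voxel_size = 0.01) {
  m <- array(FALSE, c(nx + 2 * pad, ny + 2 * pad, nz + 2 * pad))
  m[pad + seq_len(nx), pad + seq_len(ny), pad + seq_len(nz)] <- TRUE
  binary_mask(m, voxel_size)
}

test_that("grain length is the Z extent of the bounding box in mm", {
  m <- cuboid_mask(40, 60, 100)
  expect_equal(grain_length(m), 1.00)
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(grain_length(binary_mask(single, 0.01)), 0.01)
  expect_error(grain_length(binary_mask(array(FALSE, c(3, 3, 3)), 0.01)),
               class = "graintomo_empty_mask")
})

test_that("width and thickness are the mean central Y and X extents", {
  m <- cuboid_mask(40, 60, 100)
  wt <- width_thickness(m)
  expect_equal(unname(wt["width"]), 0.60)
  expect_equal(unname(wt["thickness"]), 0.40)

  # elliptic cylinder, semi-axes a = 20 (X), b = 30 (Y)
  n <- 70
  xs <- matrix(seq_len(n), n, n)
  sl <- ((xs - 35.5) / 20)^2 + ((t(xs) - 35.5) / 30)^2 <= 1
  cyl <- array(rep(sl, 50), c(n, n, 50))
  wt2 <- width_thickness(binary_mask(cyl, 0.01))
  expect_lt(abs(wt2["width"] / 0.01 - 60), 1.5)
  expect_lt(abs(wt2["thickness"] / 0.01 - 40), 1.5)
})

test_that("compartment volumes obey the partition identity exactly", {
  lab <- array(0L, c(6, 6, 6))
  lab[2:5, 2:5, 2:5] <- 1L
  lab[3:4, 3:4, 3:4] <- 2L
  labels <- structure(list(data = lab, dims = dim(lab), voxel_size = 0.004,
                           se_radius_used = 3, downsample_factor = 1L),
                      class = "tissue_labels")
  voids <- binary_mask(array(FALSE, c(6, 6, 6)), 0.004)
  v <- compartment_volumes(labels, voids)
  expect_identical(unname(v["vol_inner"] + v["vol_outer"]), unname(v["vol_grain"]))
  expect_equal(unname(v["vol_inner"]), 8 * 0.004^3)
  expect_equal(unname(v["vol_grain"]), 64 * 0.004^3)
  expect_equal(unname(v["vol_void"]), 0)

  all_inner <- labels
  all_inner$data[] <- 0L; all_inner$data[1:3, 1:3, 1:3] <- 2L
  v2 <- compartment_volumes(all_inner, voids)
  expect_equal(unname(v2["vol_inner"]), 27 * 6.4e-8)

  bad <- binary_mask(array(FALSE, c(5, 5, 5)), 0.004)
  expect_error(compartment_volumes(labels, bad), class = "graintomo_argument")
})

test_that("voxel-size scaling laws hold exactly", {
  ph <- generate_phantom(mini_phantom_params(seed = 9))
  g <- phantom_grain_mask(ph)
  tis <- segment_tissues(g, se_radius = 6, downsample = 2)
  voids <- detect_voids(g)
  s <- 3.5
  g2 <- binary_mask(g$data, g$voxel_size * s)
  tis2 <- tis; tis2$voxel_size <- tis$voxel_size * s
  voids2 <- binary_mask(voids$data, voids$voxel_size * s)
  expect_equal(grain_length(g2), grain_length(g) * s)
  expect_equal(width_thickness(g2), width_thickness(g) * s, ignore_attr = TRUE)
  expect_equal(compartment_volumes(tis2, voids2),
               compartment_volumes(tis, voids) * s^3)
})

test_that("replicate summaries use the sample standard deviation", {
  rec <- data.frame(id = c("a", "b", "c"), stage = 240,
                    vol_grain_mm3 = c(14.2, 14.5, 14.8),
                    voxel_size_mm = 0.01)
  s <- summarize_replicates(rec)
  row <- s[s$feature == "vol_grain_mm3", ]
  expect_equal(row$mean, 14.5)
  expect_equal(row$sd, sd(c(14.2, 14.5, 14.8)))
  expect_equal(row$n, 3L)

  one <- summarize_replicates(rec[1, ])
  expect_true(all(one$sd == 0))
  expect_true(all(one$n == 1))

  set.seed(31)
  rnd <- data.frame(stage = rep(c(60, 120), each = 4),
                    length_mm = runif(8, 4, 8), width_mm = runif(8, 2, 4))
  s2 <- summarize_replicates(rnd)
  for (st in c(60, 120)) {
    x <- rnd$length_mm[rnd$stage == st]
    # brute-force two-pass mean / sd
    mu <- sum(x) / length(x)
    sdv <- sqrt(sum((x - mu)^2) / (length(x) - 1))
    row <- s2[s2$stage == st & s2$feature == "length_mm", ]
    expect_equal(row$mean, mu)
    expect_equal(row$sd, sdv)
  }
})

test_that("a full morphometry record assembles with consistent fields", {
  ph <- generate_phantom(mini_phantom_params(seed = 9))
  g <- phantom_grain_mask(ph)
  a <- align_grain(g, target_dims = c(96, 96, 112))
  tis <- segment_tissues(g, se_radius = 6, downsample = 2)
  voids <- detect_voids(g)
  rec <- grain_morphometry(a, tis, voids, id = "p9", stage = 120)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$vol_inner_mm3 + rec$vol_outer_mm3, rec$vol_grain_mm3)
  expect_gt(rec$length_mm, rec$width_mm)
  expect_true(all(is.finite(unlist(rec[3:9]))))
})
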