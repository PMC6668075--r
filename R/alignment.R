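#' Orientation of the equivalent ellipse of a 2D region
#'
#' Angle (degrees, measured from the first coordinate axis toward the second,
#' mapped to (-90, 90]) of the ellipse with the same normalized second central
#' moments as the region: `theta = 0.5 * atan2(2*mu11, mu20 - mu02)`.
#' Isotropic regions (`mu11 ~ 0`, `mu20 ~ mu02`), whose orientation is
#' undefined, return 0 with attribute `isotropic = TRUE`.
#'
#' @param slice 2D logical/0-1 matrix.
#' @return Angle in degrees in (-90, 90].
#' @export
equivalent_ellipse_angle <- function(slice) {
  idx <- which(slice != 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (is.null(n) || n < 3) {
    gt_error("degenerate_slice", "need at least 3 foreground pixels")
  }
  x <- idx[, 1] - mean(idx[, 1])
  y <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(x * x); mu02 <- mean(y * y); mu11 <- mean(x * y)
  tr <- mu20 + mu02
  if (mu20 * mu02 - mu11^2 <= 1e-12 * tr^2) {
    gt_error("degenerate_slice", "foreground pixels are collinear")
  }
  aniso <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  if (aniso < 1e-8 * tr) {
    return(structure(0, isotropic = TRUE))
  }
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  theta
}

# Map an orientation (period 180 degrees) into (-90, 90].
axial_wrap <- function(a) {
  a <- (a + 90) %% 180 - 90
  ifelse(a <= -90, a + 180, ifelse(a > 90, a - 180, a))
}

#' Axial circular mean of orientations
#'
#' Orientations have period 180 degrees, so angles are doubled, averaged on
#' the unit circle and halved back. Reduces to the arithmetic mean when all
#' angles lie within +-45 degrees of it. `NA` entries (degenerate slices) are
#' skipped; their count is attached as attribute `n_skipped`.
#'
#' @param angles numeric vector of degrees.
#' @param weights optional non-negative weights (e.g. section areas), same
#'   length as `angles`.
#' @return Mean orientation in (-90, 90].
#' @export
average_orientation <- function(angles, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  skipped <- sum(is.na(angles))
  keep <- !is.na(angles)
  a <- angles[keep]; w <- weights[keep]
  if (length(a) == 0 || sum(w) <= 0) {
    gt_error("alignment_failed", "no valid orientation estimates (all slices degenerate)")
  }
  rad2 <- a * pi / 90   # doubled angle in radians
  m <- atan2(sum(w * sin(rad2)) / sum(w), sum(w * cos(rad2)) / sum(w)) * 90 / pi
  m <- axial_wrap(m)
  structure(m, n_skipped = skipped)
}

rot_z <- function(deg) {
  th <- deg * pi / 180; c <- cos(th); s <- sin(th)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
rot_y <- function(deg) {
  th <- deg * pi / 180; c <- cos(th); s <- sin(th)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

mask_centroid <- function(dat) {
  idx <- which(dat)
  d <- dim(dat)
  x <- ((idx - 1) %% d[1]) + 1
  y <- ((idx - 1) %/% d[1]) %% d[2] + 1
  z <- ((idx - 1) %/% (d[1] * d[2])) + 1
  c(mean(x), mean(y), mean(z))
}

# z indices of nonempty slices along a given axis
nonempty_range <- function(dat, axis = 3) {
  pres <- apply(dat, axis, any)
  which(pres)
}

# Central window of n slices around the middle of the nonempty range,
# clipped symmetrically when the grain spans fewer slices.
central_window <- function(nonempty, n) {
  if (length(nonempty) == 0) return(integer(0))
  mid <- nonempty[ceiling(length(nonempty) / 2)]
  half <- floor(min(n, length(nonempty)) / 2)
  window <- (mid - half):(mid + half)
  intersect(window, nonempty)
}

# Orientation of one section; internal voids are filled first so that the
# lysis cavities inside the grain do not bias the second moments.
slice_angle_safe <- function(slice, fill = TRUE) {
  if (fill && sum(slice) >= 3) slice <- fill_holes_2d(slice)
  tryCatch(as.numeric(equivalent_ellipse_angle(slice)),
           graintomo_degenerate_slice = function(e) NA_real_)
}

# Mean equivalent-ellipse angle over XY slices in the central z window,
# weighted by section area so sliver sections near the tips cannot bias it.
estimate_theta_z <- function(dat, n_slices) {
  zs <- central_window(nonempty_range(dat, 3), n_slices)
  angles <- vapply(zs, function(z) slice_angle_safe(dat[, , z]), numeric(1))
  areas <- vapply(zs, function(z) sum(dat[, , z]), numeric(1))
  average_orientation(angles, areas)
}

# Tilt of the long axis out of Z, from XZ slices in the central y window.
# The XZ equivalent-ellipse angle phi is measured from +X toward +Z; a grain
# whose long axis is tilted by theta_y (about +Y, moving +Z toward +X) shows
# phi = 90 - theta_y, hence theta_y = 90 - phi (axially wrapped).
estimate_theta_y <- function(dat, n_slices) {
  ys <- central_window(nonempty_range(dat, 2), n_slices)
  angles <- vapply(ys, function(y) {
    phi <- slice_angle_safe(dat[, y, ])
    axial_wrap(90 - phi)
  }, numeric(1))
  areas <- vapply(ys, function(y) sum(dat[, y, ]), numeric(1))
  average_orientation(angles, areas)
}

# Resample a mask into a target grid under the inverse of the forward pose
# p_dst-frame -> src: p_src = Rz(theta_z) %*% Ry(theta_y) %*% F %*% p_rel + centroid,
# nearest-neighbour so the mask stays binary. Linear-interpolation-with-0.5
# threshold is available via interp = "linear".
resample_pose <- function(dat, theta_z, theta_y, flip_y, centroid, target_dims,
                          interp = c("nn", "linear")) {
  interp <- match.arg(interp)
  M <- rot_z(theta_z) %*% rot_y(theta_y)
  if (flip_y) M <- M %*% diag(c(1, -1, 1))
  resample_core(dat, M, centroid, target_dims, interp)
}

# Shared inverse-map resampler: output voxel p (relative to the target centre)
# samples the source at M %*% p + centroid.
resample_core <- function(dat, M, centroid, target_dims, interp) {
  td <- as.integer(target_dims)
  ctr <- (td + 1) / 2
  d <- dim(dat)
  out <- array(FALSE, dim = td)
  xg <- rep(seq_len(td[1]) - ctr[1], times = td[2])
  yg <- rep(seq_len(td[2]) - ctr[2], each = td[1])
  for (z in seq_len(td[3])) {
    zg <- z - ctr[3]
    sx <- M[1, 1] * xg + M[1, 2] * yg + M[1, 3] * zg + centroid[1]
    sy <- M[2, 1] * xg + M[2, 2] * yg + M[2, 3] * zg + centroid[2]
    sz <- M[3, 1] * xg + M[3, 2] * yg + M[3, 3] * zg + centroid[3]
    if (interp == "nn") {
      ix <- round(sx); iy <- round(sy); iz <- round(sz)
      ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
      vals <- logical(length(xg))
      if (any(ok)) {
        lin <- ix[ok] + d[1] * (iy[ok] - 1) + d[1] * d[2] * (iz[ok] - 1)
        vals[ok] <- dat[lin]
      }
    } else {
      vals <- trilinear_at(dat, d, sx, sy, sz) >= 0.5
    }
    out[, , z] <- vals
  }
  out
}

trilinear_at <- function(dat, d, sx, sy, sz) {
  x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
  fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
  acc <- numeric(length(sx))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    ix <- x0 + dx; iy <- y0 + dy; iz <- z0 + dz
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3] & w > 0
    if (any(ok)) {
      lin <- ix[ok] + d[1] * (iy[ok] - 1) + d[1] * d[2] * (iz[ok] - 1)
      acc[ok] <- acc[ok] + w[ok] * dat[lin]
    }
  }
  acc
}

# Crease-side statistic: signed imbalance of convex-hull concavity mass
# between the -Y and +Y halves of sampled central sections. The ventral
# crease is the dominant concavity, so a positive value (more concavity mass
# below the section centroid) means the crease faces -Y and the grain must
# be flipped about the XZ plane.
crease_side_stat <- function(dat, n_slices) {
  zs <- central_window(nonempty_range(dat, 3), n_slices)
  if (length(zs) > 31) zs <- zs[seq(1, length(zs), length.out = 31)]
  up <- 0; down <- 0
  for (z in zs) {
    sl <- dat[, , z]
    if (sum(sl) < 16) next
    reg <- concavity_region(sl)
    if (!any(reg)) next
    cy <- mean(which(attr(reg, "filled"), arr.ind = TRUE)[, 2])
    idx <- which(reg, arr.ind = TRUE)
    up <- up + sum(idx[, 2] > cy)
    down <- down + sum(idx[, 2] <= cy)
  }
  if (up + down == 0) return(0)
  (down - up) / (up + down)
}

#' Rotate a mask out of canonical pose
#'
#' Applies the forward pose `Rz(theta_z) %*% Ry(theta_y)` to a canonical-pose
#' mask by nearest-neighbour resampling (the rasterized rotation used in pose
#' recovery experiments).
#'
#' @param g a [binary_mask] or logical array.
#' @param theta_z,theta_y pose angles in degrees.
#' @param target_dims output grid (defaults to the input grid).
#' @return A [binary_mask] in the target grid, centred.
#' @export
pose_mask <- function(g, theta_z, theta_y, target_dims = NULL) {
  dat <- mask_data(g)
  if (is.null(target_dims)) target_dims <- dim(dat)
  M <- rot_y(-theta_y) %*% rot_z(-theta_z)   # inverse map of the forward pose
  out <- resample_core(dat, M, mask_centroid(dat), target_dims, "nn")
  binary_mask(out, obj_voxel_size(g))
}

#' Align a grain into the canonical pose
#'
#' Places the grain at the centre of a target grid with the crease plane on
#' YZ and the long axis on Z: (1) centering translation to the target centre;
#' (2) rotation about Z by the average equivalent-ellipse angle over up to
#' `n_slices` XY slices centred on the middle slice; (3) rotation about Y by
#' the average angle over XZ slices around the middle Y slice; (4) flip about
#' the XZ plane if the crease (the concave ventral side) faces -Y, so the
#' crease always opens toward +Y. The output is resampled once from the input
#' with the combined inverse transform (nearest-neighbour by default, so the
#' mask stays binary).
#'
#' @param g a [binary_mask] holding one connected component.
#' @param n_slices number of slices in each estimation window (default 200).
#' @param target_dims output grid in voxels (default `c(1000, 1000, 1200)`,
#'   the canonical full-scan grid; tests and phantoms use smaller grids).
#' @param interp `"nn"` (default) or `"linear"` (interpolate then threshold
#'   at 0.5).
#' @param flip `"auto"` applies the crease-side disambiguation; `"never"`
#'   skips it.
#' @param residuals re-estimate the pose angles on the aligned output (the
#'   idempotence check); disable for large pose-recovery sweeps.
#' @return An `aligned_grain`: `mask` ([binary_mask] in the target grid),
#'   `pose` (translation, theta_z, theta_y, theta_x = 0, flip_y, target_dims)
#'   and `voxel_size`; residual re-estimated angles are attached in
#'   `residual_theta_z` / `residual_theta_y`.
#' @export
align_grain <- function(g, n_slices = 200L, target_dims = c(1000L, 1000L, 1200L),
                        interp = c("nn", "linear"), flip = c("auto", "never"),
                        residuals = TRUE) {
  interp <- match.arg(interp)
  flip <- match.arg(flip)
  dat <- mask_data(g)
  gt_assert(any(dat), "empty_mask", "grain mask is empty")
  vs <- obj_voxel_size(g)
  vol_in <- sum(dat)
  centroid <- mask_centroid(dat)

  theta_z <- as.numeric(estimate_theta_z(dat, n_slices))
  interm <- resample_pose(dat, theta_z, 0, FALSE, centroid, dim(dat), interp)
  theta_y <- as.numeric(estimate_theta_y(interm, n_slices))

  build <- function(flip_y) {
    resample_pose(dat, theta_z, theta_y, flip_y, centroid, target_dims, interp)
  }
  aligned <- build(FALSE)
  flip_y <- FALSE
  if (flip == "auto") {
    stat <- crease_side_stat(aligned, n_slices)
    if (is.finite(stat) && stat > 0) {
      flip_y <- TRUE
      aligned <- build(TRUE)
    }
  }

  vol_out <- sum(aligned)
  if (vol_out < 0.9 * vol_in) {
    idx <- which(dat, arr.ind = TRUE)
    r_max <- sqrt(max(rowSums(sweep(idx, 2, centroid)^2)))
    gt_error("target_too_small",
             sprintf(paste0("aligned grain exceeds the target grid ",
                            "(volume dropped from %d to %d voxels); ",
                            "suggest target dims of at least %d per axis"),
                     vol_in, vol_out, 2 * ceiling(r_max) + 3))
  }

  res_z <- res_y <- NA_real_
  if (residuals) {
    res_z <- tryCatch(as.numeric(estimate_theta_z(aligned, n_slices)),
                      graintomo_error = function(e) NA_real_)
    res_y <- tryCatch(as.numeric(estimate_theta_y(aligned, n_slices)),
                      graintomo_error = function(e) NA_real_)
  }

  ctr <- (as.integer(target_dims) + 1) / 2
  structure(list(
    mask = binary_mask(aligned, vs),
    pose = list(translation = ctr - centroid,
                theta_z = theta_z, theta_y = theta_y, theta_x = 0,
                flip_y = flip_y, target_dims = as.integer(target_dims)),
    voxel_size = vs,
    residual_theta_z = res_z,
    residual_theta_y = res_y),
    class = "aligned_grain")
}

#' @export
print.aligned_grain <- function(x, ...) {
  cat(sprintf(paste0("<aligned_grain> dims %s  theta_z %.2f  theta_y %.2f  ",
                     "flip_y %s  residuals (%.2f, %.2f)\n"),
              paste(x$pose$target_dims, collapse = "x"),
              x$pose$theta_z, x$pose$theta_y, x$pose$flip_y,
              x$residual_theta_z, x$residual_theta_y))
  invisible(x)
}
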