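# Brute-force oracles, independent of the package's compiled kernels, plus
# small fixture builders. Everything here is deliberately naive R.

# integer offsets of the discrete ball |o|^2 <= r^2
bf_ball_offsets <- function(r) {
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  g[rowSums(g^2) <= r^2 + 1e-9, , drop = FALSE]
}

bf_shift <- function(m, o) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  xs <- seq_len(d[1]) + o[1]; ys <- seq_len(d[2]) + o[2]; zs <- seq_len(d[3]) + o[3]
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]; okz <- zs >= 1 & zs <= d[3]
  out[okx, oky, okz] <- m[xs[okx], ys[oky], zs[okz]]
  out
}

# erosion as intersection of shifts (out-of-grid = background)
bf_erode <- function(m, offs) {
  out <- m
  for (i in seq_len(nrow(offs))) out <- out & bf_shift(m, offs[i, ])
  out
}

# dilation as union of reflected shifts
bf_dilate <- function(m, offs) {
  out <- array(FALSE, dim = dim(m))
  for (i in seq_len(nrow(offs))) out <- out | bf_shift(m, -offs[i, ])
  out
}

bf_opening <- function(m, r) {
  offs <- bf_ball_offsets(r)
  bf_dilate(bf_erode(m, offs), offs)
}

# majority vote over the ball neighbourhood (median of a binary image)
bf_ball_majority <- function(m, r) {
  offs <- bf_ball_offsets(r)
  cnt <- array(0L, dim = dim(m))
  for (i in seq_len(nrow(offs))) cnt <- cnt + bf_shift(m, offs[i, ])
  cnt * 2L > nrow(offs)
}

# flood-fill component sizes by BFS on linear indices
bf_component_sizes <- function(m, connectivity = 26) {
  d <- dim(m)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  s <- rowSums(abs(offs))
  offs <- offs[s > 0 & s <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  lab <- array(0L, dim = d)
  sizes <- integer(0)
  coords <- which(m, arr.ind = TRUE)
  for (i in seq_len(nrow(coords))) {
    p0 <- coords[i, ]
    if (lab[p0[1], p0[2], p0[3]] > 0) next
    id <- length(sizes) + 1L
    queue <- matrix(p0, ncol = 3)
    lab[p0[1], p0[2], p0[3]] <- id
    n <- 1L
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        if (m[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0) {
          lab[q[1], q[2], q[3]] <- id
          queue <- rbind(queue, q)
          n <- n + 1L
        }
      }
    }
    sizes[id] <- n
  }
  list(labels = lab, sizes = sizes)
}

# principal-axis orientation of 2D pixels (eigenvector of the covariance)
bf_pca_angle <- function(slice) {
  idx <- which(slice != 0, arr.ind = TRUE)
  cv <- stats::cov(idx)
  e <- eigen(cv)
  v <- e$vectors[, 1]
  a <- atan2(v[2], v[1]) * 180 / pi
  ((a + 90) %% 180) - 90
}

# axial mean by brute-force minimisation of summed squared axial distance
bf_axial_mean <- function(angles, step = 0.05) {
  cand <- seq(-90 + step, 90, by = step)
  axdist <- function(a, b) {
    d <- abs(a - b) %% 180
    pmin(d, 180 - d)
  }
  cost <- vapply(cand, function(m) sum(axdist(angles, m)^2), numeric(1))
  cand[which.min(cost)]
}

# gift-wrapping convex hull of 2D points, then half-plane rasterization --
# independent of grDevices::chull and of the package's hull code
bf_hull_mask <- function(slice) {
  pts <- which(slice != 0, arr.ind = TRUE)
  if (nrow(pts) < 3) return(slice != 0)
  pts <- unique(pts)
  start <- pts[order(pts[, 1], pts[, 2])[1], ]
  hull <- list(start)
  cur <- start
  repeat {
    cand <- pts[1, ]
    if (all(cand == cur)) cand <- pts[2, ]
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      cr <- (cand[1] - cur[1]) * (p[2] - cur[2]) - (cand[2] - cur[2]) * (p[1] - cur[1])
      further <- sum((p - cur)^2) > sum((cand - cur)^2)
      if (cr < 0 || (abs(cr) < 1e-9 && further)) cand <- p
    }
    if (all(cand == start)) break
    hull[[length(hull) + 1]] <- cand
    cur <- cand
    if (length(hull) > nrow(pts)) break
  }
  hv <- do.call(rbind, hull)
  out <- array(FALSE, dim = dim(slice))
  d <- dim(slice)
  px <- rep(seq_len(d[1]), times = d[2])
  py <- rep(seq_len(d[2]), each = d[1])
  inside <- rep(TRUE, length(px))
  m <- nrow(hv)
  for (i in seq_len(m)) {
    j <- if (i == m) 1 else i + 1
    cr <- (hv[j, 1] - hv[i, 1]) * (py - hv[i, 2]) - (hv[j, 2] - hv[i, 2]) * (px - hv[i, 1])
    inside <- inside & (cr >= -1e-7)
  }
  out[cbind(px[inside], py[inside])] <- TRUE
  out
}

# ---------------------------------------------------------------------------
# fixture builders

# small grain phantom used throughout the unit tests
mini_phantom_params <- function(seed = 1, theta_z = 0, theta_y = 0,
                                depth_peak = 7, bumps = NULL,
                                void_fraction = 0.85, ...) {
  if (is.null(bumps)) bumps <- list(c(0.5, 0.5, depth_peak))
  phantom_params(dims = c(96L, 96L, 112L), half_length = 34, lobe_radius = 16,
                 lobe_separation = 8, crease_depth_fn = bumps,
                 crease_width = 6, shell_thickness = 3, gap_width = 2,
                 void_fraction = void_fraction, seed = seed,
                 pose = list(theta_z = theta_z, theta_y = theta_y,
                             translation = c(0, 0, 0)), ...)
}

# disc of radius R with a crease-up wedge notch; with halfw >= 15 the
# rasterized notch depth matches the nominal depth to ~1 px
disc_with_notch <- function(R = 50, depth = 30, halfw = 18, pad = 10) {
  n <- 2 * R + 2 * pad
  cx <- cy <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n); ys <- t(xs)
  disc <- (xs - cx)^2 + (ys - cy)^2 <= R^2
  if (depth <= 0) return(disc)
  ym <- cy + sqrt(R^2 - halfw^2)
  cut <- abs(xs - cx) <= halfw & ys >= ym - depth * (1 - abs(xs - cx) / halfw)
  disc & !cut
}

rect_with_notch <- function(depth = 15, width = 6) {
  m <- matrix(FALSE, 80, 60)
  m[11:70, 11:50] <- TRUE
  x0 <- 41 - floor(width / 2)
  m[x0:(x0 + width - 1), (50 - depth + 1):50] <- FALSE
  m
}

raster_circle <- function(r, pad = 10) {
  n <- 2 * r + 2 * pad
  xs <- matrix(seq_len(n), n, n)
  (xs - (n + 1) / 2)^2 + (t(xs) - (n + 1) / 2)^2 <= r^2
}

raster_square <- function(side = 40, pad = 20) {
  n <- side + 2 * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

raster_triangle <- function() {
  m <- matrix(FALSE, 100, 100)
  for (x in 20:80) {
    h <- round((x - 20) * 0.8)
    if (h > 0) m[x, 20:(20 + h)] <- TRUE
  }
  m
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# memoised study-scale phantoms shared by the acceptance tests
.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(key, params) {
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- generate_phantom(params)
  }
  .phantom_cache[[key]]
}

# position of a profile bulge: NA-aware running-mean smoothing (width 9)
# then argmax within [lo, hi); centres the plateau that integer-valued
# depths produce around a parabolic bulge
profile_peak_position <- function(depth, position, lo = 0, hi = 1) {
  n <- length(depth)
  sm <- vapply(seq_len(n), function(i) {
    w <- max(1, i - 4):min(n, i + 4)
    v <- depth[w]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  sel <- position >= lo & position < hi & !is.na(sm)
  position[sel][which.max(sm[sel])]
}
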