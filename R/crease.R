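# Convex hull of a 2D binary region, rasterized at pixel centres. Returns a
# logical matrix with the hull polygon vertices attached. Degenerate regions
# (< 3 pixels or collinear) hull to themselves.
convex_hull_mask <- function(slice) {
  fg <- slice != 0
  pts <- which(fg, arr.ind = TRUE)
  if (nrow(pts) < 3) {
    return(structure(fg, polygon = NULL))
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) {
    return(structure(fg, polygon = NULL))
  }
  vx <- pts[h, 1]; vy <- pts[h, 2]
  m <- length(h)
  # polygon orientation (shoelace); boundary pixels kept via the eps slack
  area2 <- sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy)
  s <- if (area2 >= 0) 1 else -1
  xr <- range(vx); yr <- range(vy)
  gx <- xr[1]:xr[2]; gy <- yr[1]:yr[2]
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  inside <- rep(TRUE, length(px))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    cr <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
    inside <- inside & (s * cr >= -1e-7)
  }
  out <- array(FALSE, dim = dim(fg))
  out[cbind(px[inside], py[inside])] <- TRUE
  structure(out, polygon = cbind(x = vx, y = vy))
}

#' Concavity region of a cross-section
#'
#' Difference between the convex hull of the (hole-filled) slice and the
#' filled slice itself: the region where the section falls short of its hull,
#' which contains the crease. Internal holes are removed by the filling, so an
#' annulus has no concavity; a convex section returns an empty region.
#'
#' @param slice 2D logical/0-1 matrix (an XY cross-section of the grain mask).
#' @return Logical matrix of the concavity region, with the hull polygon
#'   (matrix of vertex coordinates) as attribute `polygon` and the filled
#'   slice as attribute `filled`.
#' @export
concavity_region <- function(slice) {
  gt_assert(any(slice != 0), "empty_mask", "slice is empty")
  filled <- fill_holes_2d(slice)
  hull <- convex_hull_mask(filled)
  structure(hull & !filled, polygon = attr(hull, "polygon"), filled = filled)
}

# Moore-neighbour directions in clockwise order (y axis pointing up).
moore_dirs <- cbind(x = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
                    y = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L))

#' Trace the boundary of a 2D region as an ordered closed curve
#'
#' Moore-neighbour tracing (with Jacob's stopping criterion) of the outer
#' boundary of the largest 8-connected component: the boundary of a binary
#' region is its edge set, and the tracing orders it into a curve whose
#' consecutive points are 8-neighbours.
#'
#' @param region 2D logical/0-1 matrix with at least 8 foreground pixels.
#' @return An `n x 2` matrix of (x, y) pixel coordinates in boundary order,
#'   with attribute `closed = TRUE`.
#' @export
trace_boundary <- function(region) {
  fg <- region != 0
  if (sum(fg) < 8) {
    gt_error("detector_failed", "region too small to trace (< 8 pixels)")
  }
  d <- dim(fg)
  lab <- array(cc_label_cpp(as.logical(fg), c(d, 1L), 26L), d)
  sizes <- tabulate(lab)
  fg <- lab == which.max(sizes)

  pts <- which(fg, arr.ind = TRUE)
  o <- order(pts[, 2], pts[, 1])          # bottom-most, then left-most
  s <- pts[o[1], ]
  at <- function(x, y) x >= 1 && x <= d[1] && y >= 1 && y <= d[2] && fg[x, y]
  dir_index <- function(dx, dy) which(moore_dirs[, 1] == dx & moore_dirs[, 2] == dy)

  # The walk state is (pixel, backtrack direction); the boundary cycle is the
  # segment between the first repeated state, which handles pixels the outer
  # boundary legitimately visits twice (one-pixel isthmuses).
  p <- s
  b_dir <- dir_index(-1L, 0L)             # enter moving east; backtrack = west
  seen <- new.env(hash = TRUE)
  px <- integer(0); py <- integer(0)
  step <- 0L
  cycle_start <- 1L
  max_iter <- 8L * sum(fg) + 16L
  repeat {
    key <- paste0(p[1], ",", p[2], ",", b_dir)
    t0 <- seen[[key]]
    if (!is.null(t0)) { cycle_start <- t0; break }
    step <- step + 1L
    seen[[key]] <- step
    px[step] <- p[1]; py[step] <- p[2]
    if (step > max_iter) break
    found <- FALSE
    for (k in 1:8) {
      di <- ((b_dir - 1L + k - 1L) %% 8L) + 1L
      nx <- p[1] + moore_dirs[di, 1]; ny <- p[2] + moore_dirs[di, 2]
      if (at(nx, ny)) {
        prev <- ((di - 2L) %% 8L) + 1L    # background cell examined just before
        bx <- p[1] + moore_dirs[prev, 1] - nx
        by <- p[2] + moore_dirs[prev, 2] - ny
        b_dir <- dir_index(as.integer(bx), as.integer(by))
        p <- c(nx, ny)
        found <- TRUE
        break
      }
    }
    if (!found) break                     # cannot happen for size >= 8
  }
  path <- cbind(x = px[cycle_start:step], y = py[cycle_start:step])
  structure(path, closed = TRUE)
}

# Circular Gaussian smoothing of a closed curve's coordinates.
smooth_closed_curve <- function(pts, sigma) {
  if (sigma <= 0) return(pts)
  n <- nrow(pts)
  h <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-h:h, sd = sigma); w <- w / sum(w)
  sm <- function(v) {
    vp <- v[((seq(-h + 1, n + h) - 1) %% n) + 1]
    as.numeric(stats::filter(vp, w, sides = 2))[(h + 1):(h + n)]
  }
  cbind(x = sm(pts[, 1]), y = sm(pts[, 2]))
}

wrap_idx <- function(i, n) ((i - 1) %% n) + 1

#' CPDA corner detection on a boundary curve
#'
#' Chord-to-point distance accumulation: for each chord length `L` and each
#' curve point, the perpendicular distances from the point to every chord of
#' `L` curve samples that spans it are accumulated; each scale is normalized
#' to `[0, 1]` and the per-point multi-scale product forms the corner
#' response. Corners are local maxima of the response above `threshold`,
#' excluding points whose opening angle (measured to neighbours
#' `angle_span` samples away) is obtuse beyond `angle_max` degrees --
#' this rejects the near-flat maxima that survive normalization on
#' constant-curvature curves. The curve is pre-smoothed with a circular
#' Gaussian; reported corner positions are the unsmoothed curve points.
#'
#' @param curve `n x 2` point matrix from [trace_boundary()] (closed).
#' @param chord_lengths accumulation scales in curve samples.
#' @param threshold corner response threshold in `[0, 1]`.
#' @param angle_max obtuse-angle rejection threshold in degrees.
#' @param angle_span neighbour offset (samples) for the angle test.
#' @param smooth_sigma Gaussian smoothing of the curve (pixels).
#' @return `data.frame(index, x, y, value)` sorted by decreasing response;
#'   zero rows when no corner passes.
#' @export
cpda_corners <- function(curve, chord_lengths = c(10L, 20L, 30L),
                         threshold = 0.2, angle_max = 157, angle_span = 5L,
                         smooth_sigma = 1.5) {
  pts <- curve
  n <- nrow(pts)
  if (n <= max(chord_lengths) + 2) {
    gt_error("detector_failed",
             sprintf("curve too short (%d points) for chord length %d",
                     n, max(chord_lengths)))
  }
  sp <- smooth_closed_curve(pts, smooth_sigma)

  H <- rep(1, n)
  for (L in chord_lengths) {
    hL <- rep(0, n)
    i <- seq_len(n)
    for (k in seq_len(L - 1)) {
      ia <- wrap_idx(i - k, n)
      ib <- wrap_idx(i - k + L, n)
      ax <- sp[ia, 1]; ay <- sp[ia, 2]
      bx <- sp[ib, 1]; by <- sp[ib, 2]
      len <- sqrt((bx - ax)^2 + (by - ay)^2)
      cr <- abs((bx - ax) * (sp[, 2] - ay) - (by - ay) * (sp[, 1] - ax))
      hL <- hL + ifelse(len > 1e-9, cr / len, 0)
    }
    mx <- max(hL)
    H <- H * (if (mx > 0) hL / mx else 0)
  }

  nxt <- wrap_idx(seq_len(n) + 1, n)
  prv <- wrap_idx(seq_len(n) - 1, n)
  cand <- which(H > threshold & H >= H[prv] & H > H[nxt])
  if (length(cand) > 0) {
    K <- angle_span
    keep <- vapply(cand, function(i) {
      a <- sp[wrap_idx(i - K, n), ]; b <- sp[wrap_idx(i + K, n), ]; p <- sp[i, ]
      u <- a - p; v <- b - p
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu < 1e-9 || nv < 1e-9) return(FALSE)
      ang <- acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
      ang <= angle_max
    }, logical(1))
    cand <- cand[keep]
  }
  out <- data.frame(index = cand, x = pts[cand, 1], y = pts[cand, 2],
                    value = H[cand])
  out[order(-out$value), , drop = FALSE]
}

# Perpendicular distance of points to the line through (a, b).
line_dist <- function(px, py, a, b) {
  abs((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])) /
    sqrt((b[1] - a[1])^2 + (b[2] - a[2])^2)
}

failed_measurement <- function(code) {
  list(apex = c(NA_real_, NA_real_), depth_vox = NA_real_,
       valid = FALSE, failure_code = code)
}

#' Crease depth of a single cross-section
#'
#' Pipeline per slice: concavity region (hull minus filled section), boundary
#' tracing, CPDA corner detection. Among the three strongest corners the
#' crease apex is the point deepest below the convex-hull chord that closes
#' the concavity (the crease mouth); the depth is its perpendicular distance
#' to that chord. With `depth_mode = "dorsal"` the depth is instead measured
#' from the apex straight across to the dorsal (-Y) boundary of the section.
#' Only the ventral concavity (centroid on the +Y side of the section, the
#' crease-up convention of [align_grain()]) is measured; a dorsal indentation
#' is ignored. Failures never raise: they are encoded in the measurement as
#' `failure_code` `"no-concavity"` or `"detector-failed"`.
#'
#' @param slice 2D logical/0-1 matrix, crease opening toward +Y.
#' @param chord_lengths,threshold,angle_max,smooth_sigma passed to
#'   [cpda_corners()]; chord lengths are clipped for short boundaries.
#' @param depth_mode `"chord"` (default) or `"dorsal"`.
#' @return List with `apex` (x, y), `depth_vox`, `valid`, `failure_code`.
#' @export
crease_depth <- function(slice, chord_lengths = c(10L, 20L, 30L),
                         threshold = 0.2, angle_max = 157, smooth_sigma = 1.5,
                         depth_mode = c("chord", "dorsal")) {
  depth_mode <- match.arg(depth_mode)
  if (!any(slice != 0)) return(failed_measurement("no-concavity"))
  region <- concavity_region(slice)
  if (!any(region)) return(failed_measurement("no-concavity"))
  filled <- attr(region, "filled")

  d <- dim(region)
  lab <- array(cc_label_cpp(as.logical(region), c(d, 1L), 26L), d)
  ncomp <- max(lab)
  slice_cy <- mean(which(filled, arr.ind = TRUE)[, 2])
  best <- 0L; best_area <- 0L
  for (ci in seq_len(ncomp)) {
    idx <- which(lab == ci, arr.ind = TRUE)
    if (mean(idx[, 2]) >= slice_cy && nrow(idx) > best_area) {
      best <- ci; best_area <- nrow(idx)
    }
  }
  if (best == 0L) return(failed_measurement("no-concavity"))
  comp <- lab == best
  if (best_area < 8) return(failed_measurement("detector-failed"))

  curve <- tryCatch(trace_boundary(comp),
                    graintomo_detector_failed = function(e) NULL)
  if (is.null(curve)) return(failed_measurement("detector-failed"))
  n <- nrow(curve)
  ch <- sort(unique(pmin(as.integer(chord_lengths), n - 3L)))
  ch <- ch[ch >= 4L]
  if (length(ch) == 0) return(failed_measurement("detector-failed"))
  corners <- tryCatch(
    cpda_corners(curve, ch, threshold, angle_max, smooth_sigma = smooth_sigma),
    graintomo_detector_failed = function(e) NULL)
  if (is.null(corners) || nrow(corners) == 0) {
    return(failed_measurement("detector-failed"))
  }

  chord <- mouth_chord(filled, comp, curve)
  if (is.null(chord)) return(failed_measurement("detector-failed"))

  top <- utils::head(corners, 3)
  dd <- line_dist(top$x, top$y, chord$a, chord$b)
  pick <- which.max(dd)
  apex <- c(top$x[pick], top$y[pick])
  depth <- dd[pick]
  if (depth_mode == "dorsal") {
    col <- max(1, min(d[1], round(apex[1])))
    ys <- which(filled[col, ])
    if (length(ys) == 0) return(failed_measurement("detector-failed"))
    depth <- apex[2] - min(ys)
  }
  if (!is.finite(depth) || depth < 0) return(failed_measurement("detector-failed"))
  list(apex = apex, depth_vox = depth, valid = TRUE, failure_code = "none",
       chord = chord)
}

# The convex-hull edge that closes the concavity: the hull-polygon edge of
# the filled section along which the concavity boundary points lie.
mouth_chord <- function(filled, comp, curve) {
  hull <- convex_hull_mask(filled)
  poly <- attr(hull, "polygon")
  if (is.null(poly)) return(NULL)
  m <- nrow(poly)
  best <- NULL; best_count <- 1L
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    ab2 <- sum((b - a)^2)
    if (ab2 < 2) next
    t <- ((curve[, 1] - a[1]) * (b[1] - a[1]) + (curve[, 2] - a[2]) * (b[2] - a[2])) / ab2
    dist <- line_dist(curve[, 1], curve[, 2], a, b)
    count <- sum(dist < 1.5 & t > -0.05 & t < 1.05)
    if (count > best_count) {
      best_count <- count
      best <- list(a = a, b = b)
    }
  }
  best
}

#' Crease depth profile along a grain
#'
#' Runs [crease_depth()] on every nonempty transverse slice of an aligned
#' grain, converts depths to mm, and resamples the valid measurements onto
#' `k` points over relative position 0 (grain bottom) to 1 (top) by linear
#' interpolation for cross-grain averaging.
#'
#' @param a an `aligned_grain` or crease-up [binary_mask].
#' @param voxel_size optional override of the voxel size (mm).
#' @param k number of points of the normalized profile.
#' @param min_valid minimum fraction of valid slices (default 0.1); below it
#'   a `profile-failed` error is raised.
#' @param id optional sample label carried into the result.
#' @param ... passed to [crease_depth()].
#' @return A `crease_profile`: `measurements` data.frame (slice_index, apex_x,
#'   apex_y, depth_vox, depth_mm, valid, failure_code), `normalized`
#'   data.frame (position, depth_vox, depth_mm), `voxel_size`, `id`.
#' @export
crease_profile <- function(a, voxel_size = NULL, k = 100L, min_valid = 0.1,
                           id = NULL, ...) {
  dat <- aligned_mask_data(a)
  vs <- aligned_voxel_size(a, voxel_size)
  zs <- nonempty_range(dat, 3)
  gt_assert(length(zs) > 0, "empty_mask", "mask is empty")
  rows <- lapply(zs, function(z) {
    m <- crease_depth(dat[, , z], ...)
    data.frame(slice_index = z, apex_x = m$apex[1], apex_y = m$apex[2],
               depth_vox = m$depth_vox, depth_mm = m$depth_vox * vs,
               valid = m$valid, failure_code = m$failure_code,
               stringsAsFactors = FALSE)
  })
  meas <- do.call(rbind, rows)
  frac_valid <- mean(meas$valid)
  if (frac_valid < min_valid) {
    gt_error("profile_failed",
             sprintf("only %.0f%% of slices yielded a valid crease depth",
                     100 * frac_valid),
             fraction_valid = frac_valid)
  }
  rel <- (meas$slice_index - min(zs)) / max(1, (max(zs) - min(zs)))
  ok <- meas$valid
  pos <- seq(0, 1, length.out = k)
  depth_n <- stats::approx(rel[ok], meas$depth_vox[ok], xout = pos,
                           rule = 1, ties = mean)$y
  structure(list(id = id,
                 measurements = meas,
                 normalized = data.frame(position = pos,
                                         depth_vox = depth_n,
                                         depth_mm = depth_n * vs),
                 voxel_size = vs),
            class = "crease_profile")
}

#' Mean crease profile over replicate grains
#'
#' Pointwise mean and sample standard deviation of the normalized profiles;
#' missing points (slices without a valid measurement near the grain ends)
#' are excluded pointwise, with the contributing count reported.
#'
#' @param profiles list of `crease_profile` objects (same `k`).
#' @return `data.frame(position, mean_depth_mm, sd_depth_mm, n)`.
#' @export
mean_profile <- function(profiles) {
  gt_assert(length(profiles) >= 1, "argument", "need at least one profile")
  mats <- lapply(profiles, function(p) p$normalized$depth_mm)
  ks <- vapply(mats, length, integer(1))
  gt_assert(length(unique(ks)) == 1, "argument",
            "profiles have different normalized lengths")
  M <- do.call(rbind, mats)
  pos <- profiles[[1]]$normalized$position
  n_ok <- colSums(!is.na(M))
  mu <- colMeans(M, na.rm = TRUE)
  sdv <- apply(M, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) > 1) stats::sd(col) else 0
  })
  mu[n_ok == 0] <- NA_real_
  data.frame(position = pos, mean_depth_mm = mu, sd_depth_mm = sdv, n = n_ok)
}

#' @export
print.crease_profile <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("<crease_profile> %s  %d slices, %d valid (%.0f%%), max depth %.3g mm\n",
              if (is.null(x$id)) "(unnamed)" else x$id,
              nrow(m), sum(m$valid), 100 * mean(m$valid),
              suppressWarnings(max(m$depth_mm, na.rm = TRUE))))
  invisible(x)
}
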