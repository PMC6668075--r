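#' Segmentation parameters
#'
#' Bundles the tunable parameters of [segment_grain()]. The pooled histogram
#' of a grain scan is trimodal (dark background, intermediate paraffin, bright
#' grain and capsule); the threshold is placed in the valley between the
#' intermediate and bright modes.
#'
#' @param n_bins number of histogram bins (default 256; the modes of 16-bit
#'   scans are broad, fine binning only adds ripple).
#' @param smoothing_window moving-average window (bins) applied before
#'   extremum detection.
#' @param median_radius radius of the ball median filter in voxels (2 or 3 in
#'   routine use, any >= 1 accepted).
#' @param connectivity foreground connectivity for component selection
#'   (6, 18 or 26).
#' @param min_prominence minimum valley prominence as a fraction of total
#'   voxel mass; valleys shallower than this are treated as ripple.
#' @param median_2d apply the median filter slice-wise (2D disc) instead of in
#'   3D; kept for fidelity experiments.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(n_bins = 256L, smoothing_window = 5L,
                                median_radius = 2L, connectivity = 26L,
                                min_prominence = 0.005, median_2d = FALSE) {
  gt_assert(n_bins >= 2, "argument", "n_bins must be >= 2")
  gt_assert(smoothing_window >= 1, "argument", "smoothing_window must be >= 1")
  gt_assert(median_radius >= 1, "argument", "median_radius must be >= 1")
  gt_assert(connectivity %in% c(6L, 18L, 26L), "argument",
            "connectivity must be 6, 18 or 26")
  structure(list(n_bins = as.integer(n_bins),
                 smoothing_window = as.integer(smoothing_window),
                 median_radius = median_radius,
                 connectivity = as.integer(connectivity),
                 min_prominence = min_prominence,
                 median_2d = isTRUE(median_2d)),
            class = "segmentation_params")
}

#' Pooled intensity histogram of a volume
#'
#' Histogram of all voxels pooled over every slice of the scan, spanning the
#' observed intensity range. The bin counts conserve the total voxel count.
#'
#' @param v a [vol_image] or 3D array.
#' @param n_bins number of bins (>= 2).
#' @return A list of class `intensity_histogram` with `bin_edges` (length
#'   `n_bins + 1`), `mids`, `counts` and `n_bins`.
#' @export
pooled_histogram <- function(v, n_bins = 256L) {
  gt_assert(n_bins >= 2, "argument", "n_bins must be >= 2")
  dat <- vol_data(v)
  gt_assert(length(dat) > 0, "empty_input", "volume is empty")
  rng <- range(dat)
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1   # constant volume: one occupied bin
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- findInterval(dat, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, n_bins = as.integer(n_bins)),
            class = "intensity_histogram")
}

moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1) return(x)
  half <- window %/% 2
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))   # edge replication
  k <- 2 * half + 1
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(half + 1):(half + n)]
}

# Interior valleys of a smoothed histogram: local minima lying between two
# modes, with prominence (height of the lower flanking peak above the valley)
# of at least min_prominence * total mass.
find_valleys <- function(counts, smoothing_window, min_prominence) {
  s <- moving_average(counts, smoothing_window)
  n <- length(s)
  total <- sum(counts)
  # local extrema with plateau handling: compare against nearest differing values
  d <- diff(s)
  sign_d <- sign(d)
  nz <- which(sign_d != 0)
  valleys <- integer(0)
  if (length(nz) >= 2) {
    for (j in seq_len(length(nz) - 1)) {
      i1 <- nz[j]; i2 <- nz[j + 1]
      if (sign_d[i1] < 0 && sign_d[i2] > 0) {
        seg <- (i1 + 1):i2
        valleys <- c(valleys, seg[which.min(s[seg])])
      }
    }
  }
  if (length(valleys) > 0) {
    keep <- vapply(valleys, function(i) {
      left_peak <- max(s[1:i]); right_peak <- max(s[i:n])
      min(left_peak, right_peak) - s[i] >= min_prominence * total
    }, logical(1))
    valleys <- valleys[keep]
  }
  list(smoothed = s, valleys = valleys)
}

#' Select the grain threshold from a trimodal histogram
#'
#' Smooths the pooled histogram, inverts it, and locates its interior peaks
#' (the valleys of the original histogram). The threshold is the intensity of
#' the highest-intensity valley, i.e. the valley between the intermediate
#' (paraffin) mode and the bright (grain) mode; it therefore lies strictly
#' between those two mode centres.
#'
#' @param h an [pooled_histogram()] result.
#' @param smoothing_window moving-average window in bins.
#' @param min_prominence minimum valley prominence as a fraction of total mass.
#' @return The threshold intensity, with attributes `valleys` (intensities of
#'   all accepted valleys) and `n_valleys`.
#' @export
select_threshold <- function(h, smoothing_window = 5L, min_prominence = 0.005) {
  gt_assert(inherits(h, "intensity_histogram"), "argument",
            "h must be an intensity_histogram")
  gt_assert(smoothing_window >= 1, "argument", "smoothing_window must be >= 1")
  fv <- find_valleys(h$counts, smoothing_window, min_prominence)
  nv <- length(fv$valleys)
  if (nv < 2) {
    gt_error("degenerate_histogram",
             sprintf("expected a trimodal histogram with >= 2 valleys, found %d", nv),
             n_valleys = nv)
  }
  vals <- sort(h$mids[fv$valleys])
  structure(vals[length(vals)], valleys = vals, n_valleys = nv)
}

#' Threshold a volume
#'
#' Strict thresholding: voxels with intensity greater than `t` are foreground.
#'
#' @param v a [vol_image] or 3D array.
#' @param t threshold intensity.
#' @return A [binary_mask].
#' @export
apply_threshold <- function(v, t) {
  dat <- vol_data(v)
  binary_mask(array(dat > t, dim = dim(dat)), obj_voxel_size(v))
}

#' Keep the largest connected component
#'
#' Labels the foreground with the stated 3D connectivity and keeps a
#' maximal-size component. Ties are broken deterministically by the lowest
#' minimum linear index (the raster-scan order of component discovery).
#'
#' @param m a [binary_mask] or logical array.
#' @param connectivity 6, 18 or 26.
#' @return A [binary_mask] with attributes `component_size` and `n_components`.
#' @export
largest_component <- function(m, connectivity = 26L) {
  dat <- mask_data(m)
  gt_assert(any(dat), "empty_mask", "mask has no foreground voxels")
  lab <- cc_label_cpp(as.logical(dat), dim(dat), as.integer(connectivity))
  sizes <- tabulate(lab)
  best <- which.max(sizes)   # first maximal label = lowest minimum linear index
  out <- binary_mask(array(lab == best, dim = dim(dat)), obj_voxel_size(m))
  attr(out, "component_size") <- sizes[best]
  attr(out, "n_components") <- length(sizes)
  out
}

#' Median filter of a binary mask over a ball neighbourhood
#'
#' 3D median (majority vote) over the discrete ball of the given radius;
#' voxels outside the grid count as background. With `per_slice = TRUE` the
#' disc-shaped 2D filter is applied independently to every XY slice.
#'
#' @param m a [binary_mask] or logical array.
#' @param radius ball radius in voxels (>= 1; 2--3 in routine use).
#' @param per_slice apply slice-wise in 2D instead of in 3D.
#' @return A [binary_mask].
#' @export
median_smooth <- function(m, radius = 2, per_slice = FALSE) {
  gt_assert(radius >= 1, "argument", "radius must be >= 1")
  dat <- mask_data(m)
  if (per_slice) {
    out <- dat
    for (k in seq_len(dim(dat)[3])) {
      sl <- dat[, , k, drop = FALSE]
      out[, , k] <- array(ball_median_cpp(as.logical(sl), dim(sl), radius), dim(sl))
    }
  } else {
    out <- array(ball_median_cpp(as.logical(dat), dim(dat), radius), dim(dat))
  }
  binary_mask(out, obj_voxel_size(m))
}

#' Segment the grain from a raw scan
#'
#' Full grain segmentation pipeline: pooled histogram, valley threshold,
#' strict thresholding, largest 26-connected component, ball median filter,
#' and a second largest-component pass (the median filter can split the
#' component; downstream stages require exactly one). The chosen threshold and
#' stage statistics are attached as the `log` attribute.
#'
#' @param v a [vol_image].
#' @param params a [segmentation_params()] bundle.
#' @return A [binary_mask] of the grain (one connected component), with a
#'   `log` attribute recording the threshold, component counts and parameters.
#' @export
segment_grain <- function(v, params = segmentation_params()) {
  h <- pooled_histogram(v, params$n_bins)
  t <- select_threshold(h, params$smoothing_window, params$min_prominence)
  m <- apply_threshold(v, as.numeric(t))
  gt_assert(any(m$data), "empty_mask", "no voxels above threshold")
  m1 <- largest_component(m, params$connectivity)
  m2 <- median_smooth(m1, params$median_radius, per_slice = params$median_2d)
  gt_assert(any(m2$data), "empty_mask", "median filter removed all voxels")
  out <- largest_component(m2, params$connectivity)
  attr(out, "log") <- list(threshold = as.numeric(t),
                           valleys = attr(t, "valleys"),
                           thresholded_voxels = sum(m$data),
                           component_size_initial = attr(m1, "component_size"),
                           n_components_initial = attr(m1, "n_components"),
                           component_size_final = attr(out, "component_size"),
                           params = params)
  out
}
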