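#' Spherical structuring element
#'
#' Discrete 3D ball: all integer offsets with Euclidean norm at most `radius`.
#' The element contains its centre and is symmetric under axis permutation and
#' reflection, so erosion followed by dilation with it is a true opening.
#'
#' @param radius ball radius in voxels (>= 1; non-integer radii allowed).
#' @return A `(2r+1)^3` 0/1 array with attribute `radius`; the centre voxel is
#'   at position `r + 1` along each axis.
#' @export
spherical_element <- function(radius) {
  gt_assert(is.numeric(radius) && length(radius) == 1 && radius >= 1,
            "argument", "radius must be a single number >= 1")
  r <- floor(radius)
  ax <- (-r):r
  g <- expand.grid(x = ax, y = ax, z = ax)
  inside <- g$x^2 + g$y^2 + g$z^2 <= radius^2 + 1e-9
  se <- array(as.integer(inside), dim = rep(2 * r + 1, 3))
  attr(se, "radius") <- radius
  se
}

se_offsets <- function(se) {
  d <- dim(se)
  ctr <- (d + 1) %/% 2
  idx <- which(se != 0, arr.ind = TRUE)
  cbind(idx[, 1] - ctr[1], idx[, 2] - ctr[2], idx[, 3] - ctr[3])
}

# Squared distance from every voxel to the outside of the grid (the nearest
# voxel beyond any face), used so erosion treats out-of-image as background.
border_dist_sq <- function(dims) {
  bx <- pmin(seq_len(dims[1]), dims[1] - seq_len(dims[1]) + 1)
  by <- pmin(seq_len(dims[2]), dims[2] - seq_len(dims[2]) + 1)
  bz <- pmin(seq_len(dims[3]), dims[3] - seq_len(dims[3]) + 1)
  b <- array(rep(bx, times = dims[2] * dims[3]), dim = dims)
  b <- pmin(b, array(rep(rep(by, each = dims[1]), times = dims[3]), dim = dims))
  b <- pmin(b, array(rep(bz, each = dims[1] * dims[2]), dim = dims))
  b * b
}

#' Binary erosion
#'
#' For a spherical element (built by [spherical_element()]) the erosion is
#' computed exactly through the squared Euclidean distance transform: a voxel
#' survives iff its distance to the nearest background voxel (including the
#' outside of the image, which counts as background) exceeds the radius. For
#' arbitrary elements an explicit minimum sweep is used. Both routes are
#' voxel-identical to the definition `min` over the structuring element.
#'
#' @param m a [binary_mask] or logical array.
#' @param se structuring element array (see [spherical_element()]).
#' @return A [binary_mask].
#' @export
erode_mask <- function(m, se) {
  dat <- mask_data(m)
  r <- attr(se, "radius")
  if (!is.null(r)) {
    d_bg <- array(edt_sq_cpp(as.logical(!dat), dim(dat)), dim(dat))
    d_bg <- pmin(d_bg, border_dist_sq(dim(dat)))
    out <- dat & (d_bg > r^2 + 1e-9)
  } else {
    out <- array(sweep_erode_cpp(as.logical(dat), dim(dat), se_offsets(se)), dim(dat))
  }
  binary_mask(out, obj_voxel_size(m))
}

#' Binary dilation
#'
#' Dual of [erode_mask()]; the spherical fast path marks every voxel within
#' `radius` of the foreground (squared-distance test, exact).
#'
#' @inheritParams erode_mask
#' @return A [binary_mask].
#' @export
dilate_mask <- function(m, se) {
  dat <- mask_data(m)
  r <- attr(se, "radius")
  if (!is.null(r)) {
    d_fg <- array(edt_sq_cpp(as.logical(dat), dim(dat)), dim(dat))
    out <- d_fg <= r^2 + 1e-9
  } else {
    out <- array(sweep_dilate_cpp(as.logical(dat), dim(dat), se_offsets(se)), dim(dat))
  }
  binary_mask(out, obj_voxel_size(m))
}

#' Morphological opening
#'
#' Erosion followed by dilation with the same structuring element. Removes
#' bright structures thinner than the element while approximately preserving
#' larger shapes; anti-extensive (`opening(m)` is a subset of `m`) and
#' idempotent.
#'
#' @inheritParams erode_mask
#' @return A [binary_mask].
#' @export
opening <- function(m, se) {
  dilate_mask(erode_mask(m, se), se)
}

#' Detect enclosed voids inside a grain mask
#'
#' Voids are background components (6-connected, the dual of the 26-connected
#' foreground) that are not connected to the image border. Cavities open to
#' the outside -- such as the crease channel -- are excluded by construction.
#'
#' @param g a [binary_mask] of the grain.
#' @return A [binary_mask] of the voids with attributes `n_voids` and
#'   `void_sizes`.
#' @export
detect_voids <- function(g) {
  dat <- mask_data(g)
  bg <- !dat
  lab <- array(cc_label_cpp(as.logical(bg), dim(dat), 6L), dim(dat))
  d <- dim(dat)
  border_labels <- unique(c(lab[1, , ], lab[d[1], , ],
                            lab[, 1, ], lab[, d[2], ],
                            lab[, , 1], lab[, , d[3]]))
  border_labels <- border_labels[border_labels > 0]
  voids <- bg & !(lab %in% border_labels)
  dim(voids) <- d
  out <- binary_mask(voids, obj_voxel_size(g))
  kept <- setdiff(unique(lab[voids]), 0)
  attr(out, "n_voids") <- length(kept)
  attr(out, "void_sizes") <- as.integer(tabulate(lab)[kept])
  out
}

#' Fill enclosed cavities of a mask
#'
#' Union of the mask with its [detect_voids()] result.
#' @param m a [binary_mask] or logical array.
#' @return A [binary_mask].
#' @export
fill_holes <- function(m) {
  dat <- mask_data(m)
  v <- detect_voids(binary_mask(dat, obj_voxel_size(m)))
  binary_mask(dat | v$data, obj_voxel_size(m))
}

# 2D hole filling of a slice (4-connected background). The z faces of the
# single-slice volume are not borders here, only the in-plane edges are.
fill_holes_2d <- function(slice) {
  fg <- slice != 0
  d <- dim(fg)
  bg <- !fg
  lab <- array(cc_label_cpp(as.logical(bg), c(d, 1L), 6L), d)
  border_labels <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
  border_labels <- border_labels[border_labels > 0]
  filled <- fg | !(lab %in% border_labels)
  dim(filled) <- d
  filled
}
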