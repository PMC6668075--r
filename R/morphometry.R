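aligned_mask_data <- function(a) {
  if (inherits(a, "aligned_grain")) mask_data(a$mask) else mask_data(a)
}

aligned_voxel_size <- function(a, voxel_size = NULL) {
  if (!is.null(voxel_size)) return(voxel_size)
  if (inherits(a, "aligned_grain")) return(a$voxel_size)
  obj_voxel_size(a)
}

#' Grain length
#'
#' Length of the bounding box of the aligned grain along its long (Z) axis:
#' `(z_max - z_min + 1) * voxel_size`, in mm.
#'
#' @param a an `aligned_grain` or [binary_mask] in canonical pose.
#' @param voxel_size optional override of the object's voxel size (mm).
#' @return Length in mm.
#' @export
grain_length <- function(a, voxel_size = NULL) {
  dat <- aligned_mask_data(a)
  gt_assert(any(dat), "empty_mask", "mask is empty")
  zs <- nonempty_range(dat, 3)
  (max(zs) - min(zs) + 1) * aligned_voxel_size(a, voxel_size)
}

#' Grain width and thickness
#'
#' 2D bounding boxes are fitted on up to `n_slices` transverse (XY)
#' cross-sections centred on the middle of the grain; width is the mean Y
#' extent (the crease-to-dorsal dimension, since the crease plane is YZ) and
#' thickness the mean X extent, both in mm. Empty slices in the window are
#' skipped; their count is attached as attribute `n_skipped`.
#'
#' @inheritParams grain_length
#' @param n_slices size of the central window (default 200, matching the
#'   alignment window).
#' @return Named numeric vector `c(width = , thickness = )` in mm.
#' @export
width_thickness <- function(a, n_slices = 200L, voxel_size = NULL) {
  dat <- aligned_mask_data(a)
  gt_assert(any(dat), "empty_mask", "mask is empty")
  vs <- aligned_voxel_size(a, voxel_size)
  zs <- central_window(nonempty_range(dat, 3), n_slices)
  ext <- vapply(zs, function(z) {
    sl <- dat[, , z]
    xs <- which(rowSums(sl) > 0)
    ys <- which(colSums(sl) > 0)
    if (length(xs) == 0) return(c(NA_real_, NA_real_))
    c(max(ys) - min(ys) + 1, max(xs) - min(xs) + 1)
  }, numeric(2))
  ok <- !is.na(ext[1, ])
  gt_assert(any(ok), "empty_mask", "all central slices are empty")
  out <- c(width = mean(ext[1, ok]) * vs, thickness = mean(ext[2, ok]) * vs)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Compartment volumes
#'
#' Voxel counts of the grain, inner and outer compartments and the voids,
#' converted to mm^3 with `voxel_size^3`. The partition identity
#' `vol_inner + vol_outer == vol_grain` holds exactly because the tissue
#' labels partition the grain foreground.
#'
#' @param labels a `tissue_labels` object from [segment_tissues()].
#' @param voids a [binary_mask] from [detect_voids()].
#' @return Named numeric vector `c(vol_grain, vol_inner, vol_outer, vol_void)`
#'   in mm^3.
#' @export
compartment_volumes <- function(labels, voids) {
  gt_assert(inherits(labels, "tissue_labels"), "argument",
            "labels must come from segment_tissues()")
  vdat <- mask_data(voids)
  gt_assert(identical(dim(labels$data), dim(vdat)), "argument",
            "labels and voids dims differ")
  gt_assert(isTRUE(all.equal(labels$voxel_size, obj_voxel_size(voids))),
            "argument", "labels and voids voxel sizes differ")
  v3 <- labels$voxel_size^3
  n_outer <- sum(labels$data == 1L)
  n_inner <- sum(labels$data == 2L)
  c(vol_grain = (n_outer + n_inner) * v3,
    vol_inner = n_inner * v3,
    vol_outer = n_outer * v3,
    vol_void = sum(vdat) * v3)
}

#' Assemble a per-grain morphometry record
#'
#' @param aligned an `aligned_grain` (dimensions are measured in the
#'   canonical pose).
#' @param labels,voids tissue labels and void mask (any consistent frame;
#'   volumes are voxel counts and pose-independent).
#' @param id,stage sample label and developmental stage (degree days after
#'   anthesis).
#' @param n_slices central window for width/thickness.
#' @return One-row `data.frame` with columns id, stage, length_mm, width_mm,
#'   thickness_mm, vol_grain_mm3, vol_inner_mm3, vol_outer_mm3, vol_void_mm3,
#'   voxel_size_mm.
#' @export
grain_morphometry <- function(aligned, labels, voids, id = NA_character_,
                              stage = NA_real_, n_slices = 200L) {
  wt <- width_thickness(aligned, n_slices)
  vols <- compartment_volumes(labels, voids)
  data.frame(id = id, stage = stage,
             length_mm = grain_length(aligned),
             width_mm = unname(wt["width"]),
             thickness_mm = unname(wt["thickness"]),
             vol_grain_mm3 = unname(vols["vol_grain"]),
             vol_inner_mm3 = unname(vols["vol_inner"]),
             vol_outer_mm3 = unname(vols["vol_outer"]),
             vol_void_mm3 = unname(vols["vol_void"]),
             voxel_size_mm = aligned_voxel_size(aligned),
             stringsAsFactors = FALSE)
}

#' Summarise replicate grains per developmental stage
#'
#' Mean and sample standard deviation (n - 1 denominator; 0 when n = 1) of
#' every numeric morphometric feature, grouped by stage.
#'
#' @param records data.frame of [grain_morphometry()] rows.
#' @param group_by grouping column (default `"stage"`).
#' @return Long-format data.frame with columns group value, `feature`,
#'   `mean`, `sd`, `n`.
#' @export
summarize_replicates <- function(records, group_by = "stage") {
  gt_assert(is.data.frame(records) && nrow(records) >= 1, "argument",
            "records must be a nonempty data.frame")
  gt_assert(group_by %in% names(records), "argument",
            sprintf("no column '%s' in records", group_by))
  feats <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                   c(group_by, "voxel_size_mm"))
  groups <- split(records, records[[group_by]])
  out <- do.call(rbind, lapply(names(groups), function(gname) {
    gdf <- groups[[gname]]
    do.call(rbind, lapply(feats, function(f) {
      x <- gdf[[f]]
      data.frame(group = gname, feature = f, mean = mean(x),
                 sd = if (length(x) > 1) stats::sd(x) else 0,
                 n = length(x), stringsAsFactors = FALSE)
    }))
  }))
  names(out)[1] <- group_by
  rownames(out) <- NULL
  out
}
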