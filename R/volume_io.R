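#' Volumetric image container
#'
#' A `vol_image` wraps a 3D intensity array together with its physical voxel
#' size. The array is indexed `[x, y, z]` (0-based indices in file terms map to
#' 1-based array indices): `x` is the image column, `y` the image row and `z`
#' the slice number, so the XY plane is the transverse view, ZY the frontal
#' view and XZ the sagittal view.
#'
#' @param data 3D numeric array of intensities (unsigned 16-bit semantics).
#' @param voxel_size isotropic voxel edge length in mm (> 0).
#' @param id optional free-text sample label.
#' @param stage optional developmental stage in degree days after anthesis.
#' @param bit_depth 8 or 16; bounds the representable intensity range.
#' @return An object of class `vol_image` with fields `data`, `dims`,
#'   `voxel_size`, `id`, `stage`, `bit_depth`.
#' @export
vol_image <- function(data, voxel_size, id = NULL, stage = NULL, bit_depth = 16L) {
  gt_assert(is.array(data) && length(dim(data)) == 3, "argument",
            "data must be a 3D array")
  gt_assert(all(dim(data) >= 1), "argument", "all dims must be >= 1")
  gt_assert(is.numeric(voxel_size) && length(voxel_size) == 1 &&
              is.finite(voxel_size) && voxel_size > 0,
            "argument", "voxel_size must be a single finite positive number (mm)")
  gt_assert(bit_depth %in% c(8L, 16L), "argument", "bit_depth must be 8 or 16")
  vmax <- 2^bit_depth - 1
  rng <- range(data)
  gt_assert(rng[1] >= 0 && rng[2] <= vmax, "argument",
            sprintf("intensities must lie in [0, %d] for %d-bit data", vmax, bit_depth))
  structure(list(data = data, dims = dim(data), voxel_size = voxel_size,
                 id = id, stage = stage, bit_depth = as.integer(bit_depth)),
            class = "vol_image")
}

#' Binary mask container
#'
#' @param data 3D logical (or 0/1) array, indexed `[x, y, z]`.
#' @param voxel_size voxel edge length in mm, inherited from the source volume.
#' @return An object of class `binary_mask` with fields `data` (logical),
#'   `dims`, `voxel_size`.
#' @export
binary_mask <- function(data, voxel_size) {
  gt_assert(is.array(data) && length(dim(data)) == 3, "argument",
            "data must be a 3D array")
  gt_assert(is.numeric(voxel_size) && length(voxel_size) == 1 &&
              is.finite(voxel_size) && voxel_size > 0,
            "argument", "voxel_size must be a single finite positive number (mm)")
  d <- data
  if (!is.logical(d)) {
    gt_assert(all(d %in% c(0, 1)), "argument", "mask values must be 0/1")
    d <- array(d != 0, dim = dim(data))
  }
  structure(list(data = d, dims = dim(d), voxel_size = voxel_size),
            class = "binary_mask")
}

# Accept either a container or a bare array; return the bare array.
vol_data <- function(v) if (inherits(v, c("vol_image", "binary_mask", "tissue_labels"))) v$data else v

mask_data <- function(m) {
  d <- vol_data(m)
  if (!is.logical(d)) d <- array(d != 0, dim = dim(d))
  d
}

obj_voxel_size <- function(v, default = 1) {
  if (is.list(v) && !is.null(v$voxel_size)) v$voxel_size else default
}

#' @export
print.vol_image <- function(x, ...) {
  cat(sprintf("<vol_image> %s  dims %s  voxel %.4g mm  %d-bit%s\n",
              if (is.null(x$id)) "(unnamed)" else x$id,
              paste(x$dims, collapse = "x"), x$voxel_size, x$bit_depth,
              if (is.null(x$stage)) "" else sprintf("  stage %g °DAA", x$stage)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> dims %s  voxel %.4g mm  foreground %d voxels\n",
              paste(x$dims, collapse = "x"), x$voxel_size, sum(x$data)))
  invisible(x)
}

slice_files <- function(path) {
  fs <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE, full.names = TRUE)
  fs[order(basename(fs), method = "radix")]   # lexicographic slice order
}

#' Read a volume from a TIFF slice stack
#'
#' Reads an ordered stack of grayscale 2D TIFF slices (a directory of
#' single-page files, sorted lexicographically by filename, or one multi-page
#' file) into a [vol_image]. Slice `k` becomes `data[, , k]` with
#' `(row, col) = (Y, X)`. 8-bit and 16-bit grayscale inputs are supported;
#' values are returned on their stored integer scale.
#'
#' @param path directory of `.tif`/`.tiff` slices or a single (multi-page) file.
#' @param voxel_size isotropic voxel size in mm (metadata is never parsed from
#'   TIFF tags; the caller states it explicitly).
#' @param id,stage optional metadata attached to the result.
#' @return A [vol_image].
#' @export
read_volume <- function(path, voxel_size, id = NULL, stage = NULL) {
  gt_assert(is.numeric(voxel_size) && length(voxel_size) == 1 &&
              is.finite(voxel_size) && voxel_size > 0,
            "argument", "voxel_size must be a single finite positive number (mm)")
  gt_assert(is.character(path) && length(path) == 1 && nzchar(path),
            "io", "path must be a non-empty string")
  gt_assert(file.exists(path), "io", sprintf("path does not exist: %s", path))

  if (dir.exists(path)) {
    fs <- slice_files(path)
    gt_assert(length(fs) >= 1, "empty_input", "no TIFF slices found in directory")
    pages <- lapply(fs, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    gt_assert(length(pages) >= 1, "empty_input", "no pages in TIFF file")
  }
  shapes <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), character(1))
  gt_assert(length(unique(shapes)) == 1, "format",
            sprintf("inconsistent slice shapes: %s", paste(unique(shapes), collapse = ", ")))
  dims2 <- dim(pages[[1]])
  gt_assert(length(dims2) == 2, "format", "slices must be single-channel grayscale")

  nz <- length(pages)
  dat <- array(0, dim = c(dims2[2], dims2[1], nz))   # (x, y, z) = (col, row, slice)
  for (k in seq_len(nz)) dat[, , k] <- t(pages[[k]])
  vol_image(dat, voxel_size, id = id, stage = stage, bit_depth = 16L)
}

#' Write a volume, mask or label grid as a TIFF slice stack
#'
#' Intensity volumes are written 16-bit; binary masks are written 8-bit with
#' foreground 255; integer label grids (codes 0..255) are written 8-bit with
#' the codes preserved. `path` ending in `.tif`/`.tiff` produces one
#' multi-page file, otherwise a directory of `slice_0001.tif`, ... is created.
#'
#' @param v a [vol_image], [binary_mask], tissue label map, or bare 3D array.
#' @param path output file or directory.
#' @return Invisibly, the vector of files written.
#' @export
write_volume <- function(v, path) {
  gt_assert(is.character(path) && length(path) == 1 && nzchar(path),
            "io", "path must be a non-empty string")
  dat <- vol_data(v)
  gt_assert(is.array(dat) && length(dim(dat)) == 3, "argument", "need a 3D array")

  if (inherits(v, "binary_mask") || is.logical(dat)) {
    scaled <- array(ifelse(dat != 0, 255, 0) / 255, dim = dim(dat))
    bits <- 8L
  } else if (inherits(v, "tissue_labels") ||
             (all(dat == round(dat)) && max(dat) <= 255 && !inherits(v, "vol_image"))) {
    scaled <- dat / 255
    bits <- 8L
  } else {
    gt_assert(max(dat) <= 65535 && min(dat) >= 0, "argument",
              "intensities out of 16-bit range")
    scaled <- dat / 65535
    bits <- 16L
  }

  nz <- dim(dat)[3]
  pages <- lapply(seq_len(nz), function(k) t(scaled[, , k]))
  multi <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  ok <- tryCatch({
    if (multi) {
      tiff::writeTIFF(pages, path, bits.per.sample = bits)
      files <- path
    } else {
      if (!dir.exists(path)) dir.create(path, recursive = TRUE)
      files <- file.path(path, sprintf("slice_%04d.tif", seq_len(nz)))
      for (k in seq_len(nz)) tiff::writeTIFF(pages[[k]], files[k], bits.per.sample = bits)
    }
    files
  }, error = function(e) gt_error("io", conditionMessage(e)))
  invisible(ok)
}

#' Read a slice stack as a binary mask
#'
#' Convenience wrapper over [read_volume()] mapping any positive stored value
#' to foreground.
#' @inheritParams read_volume
#' @return A [binary_mask].
#' @export
read_mask <- function(path, voxel_size) {
  v <- read_volume(path, voxel_size)
  binary_mask(array(v$data > 0, dim = v$dims), voxel_size)
}
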