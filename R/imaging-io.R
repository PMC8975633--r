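# Slice container, intensity normalization contract, and NIfTI volume I/O.

#' A single 2D PET slice
#'
#' @param pixels numeric matrix of intensities (all finite).
#' @param spacing length-2 `c(row, col)` pixel spacing in mm.
#' @param label optional region tag (`"head"`, `"lung"`, `"abdomen"`,
#'   `"synthetic"`, ...).
#' @return an object of class `image_slice`.
#' @export
image_slice <- function(pixels, spacing = c(1, 1), label = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("'pixels' must be a numeric matrix")
  if (!all(is.finite(pixels))) stopf("'pixels' must be finite everywhere")
  if (!is.numeric(spacing) || length(spacing) != 2L || any(spacing <= 0))
    stopf("'spacing' must be two positive numbers (mm)")
  structure(list(pixels = pixels, spacing = as.numeric(spacing), label = label),
            class = "image_slice")
}

as_image_slice <- function(x) {
  if (inherits(x, "image_slice")) x
  else if (is.matrix(x)) image_slice(x)
  else stopf("expected an image_slice or a numeric matrix")
}

slice_pixels <- function(x) if (inherits(x, "image_slice")) x$pixels else x

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("image_slice %dx%d, spacing %.3gx%.3g mm%s, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              if (is.null(x$label)) "" else paste0(", label ", x$label),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' An aligned low-quality / high-quality slice pair
#'
#' @param lq the low-quality member (domain A).
#' @param hq the high-quality member (domain B); must have the same
#'   dimensions as `lq`.
#' @return an object of class `paired_sample`.
#' @export
paired_sample <- function(lq, hq) {
  lq <- as_image_slice(lq); hq <- as_image_slice(hq)
  if (!identical(dim(lq$pixels), dim(hq$pixels)))
    stopf("paired slices must have identical dimensions (%s vs %s)",
          paste(dim(lq$pixels), collapse = "x"),
          paste(dim(hq$pixels), collapse = "x"))
  structure(list(lq = lq, hq = hq), class = "paired_sample")
}

#' Linearly rescale a slice to \[-1, 1\]
#'
#' Maps `vmin` to -1 and `vmax` to +1; values outside the range are clipped.
#' The degenerate case `vmin == vmax` returns an all-zero slice with a
#' warning.
#'
#' @param slice an [image_slice()] or numeric matrix.
#' @param vmin,vmax intensities mapped to -1 and +1.
#' @return object of the same type with pixels in \[-1, 1\].
#' @export
normalize <- function(slice, vmin, vmax) {
  check_scalar(vmin, "vmin"); check_scalar(vmax, "vmax")
  px <- slice_pixels(slice)
  if (vmin > vmax) stopf("'vmin' must be <= 'vmax'")
  if (vmin == vmax) {
    warnf("vmin == vmax: constant-image degenerate case, returning zeros")
    out <- px * 0
  } else {
    out <- 2 * (pmin(pmax(px, vmin), vmax) - vmin) / (vmax - vmin) - 1
    dim(out) <- dim(px)
  }
  if (inherits(slice, "image_slice"))
    image_slice(out, spacing = slice$spacing, label = slice$label)
  else out
}

#' Invert the \[-1, 1\] rescaling back to physical intensities
#'
#' @inheritParams normalize
#' @return object of the same type on the `[vmin, vmax]` scale.
#' @export
denormalize <- function(slice, vmin, vmax) {
  check_scalar(vmin, "vmin"); check_scalar(vmax, "vmax")
  px <- slice_pixels(slice)
  out <- (px + 1) / 2 * (vmax - vmin) + vmin
  if (inherits(slice, "image_slice"))
    image_slice(out, spacing = slice$spacing, label = slice$label)
  else out
}

#' Normalize a slice pair onto one shared scale
#'
#' The scale is the per-pair min/max of the HQ member, shared by its LQ
#' member so both live on one intensity axis; the bounds are returned so
#' denormalization is exact.
#'
#' @param pair a [paired_sample()].
#' @return list with the normalized `pair` and the `vmin`, `vmax` used.
#' @export
normalize_pair <- function(pair) {
  stopifnot(inherits(pair, "paired_sample"))
  vmin <- min(pair$hq$pixels); vmax <- max(pair$hq$pixels)
  list(pair = paired_sample(normalize(pair$lq, vmin, vmax),
                            normalize(pair$hq, vmin, vmax)),
       vmin = vmin, vmax = vmax)
}

#' Read a NIfTI volume as a sequence of axial slices
#'
#' The axial axis is the third array axis; slices are returned in 0-based
#' index order with spacing taken from the header.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return list of [image_slice()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("volume not found: %s", path)
  vol <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("failed to read NIfTI '%s': %s",
                                            path, conditionMessage(e)))
  arr <- as.array(vol)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) stopf("'%s' is not a 2D/3D volume", path)
  pd <- RNifti::pixdim(vol)
  sp <- if (length(pd) >= 2L) pd[1:2] else c(1, 1)
  lapply(seq_len(dim(arr)[3]),
         function(k) image_slice(arr[, , k], spacing = sp))
}

#' Write a sequence of axial slices as a NIfTI volume
#'
#' The inverse of [read_volume()]: slices are stacked along the third axis.
#'
#' @param slices list of [image_slice()] (or matrices) with identical
#'   dimensions.
#' @param path output `.nii` or `.nii.gz` path.
#' @return invisibly, `path`.
#' @export
write_volume <- function(slices, path) {
  if (!length(slices)) stopf("'slices' must be nonempty")
  mats <- lapply(slices, slice_pixels)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), TRUE)))
    stopf("all slices must share the same dimensions")
  arr <- array(unlist(mats, use.names = FALSE), c(d, length(mats)))
  sp <- if (inherits(slices[[1]], "image_slice")) slices[[1]]$spacing else c(1, 1)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(sp, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}
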