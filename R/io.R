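#' Write and read volumes and masks as NIfTI
#'
#' Voxel spacing is stored in the NIfTI `pixdim` header field. Round trips
#' preserve array values exactly and spacing to float precision.
#'
#' @param x an [mri_volume()] or [mask_stack()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `save_volume`/`save_mask` return `path` invisibly;
#'   `load_volume` returns an [mri_volume()], `load_mask` a [mask_stack()].
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
save_volume <- function(x, path) {
  assert_that(inherits(x, "mri_volume"), "x must be an mri_volume")
  im <- RNifti::asNifti(x$data)
  RNifti::pixdim(im) <- x$spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname nifti_io
#' @param subject_id subject identifier attached to the loaded volume.
#' @param spacing optional numeric length-3 spacing override (mm); required
#'   when the file header carries no usable spacing.
#' @export
load_volume <- function(path, subject_id = basename(path), spacing = NULL) {
  im <- RNifti::readNifti(path)
  sp <- spacing %||% as.numeric(RNifti::pixdim(im))[1:3]
  if (length(sp) != 3 || any(!is.finite(sp)) || any(sp <= 0)) {
    stop("NIfTI header carries no usable voxel spacing; ",
         "supply it explicitly (CLI: --spacing AP,LR,CC in mm)",
         call. = FALSE)
  }
  arr <- as.array(im)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  if (any(!is.finite(arr))) {
    stop("volume contains NaN/Inf values; refusing to load", call. = FALSE)
  }
  mri_volume(arr, spacing = sp, subject_id = subject_id)
}

#' @rdname nifti_io
#' @export
save_mask <- function(x, path) {
  assert_that(inherits(x, "mask_stack"), "x must be a mask_stack")
  arr <- x$data
  storage.mode(arr) <- "double"
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- x$spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname nifti_io
#' @param id rater/model identifier for the loaded mask.
#' @param type `"binary"` or `"prob"`.
#' @export
load_mask <- function(path, id = basename(path), type = "binary",
                      spacing = NULL) {
  im <- RNifti::readNifti(path)
  sp <- spacing %||% as.numeric(RNifti::pixdim(im))[1:3]
  if (length(sp) != 3 || any(!is.finite(sp)) || any(sp <= 0)) {
    stop("NIfTI header carries no usable voxel spacing; ",
         "supply it explicitly (CLI: --spacing AP,LR,CC in mm)",
         call. = FALSE)
  }
  arr <- as.array(im)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  if (any(!is.finite(arr))) {
    stop("mask contains NaN/Inf values; refusing to load", call. = FALSE)
  }
  if (type == "binary" && !all(arr %in% c(0, 1))) {
    stop("mask file contains values outside {0, 1}; not a binary mask",
         call. = FALSE)
  }
  mask_stack(arr, spacing = sp, id = id, type = type)
}

#' Automated in-plane crop to the model grid
#'
#' Crops (or symmetrically zero-pads) every axial slice to `side x side`
#' pixels, the input size expected by the segmentation models. One window is
#' computed per subject - centred on the 3D intensity centre of mass - and
#' applied to all slices, so rater masks can be cropped congruently with
#' [apply_crop_window()].
#'
#' @param volume an [mri_volume()].
#' @param side target in-plane size in pixels (default 128).
#' @param pad allow symmetric zero-padding when an in-plane dimension is
#'   smaller than `side`.
#' @return An [mri_volume()] with `side x side` slices and a `crop_window`
#'   element recording the applied window (0-based offsets per in-plane
#'   axis; negative offsets denote padding).
#' @export
#' @examples
#' v <- mri_volume(array(runif(40 * 40 * 3), c(40, 40, 3)), c(1.3, 1.9, 4.4))
#' cv <- crop_to_model_grid(v, side = 32)
#' dim(cv$data)
crop_to_model_grid <- function(volume, side = 128L, pad = TRUE) {
  assert_that(inherits(volume, "mri_volume"), "volume must be an mri_volume")
  side <- as.integer(side)
  assert_that(side > 0, "side must be a positive integer")
  d <- dim(volume$data)
  w <- volume$data - min(volume$data)
  tot <- sum(w)
  com <- if (tot > 0) {
    c(sum(slice_sums(w, 1) * (seq_len(d[1]) - 1)) / tot,
      sum(slice_sums(w, 2) * (seq_len(d[2]) - 1)) / tot)
  } else {
    (d[1:2] - 1) / 2
  }
  offset <- integer(2)
  for (ax in 1:2) {
    if (d[ax] >= side) {
      o <- round(com[ax] - (side - 1) / 2)
      offset[ax] <- max(0L, min(as.integer(o), d[ax] - side))
    } else {
      if (!pad) {
        stop(sprintf("in-plane dimension %d (%d px) smaller than side %d and padding disabled",
                     ax, d[ax], side), call. = FALSE)
      }
      offset[ax] <- -as.integer(floor((side - d[ax]) / 2))
    }
  }
  window <- list(offset = offset, side = side, original_dim = d[1:2])
  out <- apply_window_array(volume$data, window)
  v <- mri_volume(out, spacing = volume$spacing,
                  subject_id = volume$subject_id)
  v$crop_window <- window
  v
}

#' Apply a recorded crop window to a congruent mask
#'
#' @param mask a [mask_stack()] with the same original shape as the volume
#'   the window was computed from.
#' @param window the `crop_window` element of a cropped [mri_volume()].
#' @return A cropped [mask_stack()].
#' @export
apply_crop_window <- function(mask, window) {
  assert_that(inherits(mask, "mask_stack"), "mask must be a mask_stack")
  assert_that(identical(dim(mask$data)[1:2], window$original_dim),
              "mask in-plane shape differs from the window's source shape")
  out <- apply_window_array(mask$data, window)
  mask_stack(out, spacing = mask$spacing, id = mask$id, type = mask$type)
}

# sum over all axes except `axis`
slice_sums <- function(x, axis) {
  apply(x, axis, sum)
}

apply_window_array <- function(arr, window) {
  d <- dim(arr)
  side <- window$side
  out <- array(0, dim = c(side, side, d[3]))
  src <- dst <- vector("list", 2)
  for (ax in 1:2) {
    o <- window$offset[ax]
    if (o >= 0) {
      src[[ax]] <- (o + 1):(o + side)
      dst[[ax]] <- seq_len(side)
    } else {
      src[[ax]] <- seq_len(d[ax])
      dst[[ax]] <- (-o + 1):(-o + d[ax])
    }
  }
  out[dst[[1]], dst[[2]], ] <- arr[src[[1]], src[[2]], , drop = FALSE]
  out
}
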