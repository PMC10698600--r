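#' MRI volume container
#'
#' A 3D intensity array with physical voxel spacing and anatomical axis
#' labels. The package-wide axis order is (AP, LR, CC): anteroposterior,
#' left-right, craniocaudal. The craniocaudal spacing of a 2D multisection
#' acquisition is the slice pitch (section thickness plus gap).
#'
#' @param intensities numeric 3D array of signal intensities (arbitrary
#'   units); must be finite.
#' @param spacing numeric length-3, mm per axis in (AP, LR, CC) order;
#'   strictly positive.
#' @param axis_labels character length-3 anatomical names; fixed default
#'   `c("AP", "LR", "CC")`.
#' @param subject_id subject identifier string.
#' @return An object of class `mri_volume`.
#' @export
#' @examples
#' v <- mri_volume(array(runif(8 * 8 * 4), c(8, 8, 4)), spacing = c(1.3, 1.9, 4.4))
#' dim(v$data)
mri_volume <- function(intensities, spacing, axis_labels = c("AP", "LR", "CC"),
                       subject_id = "subject") {
  assert_that(is.array(intensities) && length(dim(intensities)) == 3,
              "intensities must be a 3D array")
  assert_that(all(is.finite(intensities)),
              "intensities contain NaN/Inf; volumes must be finite")
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 3 && all(spacing > 0),
              "spacing must be 3 strictly positive values (mm)")
  assert_that(identical(toupper(axis_labels), c("AP", "LR", "CC")),
              "axis_labels must be c('AP','LR','CC'); the axis order is fixed")
  structure(
    list(data = intensities, spacing = spacing,
         axis_labels = c("AP", "LR", "CC"),
         subject_id = as.character(subject_id)),
    class = "mri_volume"
  )
}

#' Binary or probabilistic mask container
#'
#' A mask congruent with an [mri_volume()]: same array shape and spacing.
#' Binary masks contain only 0/1; probabilistic masks values in \[0, 1\].
#'
#' @param values numeric 3D array.
#' @param spacing numeric length-3 mm per axis (AP, LR, CC).
#' @param id rater or model identifier string.
#' @param type `"binary"` or `"prob"`.
#' @return An object of class `mask_stack`.
#' @export
mask_stack <- function(values, spacing, id = "mask",
                       type = c("binary", "prob")) {
  type <- match.arg(type)
  assert_that(is.array(values) && length(dim(values)) == 3,
              "mask values must be a 3D array")
  assert_that(all(is.finite(values)), "mask contains NaN/Inf")
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 3 && all(spacing > 0),
              "spacing must be 3 strictly positive values (mm)")
  if (type == "binary") {
    assert_that(all(values %in% c(0, 1)),
                "binary mask may contain only 0 and 1")
    storage.mode(values) <- "integer"
  } else {
    assert_that(all(values >= 0 & values <= 1),
                "probabilistic mask values must lie in [0, 1]")
  }
  structure(
    list(data = values, spacing = spacing, id = as.character(id),
         type = type),
    class = "mask_stack"
  )
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<mri_volume '%s'> %d x %d x %d voxels (AP x LR x CC), spacing %.2f x %.2f x %.2f mm\n",
    x$subject_id, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<mask_stack '%s' (%s)> %d x %d x %d voxels, %d foreground (%.1f%%)\n",
    x$id, x$type, d[1], d[2], d[3], sum(x$data > 0.5),
    100 * mean(x$data > 0.5)
  ))
  invisible(x)
}

congruent <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

as_mask_array <- function(m) {
  if (inherits(m, "mask_stack")) m$data else m
}
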