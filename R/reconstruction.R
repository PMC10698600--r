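#' 3D connected components of a binary mask
#'
#' Labels components under 26-connectivity. Components are relabeled
#' deterministically in decreasing voxel-count order (ties broken by scan
#' order of the first voxel).
#'
#' @param mask a nonempty binary [mask_stack()] (or 3D 0/1 array).
#' @return A list with `labels` (integer array, 1 = largest component) and
#'   `sizes` (voxel counts, decreasing).
#' @export
connected_components_3d <- function(mask) {
  m <- as_mask_array(mask)
  assert_that(all(m %in% c(0, 1)), "mask must be binary")
  assert_that(sum(m) > 0, "mask is empty; no components to label")
  raw <- cpp_label26(as.integer(m), dim(m))
  k <- attr(raw, "n_components")
  sizes <- tabulate(raw, nbins = k)
  ord <- order(-sizes, seq_len(k))
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  lab <- array(0L, dim = dim(m))
  nz <- raw != 0L
  lab[nz] <- remap[raw[nz]]
  list(labels = lab, sizes = sizes[ord])
}

#' Split labeled components into left and right lungs
#'
#' Keeps the two largest components and assigns them to the left and right
#' lung by centroid order along the LR axis: under the package's
#' radiological convention the left lung has the smaller LR world
#' coordinate. Smaller components (noise specks) are discarded with a
#' warning.
#'
#' @param components result of [connected_components_3d()].
#' @param spacing voxel spacing in mm (AP, LR, CC).
#' @return A list with `labels` (0 background, 1 left, 2 right) and
#'   `n_discarded`.
#' @export
split_lungs <- function(components, spacing) {
  assert_that(length(components$sizes) >= 2,
              "need at least 2 components to identify two lungs")
  lab <- components$labels
  n_discarded <- length(components$sizes) - 2L
  if (n_discarded > 0) {
    warning(sprintf("discarded %d small component(s) beyond the two largest",
                    n_discarded))
  }
  lr_centroid <- function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    mean((idx[, 2] - 1) * spacing[2])
  }
  c1 <- lr_centroid(1L)
  c2 <- lr_centroid(2L)
  if (abs(c1 - c2) < spacing[2]) {
    stop("the two largest components overlap in LR centroid; ",
         "left/right assignment is ambiguous", call. = FALSE)
  }
  out <- array(0L, dim = dim(lab))
  if (c1 < c2) {
    out[lab == 1L] <- 1L
    out[lab == 2L] <- 2L
  } else {
    out[lab == 1L] <- 2L
    out[lab == 2L] <- 1L
  }
  list(labels = out, n_discarded = n_discarded)
}

#' Build a two-lung 3D reconstruction from a binary mask
#'
#' Thresholded mask to physical 3D representation: 26-connected components,
#' retention of the two largest (the lungs), left/right assignment, and
#' alignment to a canonical anatomical frame via [align_reference_frame()].
#'
#' @param mask a binary [mask_stack()].
#' @param volume optional [mri_volume()] supplying the source intensities
#'   (required by intensity features).
#' @param align rotate to the canonical frame (default `TRUE`).
#' @return An object of class `lung_recon`: `labels` (0/1/2 array),
#'   `spacing`, `intensities`, `rotation` (3x3, aligned = R (x - center)),
#'   `center`, `voxel_counts`, `n_discarded`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 16)))
#' rec <- reconstruct_lungs(ph$mask, ph$volume)
#' lung_volume(rec, "left")
reconstruct_lungs <- function(mask, volume = NULL, align = TRUE) {
  assert_that(inherits(mask, "mask_stack") && mask$type == "binary",
              "mask must be a binary mask_stack")
  if (!is.null(volume)) {
    assert_that(congruent(volume, mask),
                "volume and mask must be congruent")
  }
  comp <- connected_components_3d(mask)
  if (length(comp$sizes) < 2) {
    stop("found only one 3D component; cannot identify two lungs",
         call. = FALSE)
  }
  sp <- split_lungs(comp, mask$spacing)
  rec <- structure(
    list(labels = sp$labels, spacing = mask$spacing,
         intensities = if (!is.null(volume)) volume$data else NULL,
         rotation = diag(3), center = c(0, 0, 0), aligned = FALSE,
         voxel_counts = c(left = sum(sp$labels == 1L),
                          right = sum(sp$labels == 2L)),
         n_discarded = sp$n_discarded,
         subject_id = if (!is.null(volume)) volume$subject_id else mask$id),
    class = "lung_recon"
  )
  if (align) rec <- align_reference_frame(rec) else rec
}

#' @export
print.lung_recon <- function(x, ...) {
  cat(sprintf(
    "<lung_recon '%s'> left %d / right %d voxels, %s\n",
    x$subject_id, x$voxel_counts["left"], x$voxel_counts["right"],
    if (x$aligned) "aligned to canonical frame" else "native frame"
  ))
  invisible(x)
}

# world coordinates (mm) of labeled voxels, optionally one side only
recon_coords <- function(rec, side = NULL) {
  sel <- if (is.null(side)) {
    rec$labels > 0L
  } else {
    rec$labels == side_code(side)
  }
  idx <- which(sel, arr.ind = TRUE)
  w <- sweep(idx - 1, 2, rec$spacing, "*")
  att <- if (!is.null(rec$intensities)) rec$intensities[sel] else NULL
  list(world = w, intensities = att)
}

# aligned-frame coordinates of labeled voxels
recon_aligned_coords <- function(rec, side = NULL) {
  rc <- recon_coords(rec, side)
  rc$world <- unname(sweep(rc$world, 2, rec$center) %*% t(rec$rotation))
  rc
}

side_code <- function(side) {
  switch(match.arg(side, c("left", "right")), left = 1L, right = 2L)
}

#' Align a reconstruction to the canonical anatomical frame
#'
#' Rotates world coordinates so the principal inertia axes of the combined
#' two-lung mask coincide with the coordinate axes. Each principal axis is
#' assigned to the anatomical axis (AP, LR or CC) it is most aligned with
#' in the acquisition frame, so axis-labelled features keep their
#' anatomical meaning even when, as for side-by-side lungs, the largest
#' principal axis is the left-right separation. Axis directions are fixed
#' deterministically and geometrically: the canonical LR axis points from
#' the left towards the right lung centroid; the CC sign is chosen so the
#' shape skewness of the voxel coordinates along CC is non-negative
#' (falling back to alignment with the acquisition CC axis when the
#' skewness is numerically zero); and AP completes the right-handed frame
#' (`AP = LR x CC`), so the rotation is always proper (determinant +1).
#' The frame depends on geometry only, never on the intensity
#' distribution. Near-degenerate inertia (two equal eigenvalues) falls
#' back to the current frame with a warning.
#'
#' @param rec a [reconstruct_lungs()] result.
#' @return The reconstruction with updated `rotation` and `center`;
#'   aligning twice is idempotent to numerical tolerance. The left lung
#'   sits at negative LR in the aligned frame.
#' @export
align_reference_frame <- function(rec) {
  assert_that(inherits(rec, "lung_recon"), "rec must be a lung_recon")
  rc <- recon_aligned_coords(rec)
  w <- rc$world
  ctr <- colMeans(w)
  wc <- sweep(w, 2, ctr)
  C <- crossprod(wc) / nrow(wc)
  eg <- eigen(C, symmetric = TRUE)
  lam <- eg$values
  if ((lam[1] - lam[2]) / lam[1] < 1e-6 || (lam[2] - lam[3]) / lam[1] < 1e-6) {
    warning("degenerate inertia tensor (near-spherical shape); keeping current frame")
    return(rec)
  }
  V <- eg$vectors
  # assign eigenvectors to anatomical axes: maximize total |alignment|
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  score <- vapply(perms, function(p) {
    abs(V[1, p[1]]) + abs(V[2, p[2]]) + abs(V[3, p[3]])
  }, 1.0)
  p <- perms[[which.max(score)]]
  lr <- V[, p[2]]
  cc <- V[, p[3]]

  # LR direction: from the left towards the right lung centroid
  cl <- colMeans(recon_aligned_coords(rec, "left")$world)
  cr <- colMeans(recon_aligned_coords(rec, "right")$world)
  if (sum((cr - cl) * lr) < 0) lr <- -lr

  # CC direction: non-negative shape skewness, geometric fallback
  proj <- as.numeric(wc %*% cc)
  s2 <- mean((proj - mean(proj))^2)
  s3 <- mean((proj - mean(proj))^3)
  skew <- if (s2 > 0) s3 / s2^1.5 else 0
  if (abs(skew) > 1e-3) {
    if (skew < 0) cc <- -cc
  } else if (cc[3] < 0) {
    cc <- -cc
  }

  # AP completes the right-handed frame
  ap <- c(lr[2] * cc[3] - lr[3] * cc[2],
          lr[3] * cc[1] - lr[1] * cc[3],
          lr[1] * cc[2] - lr[2] * cc[1])
  R_inc <- rbind(AP = ap, LR = lr, CC = cc)

  # compose with any existing alignment: aligned = R_inc (R_old (x - c_old) - ctr)
  rotation <- R_inc %*% rec$rotation
  center <- rec$center + t(rec$rotation) %*% ctr
  out <- rec
  out$rotation <- rotation
  out$center <- as.numeric(center)
  out$aligned <- TRUE
  out
}

#' Physical lung volume
#'
#' Voxel count times the voxel volume; the craniocaudal spacing is the
#' slice pitch (section thickness + gap), so a 1.3 x 1.9 x 4.4 mm grid
#' contributes 10.868 mm^3 per voxel.
#'
#' @param rec a [reconstruct_lungs()] result.
#' @param side `"left"` or `"right"`.
#' @return Volume in mm^3 (0 with a warning for an empty side).
#' @export
lung_volume <- function(rec, side) {
  assert_that(inherits(rec, "lung_recon"), "rec must be a lung_recon")
  code <- side_code(side)
  n <- sum(rec$labels == code)
  if (n == 0) {
    warning(sprintf("%s lung is empty", side))
    return(0)
  }
  n * prod(rec$spacing)
}
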