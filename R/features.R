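#' The frozen 78-feature manifest
#'
#' The named roster of the 78 morphologic lung features: 39 per lung
#' (19 volumetric, 15 intensity, 5 surface), prefixed `left_` / `right_`,
#' for a partition of 38 volumetric / 30 intensity / 10 surface features in
#' total. Ordering and naming are frozen; downstream tables, cohorts and
#' models key on these names.
#'
#' @return A tibble with columns `name`, `side`, `base`, `category`,
#'   `units` (empty string = dimensionless) and `description`.
#' @export
#' @examples
#' dplyr::count(feature_manifest(), category)
feature_manifest <- function() {
  vol <- tibble::tribble(
    ~base, ~units, ~description,
    "volume_mm3", "mm3", "lung volume (voxel count x voxel volume)",
    "bbox_extent_ap_mm", "mm", "bounding-box extent along AP",
    "bbox_extent_lr_mm", "mm", "bounding-box extent along LR",
    "bbox_extent_cc_mm", "mm", "bounding-box extent along CC",
    "centroid_ap_mm", "mm", "geometric centroid, AP, canonical frame",
    "centroid_lr_mm", "mm", "geometric centroid, LR, canonical frame",
    "centroid_cc_mm", "mm", "geometric centroid, CC, canonical frame",
    "inertia_major_mm2", "mm^2", "largest principal second moment",
    "inertia_intermediate_mm2", "mm^2", "intermediate principal second moment",
    "inertia_minor_mm2", "mm^2", "smallest principal second moment",
    "axis_major_mm", "mm", "equivalent-ellipsoid major axis length",
    "axis_intermediate_mm", "mm", "equivalent-ellipsoid intermediate axis length",
    "axis_minor_mm", "mm", "equivalent-ellipsoid minor axis length",
    "elongation", "", "major / minor equivalent axis length (>= 1)",
    "equiv_diameter_mm", "mm", "diameter of the equal-volume sphere",
    "extent", "", "volume / bounding-box volume",
    "moment2_ap_mm2", "mm^2", "second central moment along AP",
    "moment2_lr_mm2", "mm^2", "second central moment along LR",
    "moment2_cc_mm2", "mm^2", "second central moment along CC"
  )
  vol$category <- "volumetric"
  intens <- tibble::tribble(
    ~base, ~units, ~description,
    "intensity_mean", "a.u.", "mean lung signal intensity",
    "intensity_sd", "a.u.", "intensity standard deviation",
    "intensity_median", "a.u.", "median intensity",
    "intensity_min", "a.u.", "minimum intensity",
    "intensity_max", "a.u.", "maximum intensity",
    "intensity_skewness", "", "intensity distribution skewness",
    "intensity_kurtosis", "", "intensity distribution excess kurtosis",
    "intensity_p10", "a.u.", "10th intensity percentile",
    "intensity_p90", "a.u.", "90th intensity percentile",
    "intensity_entropy", "bits", "Shannon entropy of the 32-bin intensity histogram",
    "wcentroid_ap_mm", "mm", "intensity-weighted centroid, AP",
    "wcentroid_lr_mm", "mm", "intensity-weighted centroid, LR",
    "wcentroid_cc_mm", "mm", "intensity-weighted centroid, CC",
    "centroid_disp_ap", "", "(weighted - geometric AP centroid) / AP extent",
    "centroid_disp_cc", "", "(weighted - geometric CC centroid) / CC extent"
  )
  intens$category <- "intensity"
  surf <- tibble::tribble(
    ~base, ~units, ~description,
    "surface_area_mm2", "mm2", "iso-surface mesh area",
    "surface_to_volume_mm1", "mm^-1", "mesh area / lung volume",
    "hull_area_mm2", "mm2", "convex-hull surface area",
    "roughness", "", "volumetric surface roughness: mesh area / hull area (>= 1)",
    "solidity", "", "lung voxels / convex-hull voxels (<= 1)"
  )
  surf$category <- "surface"
  per_side <- dplyr::bind_rows(vol, intens, surf)
  out <- dplyr::bind_rows(
    dplyr::mutate(per_side, side = "left"),
    dplyr::mutate(per_side, side = "right")
  )
  out$name <- paste0(out$side, "_", out$base)
  out[, c("name", "side", "base", "category", "units", "description")]
}

#' Volumetric shape features of one lung
#'
#' Nineteen values computed from the voxel coordinates in the canonical
#' (aligned) frame: volume; bounding-box extent per axis; centroid per
#' axis; the three principal second moments (eigenvalues of the
#' second-central-moment tensor, with the voxel self-moment
#' `spacing^2/12` included); equivalent-ellipsoid axis lengths
#' `2*sqrt(5*lambda)`; elongation (major/minor axis length); the
#' equivalent-sphere diameter; extent (volume / bounding-box volume); and
#' the axis-aligned second central moments.
#'
#' @param rec an aligned [reconstruct_lungs()] result.
#' @param side `"left"` or `"right"`.
#' @return A named numeric vector of 19 features.
#' @export
volumetric_features <- function(rec, side) {
  rc <- recon_aligned_coords(rec, side)
  n <- nrow(rc$world)
  assert_that(n > 0, sprintf("%s lung is empty", side))
  w <- rc$world
  sp <- rec$spacing
  vox <- prod(sp)
  volume <- n * vox
  ext <- apply(w, 2, function(x) diff(range(x))) + sp
  ctr <- colMeans(w)
  wc <- sweep(w, 2, ctr)
  C <- crossprod(wc) / n + rec$rotation %*% diag(sp^2 / 12) %*% t(rec$rotation)
  lam <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  axes <- 2 * sqrt(5 * lam)
  c(volume_mm3 = volume,
    bbox_extent_ap_mm = ext[1], bbox_extent_lr_mm = ext[2],
    bbox_extent_cc_mm = ext[3],
    centroid_ap_mm = ctr[1], centroid_lr_mm = ctr[2], centroid_cc_mm = ctr[3],
    inertia_major_mm2 = lam[1], inertia_intermediate_mm2 = lam[2],
    inertia_minor_mm2 = lam[3],
    axis_major_mm = axes[1], axis_intermediate_mm = axes[2],
    axis_minor_mm = axes[3],
    elongation = axes[1] / axes[3],
    equiv_diameter_mm = (6 * volume / pi)^(1 / 3),
    extent = volume / prod(ext),
    moment2_ap_mm2 = C[1, 1], moment2_lr_mm2 = C[2, 2],
    moment2_cc_mm2 = C[3, 3])
}

#' Intensity features of one lung
#'
#' Fifteen values: descriptive statistics of the raw lung voxel
#' intensities (mean, SD, median, min, max, skewness, excess kurtosis,
#' 10th/90th percentile, 32-bin histogram entropy), the intensity-weighted
#' centroid per axis, and the normalized centroid displacements along AP
#' and CC: `(weighted - geometric centroid) / axis extent`, a
#' ventilation-inhomogeneity proxy. Raw intensities serve as the centroid
#' weights (shifted only if negative values are present); a
#' constant-intensity lung yields skewness/kurtosis of 0 and is flagged
#' via the `constant_intensity` attribute.
#'
#' @inheritParams volumetric_features
#' @return A named numeric vector of 15 features.
#' @export
intensity_features <- function(rec, side) {
  assert_that(!is.null(rec$intensities),
              "reconstruction carries no source intensities")
  rc <- recon_aligned_coords(rec, side)
  n <- nrow(rc$world)
  assert_that(n > 0, sprintf("%s lung is empty", side))
  v <- rc$intensities
  constant <- stats::sd(v) == 0
  # raw intensities as weights; shift only when negatives are present so
  # the gradient magnitude is preserved in the weighted centroid
  wgt <- if (min(v) < 0) v - min(v) else v
  if (sum(wgt) <= 0) wgt <- rep(1, n)
  wctr <- colSums(rc$world * wgt) / sum(wgt)
  ctr <- colMeans(rc$world)
  ext <- apply(rc$world, 2, function(x) diff(range(x))) + rec$spacing
  out <- c(
    intensity_mean = mean(v), intensity_sd = stats::sd(v),
    intensity_median = stats::median(v),
    intensity_min = min(v), intensity_max = max(v),
    intensity_skewness = moment_skewness(v),
    intensity_kurtosis = moment_kurtosis_excess(v),
    intensity_p10 = stats::quantile(v, 0.1, names = FALSE),
    intensity_p90 = stats::quantile(v, 0.9, names = FALSE),
    intensity_entropy = sample_entropy_bits(v),
    wcentroid_ap_mm = wctr[1], wcentroid_lr_mm = wctr[2],
    wcentroid_cc_mm = wctr[3],
    centroid_disp_ap = (wctr[1] - ctr[1]) / ext[1],
    centroid_disp_cc = (wctr[3] - ctr[3]) / ext[3]
  )
  attr(out, "constant_intensity") <- constant
  out
}

#' Surface features of one lung
#'
#' Five values from the iso-surface of the lung label: mesh surface area,
#' surface-to-volume ratio, convex-hull surface area, volumetric surface
#' roughness (mesh area / hull area, floored at its convex limit 1) and
#' solidity (lung voxels / convex-hull voxels, capped at 1). The binary
#' label is smoothed with a spacing-aware Gaussian (sigma = 1 voxel per
#' axis) before extracting the 0.5 iso-surface, removing the voxelization
#' staircase that would otherwise inflate the area.
#'
#' @inheritParams volumetric_features
#' @return A named numeric vector of 5 features.
#' @export
surface_features <- function(rec, side) {
  code <- side_code(side)
  m <- rec$labels == code
  nvox <- sum(m)
  if (nvox < 8) {
    stop(sprintf("degenerate mesh: %s lung has only %d voxels", side, nvox),
         call. = FALSE)
  }
  sp <- rec$spacing
  # pad so the iso-surface closes at the array border
  d <- dim(m)
  pad <- 3L
  f <- array(0, dim = d + 2L * pad)
  f[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- m
  f <- cpp_gaussian_blur3(f, c(1, 1, 1))
  mt <- cpp_marching_tets(f, 0.5, sp)
  if (mt$n_triangles == 0) {
    stop(sprintf("degenerate mesh: no iso-surface for the %s lung (%d voxels)",
                 side, nvox), call. = FALSE)
  }
  verts <- unique(round(mt$vertices / (0.25 * min(sp))) * (0.25 * min(sp)))
  hull <- cpp_convex_hull3(verts)
  # rasterize the hull on the padded voxel grid and count interior centers
  idx <- which(m, arr.ind = TRUE)
  lo <- apply(idx, 2, min) - 2L
  hi <- apply(idx, 2, max) + 2L
  hull_vox <- cpp_hull_voxel_count(hull$normals, hull$offsets,
                                   as.integer(lo - 1L + pad),
                                   as.integer(hi - 1L + pad),
                                   sp, 1e-9)
  volume <- nvox * prod(sp)
  c(surface_area_mm2 = mt$area,
    surface_to_volume_mm1 = mt$area / volume,
    hull_area_mm2 = hull$area,
    roughness = max(1, mt$area / hull$area),
    solidity = min(1, nvox / hull_vox))
}

#' Extract the full 78-feature set from a reconstruction
#'
#' Concatenates the per-lung volumetric, intensity and surface features
#' with the frozen naming of [feature_manifest()]: exactly 78 values,
#' 39 per lung, partitioned 38 volumetric / 30 intensity / 10 surface.
#'
#' @param rec an aligned two-lung [reconstruct_lungs()] result with source
#'   intensities.
#' @return A tibble of class `lung_feature_set` with columns `name`,
#'   `side`, `base`, `category`, `units`, `value`; attribute `subject_id`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 16)))
#' fs <- extract_features(reconstruct_lungs(ph$mask, ph$volume))
#' nrow(fs)
extract_features <- function(rec) {
  assert_that(inherits(rec, "lung_recon"), "rec must be a lung_recon")
  if (!rec$aligned) rec <- align_reference_frame(rec)
  manifest <- feature_manifest()
  vals <- numeric(0)
  for (side in c("left", "right")) {
    block <- tryCatch(
      c(volumetric_features(rec, side),
        intensity_features(rec, side),
        surface_features(rec, side)),
      error = function(e) {
        stop(sprintf("feature extraction failed for the %s lung: %s",
                     side, conditionMessage(e)), call. = FALSE)
      }
    )
    names(block) <- paste0(side, "_", names(block))
    vals <- c(vals, block)
  }
  assert_that(identical(names(vals), manifest$name),
              "internal error: feature roster out of sync with the manifest")
  out <- manifest
  out$value <- unname(vals)
  class(out) <- c("lung_feature_set", class(out))
  attr(out, "subject_id") <- rec$subject_id
  out
}

#' @export
print.lung_feature_set <- function(x, ...) {
  cat(sprintf("<lung_feature_set '%s'> %d features (",
              attr(x, "subject_id") %||% "?", nrow(x)))
  cnt <- table(x$category)
  cat(paste(sprintf("%s %d", names(cnt), cnt), collapse = ", "), ")\n")
  NextMethod()
  invisible(x)
}

#' Widen feature sets into a one-row-per-subject table
#'
#' @param feature_sets a list of [extract_features()] results.
#' @return A tibble with `subject_id` plus the 78 feature columns.
#' @export
feature_table <- function(feature_sets) {
  rows <- lapply(feature_sets, function(fs) {
    v <- stats::setNames(as.list(fs$value), fs$name)
    tibble::as_tibble(c(list(subject_id = attr(fs, "subject_id") %||% NA_character_), v))
  })
  dplyr::bind_rows(rows)
}
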