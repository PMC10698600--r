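test_that("feature roster is frozen: 78 names, 38/30/10 split, stable hash", {
  man <- feature_manifest()
  expect_equal(nrow(man), 78)
  cnt <- table(man$category)
  expect_equal(unname(cnt[c("volumetric", "intensity", "surface")]),
               c(38L, 30L, 10L), ignore_attr = TRUE)
  expect_equal(sum(man$side == "left"), 39)
  tf <- withr::local_tempfile()
  writeLines(paste(man$name, collapse = "|"), tf)
  expect_identical(unname(tools::md5sum(tf)), "348fd08459a336a477b812d63bb18452")
})

test_that("extraction yields 78 finite values with the invariant ranges", {
  ph <- training_phantom(3)
  fs <- extract_features(reconstruct_lungs(ph$mask, ph$volume))
  expect_s3_class(fs, "lung_feature_set")
  expect_equal(nrow(fs), 78)
  expect_true(all(is.finite(fs$value)))
  val <- stats::setNames(fs$value, fs$name)
  for (side in c("left", "right")) {
    expect_gte(val[paste0(side, "_elongation")], 1)
    expect_gte(val[paste0(side, "_roughness")], 1)
    expect_gt(val[paste0(side, "_solidity")], 0)
    expect_lte(val[paste0(side, "_solidity")], 1)
  }
  expect_identical(tidy(fs)$value, fs$value)
})

test_that("sphere and ellipsoid oracles: symmetry, elongation, inertia", {
  ph <- sphere_phantom(r = 14, spacing = 1.5)
  rec <- reconstruct_lungs(ph$mask, ph$volume)
  vf <- volumetric_features(rec, "left")  # the sphere
  expect_equal(unname(vf["elongation"]), 1, tolerance = 0.02)
  lam <- unname(vf[c("inertia_major_mm2", "inertia_intermediate_mm2",
                     "inertia_minor_mm2")])
  expect_lt((lam[1] - lam[3]) / lam[1], 0.03)
  # equivalent axis of a sphere = diameter
  expect_equal(unname(vf["axis_major_mm"]), 28, tolerance = 0.8)
  expect_equal(unname(vf["equiv_diameter_mm"]),
               (6 * unname(vf["volume_mm3"]) / pi)^(1 / 3))
  inf <- intensity_features(rec, "left")
  expect_equal(unname(inf["centroid_disp_ap"]), 0, tolerance = 5e-3)

  # (30, 15, 15) ellipsoid at 1 mm: elongation within 2% of 2.0
  ph2 <- generate_phantom(phantom_spec(
    grid_shape = c(80, 120, 80), spacing = c(1, 1, 1),
    left_semi_axes = c(30, 15, 15), right_semi_axes = c(30, 15, 15),
    left_center = c(40, 30, 40), right_center = c(40, 90, 40), noise_sd = 0
  ))
  vf2 <- volumetric_features(reconstruct_lungs(ph2$mask, ph2$volume), "left")
  expect_equal(unname(vf2["elongation"]), 2, tolerance = 0.02)
})

test_that("constant-intensity lungs yield flagged zero skewness/kurtosis", {
  ph <- training_phantom(1)
  flat <- mri_volume(array(0.3, dim(ph$volume$data)), ph$volume$spacing)
  rec <- reconstruct_lungs(ph$mask, flat)
  inf <- intensity_features(rec, "left")
  expect_true(attr(inf, "constant_intensity"))
  expect_equal(unname(inf["intensity_skewness"]), 0)
  expect_equal(unname(inf["intensity_kurtosis"]), 0)
  expect_equal(unname(inf["intensity_sd"]), 0)
})

test_that("whole-voxel translation leaves canonical-frame features unchanged", {
  base <- list(grid_shape = c(52, 72, 48), spacing = c(1, 1, 1),
               left_semi_axes = c(11, 8, 15), right_semi_axes = c(12, 9, 16),
               noise_sd = 0, seed = 4)
  ph1 <- generate_phantom(do.call(phantom_spec, c(base, list(
    left_center = c(24, 20, 24), right_center = c(24, 50, 24)))))
  ph2 <- generate_phantom(do.call(phantom_spec, c(base, list(
    left_center = c(27, 22, 25), right_center = c(27, 52, 25)))))
  f1 <- extract_features(reconstruct_lungs(ph1$mask, ph1$volume))
  f2 <- extract_features(reconstruct_lungs(ph2$mask, ph2$volume))
  vol_rows <- f1$category %in% c("volumetric", "surface")
  expect_equal(f1$value[vol_rows], f2$value[vol_rows], tolerance = 1e-8)
})

test_that("isotropic scaling by 2 scales features by the expected powers", {
  mk <- function(s) generate_phantom(phantom_spec(
    grid_shape = c(44, 64, 44) * s, spacing = c(1, 1, 1),
    left_semi_axes = c(11, 8, 14) * s, right_semi_axes = c(11, 8, 14) * s,
    left_center = c(22, 16, 22) * s, right_center = c(22, 48, 22) * s,
    noise_sd = 0
  ))
  f1 <- extract_features(reconstruct_lungs(mk(1)$mask, mk(1)$volume))
  f2 <- extract_features(reconstruct_lungs(mk(2)$mask, mk(2)$volume))
  v1 <- stats::setNames(f1$value, f1$name)
  v2 <- stats::setNames(f2$value, f2$name)
  expect_equal(unname(v2["left_volume_mm3"] / v1["left_volume_mm3"]), 8,
               tolerance = 0.03)
  expect_equal(unname(v2["left_surface_area_mm2"] / v1["left_surface_area_mm2"]),
               4, tolerance = 0.03)
  expect_equal(unname(v2["left_axis_major_mm"] / v1["left_axis_major_mm"]), 2,
               tolerance = 0.03)
  # extent is excluded: its one-voxel bounding-box padding makes it
  # converge to scale invariance only as the grid refines
  for (nm in c("left_elongation", "left_solidity", "left_roughness")) {
    expect_equal(unname(v2[nm] / v1[nm]), 1, tolerance = 0.03)
  }
})

test_that("mirroring swaps the left/right feature blocks (LR-sign-free features)", {
  ph <- training_phantom(5)
  flip <- function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  f <- extract_features(reconstruct_lungs(ph$mask, ph$volume))
  mf <- extract_features(reconstruct_lungs(
    mask_stack(flip(ph$mask$data), ph$mask$spacing),
    mri_volume(flip(ph$volume$data), ph$volume$spacing)
  ))
  v <- stats::setNames(f$value, f$name)
  vm <- stats::setNames(mf$value, mf$name)
  swap_free <- c("volume_mm3", "elongation", "surface_area_mm2", "roughness",
                 "solidity", "intensity_mean", "intensity_entropy",
                 "bbox_extent_ap_mm", "moment2_cc_mm2")
  for (nm in swap_free) {
    expect_equal(unname(v[paste0("left_", nm)]),
                 unname(vm[paste0("right_", nm)]), tolerance = 1e-6)
    expect_equal(unname(v[paste0("right_", nm)]),
                 unname(vm[paste0("left_", nm)]), tolerance = 1e-6)
  }
  # signed LR centroids flip sign under mirroring
  expect_equal(unname(v["left_centroid_lr_mm"]),
               -unname(vm["right_centroid_lr_mm"]), tolerance = 1e-6)
})

test_that("feature table widens one row per subject with all 78 columns", {
  ph <- training_phantom(6)
  fs <- extract_features(reconstruct_lungs(ph$mask, ph$volume))
  tab <- feature_table(list(fs, fs))
  expect_equal(dim(tab), c(2L, 79L))
  expect_identical(names(tab)[-1], feature_manifest()$name)
})
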