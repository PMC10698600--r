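test_that("phantom analytic truth matches closed forms and degenerate noise is exact", {
  ph <- sphere_phantom(r = 20)
  # sphere: 4/3 * pi * 20^3
  expect_equal(ph$truth$left$volume_mm3, 4 / 3 * pi * 20^3, tolerance = 1e-10)
  expect_equal(ph$truth$left$volume_mm3, 33510.32, tolerance = 1e-6)
  # Knud Thomsen reduces to 4 pi r^2 for a sphere
  expect_equal(ph$truth$left$surface_area_mm2, 4 * pi * 400, tolerance = 1e-10)
  # ellipsoid formula check computed independently here
  p <- 1.6075
  a <- 15; b <- 12; c <- 18
  expect_equal(ph$truth$right$surface_area_mm2,
               4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p),
               tolerance = 1e-10)
  expect_equal(ph$truth$right$volume_mm3, 4 / 3 * pi * a * b * c)
  # noise_sd = 0, no gradient: a single shared lung intensity
  expect_length(unique(ph$volume$data[ph$mask$data == 1]), 1L)
})

test_that("fixed seed reproduces phantoms bitwise; geometry errors name the axis", {
  s1 <- sphere_phantom(r = 15, noise_sd = 0.05, seed = 9)
  s2 <- sphere_phantom(r = 15, noise_sd = 0.05, seed = 9)
  expect_identical(s1$volume$data, s2$volume$data)
  expect_identical(s1$mask$data, s2$mask$data)
  s3 <- sphere_phantom(r = 15, noise_sd = 0.05, seed = 10)
  expect_false(identical(s1$volume$data, s3$volume$data))
  expect_error(
    phantom_spec(grid_shape = c(40, 60, 40), spacing = c(1, 1, 1),
                 left_semi_axes = c(10, 10, 25),
                 left_center = c(20, 15, 20)),
    "CC axis"
  )
})

test_that("voxelized mask volume converges to the analytic ellipsoid volume", {
  semi <- c(18, 12, 14)
  err_at <- function(s) {
    ph <- generate_phantom(phantom_spec(
      grid_shape = round(c(48, 64, 40) / s), spacing = c(s, s, s),
      left_semi_axes = semi, right_semi_axes = semi,
      left_center = c(24, 16, 20), right_center = c(24, 48, 20),
      noise_sd = 0
    ))
    vox <- sum(ph$mask$data) / 2 * s^3  # two identical lungs
    abs(vox / (4 / 3 * pi * prod(semi)) - 1)
  }
  errs <- vapply(c(2, 1, 0.5), err_at, 1.0)
  expect_true(all(diff(errs) < 0))  # strictly decreasing error
  expect_lt(errs[3], 0.01)
})

test_that("rater simulation: exact copies at zero jitter, calibrated overlap at 2 mm", {
  ph <- sphere_phantom(r = 20)
  r0 <- simulate_raters(ph$mask, n_raters = 3, boundary_jitter_mm = 0)
  expect_length(r0, 3)
  expect_equal(volumetric_dice(r0[[1]], r0[[2]]), 1.0)
  expect_identical(r0[[1]]$data, ph$mask$data)

  r2 <- simulate_raters(ph$mask, n_raters = 3, boundary_jitter_mm = 2, seed = 4)
  d <- c(volumetric_dice(r2[[1]], r2[[2]]),
         volumetric_dice(r2[[1]], r2[[3]]),
         volumetric_dice(r2[[2]], r2[[3]]))
  expect_true(all(d < 1))
  expect_true(all(d > 0.8))

  r1 <- simulate_raters(ph$mask, n_raters = 1, boundary_jitter_mm = 1, seed = 2)
  expect_length(r1, 1)
  expect_identical(dim(r1[[1]]$data), dim(ph$mask$data))

  empty <- mk_mask(array(0L, c(4, 4, 4)))
  expect_error(simulate_raters(empty, 2, 1), "empty")
})

test_that("interrater concordance decreases monotonically with jitter", {
  ph <- sphere_phantom(r = 13, spacing = 1.5)
  mean_dice <- function(j) {
    mean(vapply(1:10, function(s) {
      r <- simulate_raters(ph$mask, 2, j, seed = s)
      volumetric_dice(r[[1]], r[[2]])
    }, 1.0))
  }
  md <- vapply(c(0.5, 1.5, 3), mean_dice, 1.0)
  expect_true(all(diff(md) < 0))
})

test_that("cohort: proportions, planted monotone shifts, null independence", {
  co <- generate_cohort(cohort_spec(n_subjects = 60,
                                    class_proportions = c(1, 0, 0, 0),
                                    seed = 2))
  expect_true(all(co$severity == "none"))
  expect_equal(nrow(co), 60)
  expect_true(all(feature_manifest()$name %in% names(co)))

  co2 <- generate_cohort(cohort_spec(
    n_subjects = 200,
    effect_sizes = c(left_volume_mm3 = 2.0), seed = 3
  ))
  mu <- tapply(co2$left_volume_mm3, co2$severity, mean)
  expect_true(all(diff(mu) > 0))  # grade-wise means monotone

  # null cohort: a fixed feature is "significant" in at most 10% of seeds
  hits <- vapply(1:50, function(s) {
    nc <- generate_cohort(cohort_spec(n_subjects = 200,
                                      effect_sizes = numeric(0), seed = s))
    p <- stats::cor.test(nc$left_volume_mm3,
                         as.integer(nc$severity))$p.value
    p < 0.05
  }, TRUE)
  expect_lte(sum(hits), 5)
})

test_that("cohort indicators are overdispersed grade-linked counts", {
  co <- generate_cohort(cohort_spec(n_subjects = 400, seed = 6))
  expect_true(all(co$ventilation_days >= 0))
  expect_true(all(co$ventilation_days == round(co$ventilation_days)))
  mu <- tapply(co$ventilation_days, co$severity, mean)
  expect_gt(mu[["severe"]], mu[["none"]])
  # variance > mean: negative-binomial overdispersion
  expect_gt(stats::var(co$ventilation_days), mean(co$ventilation_days))
})
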