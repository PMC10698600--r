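test_that("26-connected labeling matches an independent flood-fill oracle", {
  set.seed(21)
  for (rep in 1:3) {
    m <- array(stats::rbinom(1000, 1, 0.3), c(10, 10, 10))
    if (sum(m) == 0) m[1] <- 1L
    cc <- connected_components_3d(mk_mask(m))
    expect_identical(cc$sizes, flood_fill_sizes(array(as.integer(m), dim(m))))
    expect_equal(sum(cc$labels > 0), sum(m))
  }
  # two disjoint blocks with known sizes, sorted descending
  m <- array(0L, c(12, 12, 6))
  m[2:5, 2:5, 2:4] <- 1L     # 48 voxels
  m[8:11, 8:11, 2:3] <- 1L   # 32 voxels
  cc <- connected_components_3d(mk_mask(m))
  expect_identical(cc$sizes, c(48L, 32L))
  # single voxel
  s1 <- array(0L, c(3, 3, 3)); s1[2, 2, 2] <- 1L
  expect_identical(connected_components_3d(mk_mask(s1))$sizes, 1L)
  expect_error(connected_components_3d(mk_mask(array(0L, c(2, 2, 2)))), "empty")
})

test_that("left/right split follows LR centroids, discards specks, flags ambiguity", {
  m <- array(0L, c(12, 20, 6))
  m[3:8, 2:6, 2:5] <- 1L    # low LR -> left
  m[3:8, 12:18, 2:5] <- 1L  # high LR -> right
  m[1, 1, 1] <- 1L          # speck
  cc <- connected_components_3d(mk_mask(m))
  expect_warning(sl <- split_lungs(cc, c(1, 1, 1)), "discarded 1")
  expect_equal(sl$n_discarded, 1L)
  left_lr <- mean(which(sl$labels == 1L, arr.ind = TRUE)[, 2])
  right_lr <- mean(which(sl$labels == 2L, arr.ind = TRUE)[, 2])
  expect_lt(left_lr, right_lr)

  # components stacked along CC share the LR centroid -> ambiguous
  amb <- array(0L, c(8, 8, 12))
  amb[2:5, 2:5, 2:4] <- 1L
  amb[2:5, 2:5, 8:10] <- 1L
  cca <- connected_components_3d(mk_mask(amb))
  expect_error(split_lungs(cca, c(1, 1, 1)), "ambiguous")
})

test_that("mirroring a volume swaps the lungs exactly", {
  ph <- training_phantom(2)
  rec <- reconstruct_lungs(ph$mask, ph$volume)
  flip <- function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  mvol <- mri_volume(flip(ph$volume$data), ph$volume$spacing, subject_id = "mir")
  mmask <- mask_stack(flip(ph$mask$data), ph$mask$spacing)
  mrec <- reconstruct_lungs(mmask, mvol)
  expect_identical(unname(rec$voxel_counts["left"]),
                   unname(mrec$voxel_counts["right"]))
  expect_identical(unname(rec$voxel_counts["right"]),
                   unname(mrec$voxel_counts["left"]))
})

test_that("frame alignment recovers a 20-degree in-plane rotation and is idempotent", {
  # lungs long along CC and close in LR so the canonical frame matches the grid
  d <- c(56, 64, 72)
  ctr <- c(28, 32, 36)
  centers <- list(c(0, -9, 0), c(0, 9, 0))  # relative to ctr
  semi <- c(11, 8, 26)
  build <- function(theta) {
    R <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
    g <- as.matrix(expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                               z = seq_len(d[3]) - 1))
    q <- sweep(g, 2, ctr) %*% R  # rotate coordinates about CC
    inside <- rep(FALSE, nrow(q))
    for (ce in centers) {
      e <- sweep(q, 2, ce)
      inside <- inside | (e[, 1] / semi[1])^2 + (e[, 2] / semi[2])^2 +
        (e[, 3] / semi[3])^2 <= 1
    }
    array(as.integer(inside), dim = d)
  }
  rec0 <- reconstruct_lungs(mk_mask(build(0)))
  ang <- function(R) acos(pmin(1, (sum(diag(R)) - 1) / 2)) * 180 / pi
  expect_lt(ang(rec0$rotation), 1)

  theta <- 20 * pi / 180
  rec20 <- reconstruct_lungs(mk_mask(build(theta)))
  # recovered rotation must undo the applied one
  R_applied <- rbind(c(cos(theta), -sin(theta), 0),
                     c(sin(theta), cos(theta), 0),
                     c(0, 0, 1))
  expect_lt(ang(rec20$rotation %*% R_applied), 1)

  # idempotence and eigen-alignment of the inertia tensor
  rec2 <- align_reference_frame(rec20)
  expect_lt(max(abs(rec2$rotation - rec20$rotation)), 1e-6)
  w <- lungmorph:::recon_aligned_coords(rec20)$world
  C <- crossprod(sweep(w, 2, colMeans(w))) / nrow(w)
  expect_lt(max(abs(C[upper.tri(C)])) / sum(diag(C)), 1e-6)
  # volume invariant under alignment
  expect_equal(lung_volume(rec20, "left") + lung_volume(rec20, "right"),
               sum(build(theta)) * 1)
})

test_that("near-spherical inertia falls back to the identity with a warning", {
  d <- c(40, 56, 40)
  g <- as.matrix(expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                             z = seq_len(d[3]) - 1))
  inside <- rep(FALSE, nrow(g))
  for (cy in c(16, 40)) {
    e <- sweep(g, 2, c(20, cy, 20))
    inside <- inside | rowSums((e / 9)^2) <= 1
  }
  m <- mk_mask(array(as.integer(inside), dim = d))
  expect_warning(rec <- reconstruct_lungs(m), "degenerate inertia")
  expect_identical(rec$rotation, diag(3))
})

test_that("lung volume is voxel count times voxel volume at the slice pitch", {
  m <- array(0L, c(24, 40, 12))
  m[3:12, 3:12, 2:11] <- 1L    # 10 x 10 x 10 = 1000 voxels, low LR
  m[3:7, 30:34, 3:6] <- 1L     # 5 x 5 x 4 = 100 voxels, high LR
  rec <- reconstruct_lungs(mask_stack(m, spacing = c(1.3, 1.9, 4.4)),
                           align = FALSE)
  expect_equal(lung_volume(rec, "left"), 1000 * 1.3 * 1.9 * 4.4)
  expect_equal(lung_volume(rec, "left"), 10868, tolerance = 1e-12)
  expect_equal(lung_volume(rec, "right"), 100 * 10.868)
  rec$labels[rec$labels == 2L] <- 0L
  expect_warning(v <- lung_volume(rec, "right"), "empty")
  expect_equal(v, 0)
  expect_error(lung_volume(rec, "middle"))
})
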