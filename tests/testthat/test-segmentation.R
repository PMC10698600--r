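test_that("majority vote matches its definition and a brute-force pixel oracle", {
  m <- function(v) mk_mask(array(v, c(1, 1, 1)))
  expect_equal(majority_vote(list(m(1), m(1), m(0)))$data[1], 1L)
  expect_equal(majority_vote(list(m(1), m(0), m(0)))$data[1], 0L)

  # idempotence on identical members
  set.seed(3)
  base <- mk_mask(array(stats::rbinom(64, 1, 0.5), c(8, 8, 1)))
  expect_identical(majority_vote(list(base, base, base))$data, base$data)

  # 3 random 8x8 masks vs per-pixel sum > 1.5 oracle
  ms <- lapply(1:3, function(i) mk_mask(array(stats::rbinom(64, 1, 0.5), c(8, 8, 1))))
  fused <- majority_vote(ms)
  oracle <- (ms[[1]]$data + ms[[2]]$data + ms[[3]]$data) > 1.5
  expect_identical(fused$data == 1L, oracle)

  # member order invariance
  expect_identical(majority_vote(ms[c(2, 3, 1)])$data, fused$data)

  # adding a duplicate of a majority member never changes the vote
  agree12 <- ms[[1]]$data == ms[[2]]$data
  fused5 <- majority_vote(c(ms, ms[1:2]))
  expect_identical(fused5$data[agree12], fused$data[agree12])
})

test_that("even-count ties go to background and are counted", {
  a <- mk_mask(array(c(1, 1, 0, 0), c(2, 2, 1)))
  b <- mk_mask(array(c(1, 0, 1, 0), c(2, 2, 1)))
  fused <- majority_vote(list(a, b))
  expect_identical(as.integer(fused$data), c(1L, 0L, 0L, 0L))
  expect_equal(attr(fused, "n_ties"), 2L)
  expect_error(majority_vote(list(a, mk_mask(array(0L, c(3, 1, 1))))),
               "differ")
})

test_that("volumetric Dice: identity, disjoint, hand-counted toy, symmetry, axis permutation", {
  a <- array(0L, c(10, 10, 3)); a[1:10, 1:10, 1] <- 1L  # 100 voxels
  b <- array(0L, c(10, 10, 3)); b[1:10, 1:5, 1] <- 1L; b[1:10, 1, 2] <- 1L  # 60
  # overlap = 50 (first 5 columns of slice 1)
  expect_equal(sum(a), 100); expect_equal(sum(b), 60); expect_equal(sum(a * b), 50)
  expect_equal(volumetric_dice(mk_mask(a), mk_mask(b)), 2 * 50 / 160)
  expect_equal(volumetric_dice(mk_mask(a), mk_mask(b)), 0.625)
  expect_equal(volumetric_dice(mk_mask(b), mk_mask(a)), 0.625)

  expect_equal(volumetric_dice(mk_mask(a), mk_mask(a)), 1.0)
  d <- array(0L, c(10, 10, 3)); d[1, 1, 3] <- 1L
  expect_equal(volumetric_dice(mk_mask(a), mk_mask(d)), 0.0)
  # simultaneous axis permutation leaves Dice unchanged
  expect_equal(volumetric_dice(mk_mask(aperm(a, c(3, 1, 2))),
                               mk_mask(aperm(b, c(3, 1, 2)))), 0.625)
  z <- mk_mask(array(0L, c(2, 2, 2)))
  expect_error(volumetric_dice(z, z), "undefined")
})

test_that("concordance report covers raters, pairs and consensus", {
  ph <- sphere_phantom(r = 13, spacing = 1.5)
  rs <- simulate_raters(ph$mask, 3, 1.5, seed = 6)
  rep3 <- evaluate_concordance(rs, ph$mask)
  expect_equal(sum(rep3$comparison == "ensemble_vs_rater"), 3)
  expect_equal(sum(rep3$comparison == "interrater"), 3)
  expect_equal(sum(rep3$comparison == "ensemble_vs_consensus"), 1)
  expect_true(all(rep3$vdc >= 0 & rep3$vdc <= 1))

  # identical raters: every VDC is 1
  same <- simulate_raters(ph$mask, 3, 0)
  rep1 <- evaluate_concordance(same, ph$mask)
  expect_true(all(rep1$vdc == 1))

  # 2 raters: tie policy surfaced
  rep2 <- evaluate_concordance(rs[1:2], ph$mask)
  expect_match(attr(rep2, "tie_policy"), "tied voxels")
})

test_that("prediction thresholding is exact at the cutoff and at 1.0", {
  ph <- tiny_phantom(1)
  model <- train_segmenter(list(ph$volume), list(ph$mask),
                           seg_config(depth = 2, base_channels = 4,
                                      epochs = 8, seed = 3))
  prob <- predict_mask(model, ph$volume, threshold = NULL)
  hard <- predict_mask(model, ph$volume, threshold = 0.5)
  expect_identical(hard$data == 1L, prob$data >= 0.5)
  # threshold 1.0 empties any map with probabilities < 1
  expect_equal(sum(predict_mask(model, ph$volume, threshold = 1)$data),
               sum(prob$data >= 1))
  expect_lt(mean(prob$data >= 1), 0.01)
})
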