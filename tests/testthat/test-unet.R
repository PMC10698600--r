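# correctness of the network internals: analytic gradients vs central
# finite differences through conv / ReLU / pool / upsample / skip / loss

test_that("backpropagated gradients match finite differences", {
  fw <- lungmorph:::unet_forward
  bw <- lungmorph:::unet_backward
  loss <- lungmorph:::seg_loss
  cfg <- seg_config(depth = 2, base_channels = 2, seed = 3)
  set.seed(1)
  params <- lungmorph:::unet_init(cfg)
  # move biases off zero: with zero biases, all-zero input patches sit
  # exactly on the ReLU kink where the subgradient and the central
  # difference legitimately disagree
  for (nm in names(params)) {
    params[[nm]]$b <- stats::rnorm(length(params[[nm]]$b), sd = 0.05)
  }
  x <- array(stats::rnorm(8 * 8), c(8, 8, 1))
  t_ <- matrix(stats::rbinom(64, 1, 0.4), 8, 8)
  cache <- fw(params, 2, x)
  l0 <- loss(cache$p, t_, "dice_bce")
  g <- bw(params, 2, cache, l0$dlogit)
  eps <- 1e-6
  set.seed(9)
  for (nm in names(params)) {
    for (k in 1:5) {
      i <- sample(length(params[[nm]]$w), 1)
      p2 <- params
      p2[[nm]]$w[i] <- p2[[nm]]$w[i] + eps
      lp <- loss(fw(p2, 2, x)$p, t_, "dice_bce")$loss
      p2[[nm]]$w[i] <- p2[[nm]]$w[i] - 2 * eps
      lm <- loss(fw(p2, 2, x)$p, t_, "dice_bce")$loss
      num <- (lp - lm) / (2 * eps)
      ana <- g[[nm]]$dw[i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
    i <- sample(length(params[[nm]]$b), 1)
    p2 <- params
    p2[[nm]]$b[i] <- p2[[nm]]$b[i] + eps
    lp <- loss(fw(p2, 2, x)$p, t_, "dice_bce")$loss
    p2[[nm]]$b[i] <- p2[[nm]]$b[i] - 2 * eps
    lm <- loss(fw(p2, 2, x)$p, t_, "dice_bce")$loss
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - g[[nm]]$db[i]) / max(1e-6, abs(num) + abs(g[[nm]]$db[i])),
              1e-4)
  }
})

test_that("loss is near zero and flat at a perfect prediction", {
  loss <- lungmorph:::seg_loss
  t_ <- matrix(c(1, 0, 0, 1), 2, 2)
  l <- loss(t_, t_, "dice_bce")
  expect_lt(l$loss, 1e-5)
  expect_lt(max(abs(l$dlogit)), 1e-6)
})

test_that("degenerate training on all-background masks predicts background", {
  ph <- tiny_phantom(1)
  zero <- mask_stack(array(0L, dim(ph$mask$data)), ph$mask$spacing)
  model <- train_segmenter(list(ph$volume), list(zero),
                           seg_config(depth = 2, base_channels = 4,
                                      epochs = 30, learning_rate = 3e-3,
                                      seed = 2))
  prob <- predict_mask(model, ph$volume, threshold = NULL)
  expect_equal(prob$type, "prob")
  expect_lt(mean(prob$data), 0.1)
  # per-epoch loss is logged
  expect_length(model$history, 30)
  expect_lt(model$history[30], model$history[1])
})

test_that("seeds differentiate weights; shape errors are actionable", {
  ph <- tiny_phantom(1)
  m1 <- train_segmenter(list(ph$volume), list(ph$mask),
                        seg_config(depth = 2, base_channels = 2, epochs = 2,
                                   seed = 1))
  m2 <- train_segmenter(list(ph$volume), list(ph$mask),
                        seg_config(depth = 2, base_channels = 2, epochs = 2,
                                   seed = 2))
  expect_false(identical(m1$params$enc1a$w, m2$params$enc1a$w))
  m1b <- train_segmenter(list(ph$volume), list(ph$mask),
                         seg_config(depth = 2, base_channels = 2, epochs = 2,
                                    seed = 1))
  expect_identical(m1$params, m1b$params)

  odd <- mri_volume(array(0.5, c(15, 16, 2)), c(1, 1, 1))
  expect_error(predict_mask(m1, odd), "crop_to_model_grid")
  expect_error(train_segmenter(list(), list(), seg_config()), "empty")
})
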