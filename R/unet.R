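#' Segmentation model configuration
#'
#' Configuration of the compact slice-wise 2D U-Net used for lung
#' segmentation: an encoder-decoder with skip connections, trained with a
#' soft-Dice + binary cross-entropy loss (the standard choice under strong
#' foreground/background class imbalance) and the Adam optimizer.
#'
#' @param depth number of resolution levels (>= 2); in-plane slice
#'   dimensions must be divisible by `2^(depth - 1)`.
#' @param base_channels channels at the first level; doubled per level.
#' @param loss loss name; `"dice_bce"` (soft Dice + BCE) or `"bce"`.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs (>= 1).
#' @param batch_size slices per optimizer step.
#' @param augment_flip randomly mirror slices left-right during training.
#' @param threshold probability cutoff for binarization, in (0, 1).
#' @param seed integer seed for weight init, shuffling and augmentation.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(depth = 3L, base_channels = 8L,
                       loss = c("dice_bce", "bce"),
                       learning_rate = 1e-3, epochs = 20L, batch_size = 8L,
                       augment_flip = TRUE, threshold = 0.5, seed = 1L) {
  loss <- match.arg(loss)
  assert_that(depth >= 2, "depth must be >= 2")
  assert_that(base_channels >= 1, "base_channels must be >= 1")
  assert_that(epochs >= 1, "epochs must be >= 1")
  assert_that(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  structure(
    list(depth = as.integer(depth), base_channels = as.integer(base_channels),
         loss = loss, learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         augment_flip = isTRUE(augment_flip), threshold = threshold,
         seed = as.integer(seed)),
    class = "seg_config"
  )
}

# He-normal initialized parameter set for the U-Net
unet_init <- function(config) {
  depth <- config$depth
  ch <- config$base_channels * 2^(seq_len(depth) - 1)
  conv_par <- function(cin, cout, k) {
    list(w = matrix(stats::rnorm(cout * cin * k * k,
                                 sd = sqrt(2 / (cin * k * k))),
                    nrow = cout),
         b = numeric(cout), k = k)
  }
  p <- list()
  for (i in seq_len(depth)) {
    cin <- if (i == 1) 1L else ch[i - 1]
    p[[paste0("enc", i, "a")]] <- conv_par(cin, ch[i], 3L)
    p[[paste0("enc", i, "b")]] <- conv_par(ch[i], ch[i], 3L)
  }
  for (i in rev(seq_len(depth - 1))) {
    p[[paste0("up", i)]] <- conv_par(ch[i + 1], ch[i], 3L)
    p[[paste0("dec", i, "a")]] <- conv_par(2L * ch[i], ch[i], 3L)
    p[[paste0("dec", i, "b")]] <- conv_par(ch[i], ch[i], 3L)
  }
  p[["final"]] <- conv_par(ch[1], 1L, 1L)
  p
}

unet_forward <- function(params, depth, x) {
  # x: H x W x 1 array
  cache <- list(enc_in = vector("list", depth),
                enc_mid = vector("list", depth),
                enc_out = vector("list", depth),
                up_in = vector("list", depth), up_raw = vector("list", depth),
                up_out = vector("list", depth), cat = vector("list", depth),
                dec_mid = vector("list", depth),
                dec_out = vector("list", depth))
  cur <- x
  for (i in seq_len(depth)) {
    if (i > 1) cur <- cpp_maxpool2_fwd(cache$enc_out[[i - 1]])
    cache$enc_in[[i]] <- cur
    cache$enc_mid[[i]] <- cpp_conv_fwd(cur, params[[paste0("enc", i, "a")]]$w,
                                       params[[paste0("enc", i, "a")]]$b, 3L, TRUE)
    cache$enc_out[[i]] <- cpp_conv_fwd(cache$enc_mid[[i]],
                                       params[[paste0("enc", i, "b")]]$w,
                                       params[[paste0("enc", i, "b")]]$b, 3L, TRUE)
  }
  cur <- cache$enc_out[[depth]]
  for (i in rev(seq_len(depth - 1))) {
    cache$up_in[[i]] <- cur
    cache$up_raw[[i]] <- cpp_upsample2_fwd(cur)
    cache$up_out[[i]] <- cpp_conv_fwd(cache$up_raw[[i]],
                                      params[[paste0("up", i)]]$w,
                                      params[[paste0("up", i)]]$b, 3L, TRUE)
    skip <- cache$enc_out[[i]]
    cache$cat[[i]] <- array(c(skip, cache$up_out[[i]]),
                            dim = c(dim(skip)[1:2],
                                    dim(skip)[3] + dim(cache$up_out[[i]])[3]))
    cache$dec_mid[[i]] <- cpp_conv_fwd(cache$cat[[i]],
                                       params[[paste0("dec", i, "a")]]$w,
                                       params[[paste0("dec", i, "a")]]$b, 3L, TRUE)
    cache$dec_out[[i]] <- cpp_conv_fwd(cache$dec_mid[[i]],
                                       params[[paste0("dec", i, "b")]]$w,
                                       params[[paste0("dec", i, "b")]]$b, 3L, TRUE)
    cur <- cache$dec_out[[i]]
  }
  cache$logit <- cpp_conv_fwd(cur, params$final$w, params$final$b, 1L, FALSE)
  cache$p <- 1 / (1 + exp(-cache$logit[, , 1]))
  cache
}

unet_backward <- function(params, depth, cache, dlogit) {
  g <- list()
  top <- if (depth > 1) cache$dec_out[[1]] else cache$enc_out[[1]]
  bw <- cpp_conv_bwd(top, params$final$w, 1L, FALSE, cache$logit,
                     array(dlogit, dim = dim(cache$logit)))
  g$final <- list(dw = bw$dw, db = bw$db)
  dcur <- bw$dx
  denc <- vector("list", depth)
  for (i in seq_len(depth - 1)) {
    bw <- cpp_conv_bwd(cache$dec_mid[[i]], params[[paste0("dec", i, "b")]]$w,
                       3L, TRUE, cache$dec_out[[i]], dcur)
    g[[paste0("dec", i, "b")]] <- list(dw = bw$dw, db = bw$db)
    bw <- cpp_conv_bwd(cache$cat[[i]], params[[paste0("dec", i, "a")]]$w,
                       3L, TRUE, cache$dec_mid[[i]], bw$dx)
    g[[paste0("dec", i, "a")]] <- list(dw = bw$dw, db = bw$db)
    nskip <- dim(cache$enc_out[[i]])[3]
    dcat <- bw$dx
    dskip <- dcat[, , seq_len(nskip), drop = FALSE]
    dup <- dcat[, , nskip + seq_len(dim(dcat)[3] - nskip), drop = FALSE]
    denc[[i]] <- if (is.null(denc[[i]])) dskip else denc[[i]] + dskip
    bw <- cpp_conv_bwd(cache$up_raw[[i]], params[[paste0("up", i)]]$w,
                       3L, TRUE, cache$up_out[[i]], dup)
    g[[paste0("up", i)]] <- list(dw = bw$dw, db = bw$db)
    dcur <- cpp_upsample2_bwd(bw$dx)
  }
  # dcur now holds the gradient at the bottleneck output
  denc[[depth]] <- dcur
  for (i in rev(seq_len(depth))) {
    d_out <- denc[[i]]
    bw <- cpp_conv_bwd(cache$enc_mid[[i]], params[[paste0("enc", i, "b")]]$w,
                       3L, TRUE, cache$enc_out[[i]], d_out)
    g[[paste0("enc", i, "b")]] <- list(dw = bw$dw, db = bw$db)
    bw <- cpp_conv_bwd(cache$enc_in[[i]], params[[paste0("enc", i, "a")]]$w,
                       3L, TRUE, cache$enc_mid[[i]], bw$dx)
    g[[paste0("enc", i, "a")]] <- list(dw = bw$dw, db = bw$db)
    if (i > 1) {
      dpool <- cpp_maxpool2_bwd(cache$enc_out[[i - 1]], bw$dx)
      denc[[i - 1]] <- if (is.null(denc[[i - 1]])) dpool else denc[[i - 1]] + dpool
    }
  }
  g
}

# loss value and gradient w.r.t. the logit for one slice
seg_loss <- function(p, t, kind = "dice_bce") {
  n <- length(p)
  eps <- 1e-7
  pc <- pmin(1 - eps, pmax(eps, p))
  bce <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
  dlogit <- (p - t) / n
  loss <- bce
  if (kind == "dice_bce") {
    sp <- sum(p); st <- sum(t); spt <- sum(p * t)
    denom <- sp + st + 1
    dice <- (2 * spt + 1) / denom
    loss <- loss + (1 - dice)
    dDdp <- (2 * t * denom - (2 * spt + 1)) / denom^2
    dlogit <- dlogit - dDdp * p * (1 - p)
  }
  list(loss = loss, dlogit = dlogit)
}

adam_state <- function(params) {
  lapply(params, function(p) list(mw = p$w * 0, vw = p$w * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    s <- state[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * grads[[nm]]$dw
    s$vw <- beta2 * s$vw + (1 - beta2) * grads[[nm]]$dw^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[nm]]$db
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[nm]]$db^2
    mh <- s$mw / (1 - beta1^t); vh <- s$vw / (1 - beta2^t)
    params[[nm]]$w <- params[[nm]]$w - lr * mh / (sqrt(vh) + eps)
    mh <- s$mb / (1 - beta1^t); vh <- s$vb / (1 - beta2^t)
    params[[nm]]$b <- params[[nm]]$b - lr * as.numeric(mh) / (sqrt(as.numeric(vh)) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) {
    acc[[nm]]$dw <- acc[[nm]]$dw + g[[nm]]$dw
    acc[[nm]]$db <- acc[[nm]]$db + g[[nm]]$db
  }
  acc
}

scale_grads <- function(g, f) {
  lapply(g, function(x) list(dw = x$dw * f, db = x$db * f))
}
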