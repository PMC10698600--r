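#' Train a slice-wise lung segmentation network
#'
#' Trains one compact 2D U-Net on the axial slices of the given subjects,
#' mirroring the per-rater model setup: one network per rater's
#' annotations, later fused by [majority_vote()]. Intensities are
#' normalized per volume to \[0, 1\] by robust 1st/99th-percentile scaling
#' (the raw intensities are untouched and remain available for feature
#' extraction). Training is fully seeded and records the per-epoch loss.
#'
#' @param volumes list of [mri_volume()] (one per subject).
#' @param masks list of binary [mask_stack()] congruent with `volumes`.
#' @param config a [seg_config()].
#' @param verbose print per-epoch loss.
#' @return An object of class `lung_segmenter` with elements `params`,
#'   `config`, `history` (per-epoch mean loss) and `input_dim`.
#' @export
train_segmenter <- function(volumes, masks, config = seg_config(),
                            verbose = FALSE) {
  assert_that(length(volumes) >= 1, "empty training set")
  assert_that(length(volumes) == length(masks),
              "volumes and masks must pair up")
  for (s in seq_along(volumes)) {
    assert_that(inherits(volumes[[s]], "mri_volume") &&
                  inherits(masks[[s]], "mask_stack"),
                "inputs must be mri_volume / mask_stack lists")
    assert_that(congruent(volumes[[s]], masks[[s]]),
                sprintf("subject %d: mask shape/spacing mismatch", s))
  }
  d <- dim(volumes[[1]]$data)
  div <- 2^(config$depth - 1)
  assert_that(d[1] %% div == 0 && d[2] %% div == 0,
              sprintf("in-plane dims must be divisible by %d; crop with crop_to_model_grid()", div))

  xs <- list(); ts <- list()
  for (s in seq_along(volumes)) {
    v <- robust_unit_scale(volumes[[s]]$data)
    m <- masks[[s]]$data
    for (k in seq_len(dim(v)[3])) {
      xs[[length(xs) + 1]] <- array(v[, , k], dim = c(d[1], d[2], 1))
      ts[[length(ts) + 1]] <- m[, , k]
    }
  }
  n <- length(xs)

  with_seed(config$seed, {
    params <- unet_init(config)
    state <- adam_state(params)
    history <- numeric(config$epochs)
    t_step <- 0
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      bstarts <- seq(1, n, by = config$batch_size)
      for (b0 in bstarts) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
        acc <- NULL
        for (i in idx) {
          x <- xs[[i]]; t_ <- ts[[i]]
          if (config$augment_flip && stats::runif(1) < 0.5) {
            x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
            t_ <- t_[, rev(seq_len(ncol(t_)))]
          }
          cache <- unet_forward(params, config$depth, x)
          ls <- seg_loss(cache$p, t_, config$loss)
          ep_loss <- ep_loss + ls$loss
          g <- unet_backward(params, config$depth, cache, ls$dlogit)
          acc <- accumulate_grads(acc, g)
        }
        acc <- scale_grads(acc, 1 / length(idx))
        t_step <- t_step + 1
        st <- adam_step(params, acc, state, config$learning_rate, t_step)
        params <- st$params
        state <- st$state
      }
      history[ep] <- ep_loss / n
      if (verbose) {
        message(sprintf("epoch %d/%d: loss %.4f", ep, config$epochs,
                        history[ep]))
      }
    }
    structure(
      list(params = params, config = config, history = history,
           input_dim = d[1:2]),
      class = "lung_segmenter"
    )
  })
}

#' @export
print.lung_segmenter <- function(x, ...) {
  cat(sprintf(
    "<lung_segmenter> depth %d, %d base channels, %d epochs (final loss %.4f)\n",
    x$config$depth, x$config$base_channels, x$config$epochs,
    utils::tail(x$history, 1)
  ))
  invisible(x)
}

#' Predict a lung mask for a volume
#'
#' Slice-by-slice inference with the trained network. With a numeric
#' `threshold` the output is binary; with `threshold = NULL` the raw
#' per-pixel lung probabilities are returned.
#'
#' @param model a [train_segmenter()] fit.
#' @param volume an [mri_volume()] preprocessed like the training data
#'   (same in-plane grid).
#' @param threshold probability cutoff in (0, 1\]; default from the model
#'   config; `NULL` for a probabilistic mask.
#' @return A [mask_stack()] (binary or probabilistic).
#' @export
predict_mask <- function(model, volume, threshold = model$config$threshold) {
  assert_that(inherits(model, "lung_segmenter"), "model must be a lung_segmenter")
  assert_that(inherits(volume, "mri_volume"), "volume must be an mri_volume")
  d <- dim(volume$data)
  div <- 2^(model$config$depth - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop(sprintf("volume in-plane dims %dx%d not divisible by %d; preprocess with crop_to_model_grid()",
                 d[1], d[2], div), call. = FALSE)
  }
  v <- robust_unit_scale(volume$data)
  prob <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    cache <- unet_forward(model$params, model$config$depth,
                          array(v[, , k], dim = c(d[1], d[2], 1)))
    prob[, , k] <- cache$p
  }
  if (is.null(threshold)) {
    mask_stack(prob, spacing = volume$spacing,
               id = paste0("unet_prob_", volume$subject_id), type = "prob")
  } else {
    assert_that(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
    mask_stack(array(as.integer(prob >= threshold), dim = d),
               spacing = volume$spacing,
               id = paste0("unet_", volume$subject_id))
  }
}

#' Pixelwise majority vote over binary masks
#'
#' Fuses member masks into an ensemble mask: a voxel is foreground iff
#' strictly more than half of the members vote foreground. With an even
#' member count, exactly-tied voxels are set to background and their count
#' is reported in the `n_ties` attribute (the reference setting votes over
#' three members, where ties cannot occur).
#'
#' @param masks list of congruent binary [mask_stack()]s (>= 1).
#' @return A binary [mask_stack()] with attribute `n_ties`.
#' @export
#' @examples
#' m <- function(v) mask_stack(array(v, c(1, 1, 1)), c(1, 1, 1))
#' majority_vote(list(m(1), m(1), m(0)))$data[1, 1, 1]
majority_vote <- function(masks) {
  assert_that(is.list(masks) && length(masks) >= 1,
              "masks must be a nonempty list")
  for (m in masks) {
    assert_that(inherits(m, "mask_stack") && m$type == "binary",
                "all members must be binary mask_stacks")
    assert_that(congruent(m, masks[[1]]), "member shapes/spacings differ")
  }
  n <- length(masks)
  votes <- Reduce(`+`, lapply(masks, function(m) m$data))
  fused <- votes > n / 2
  n_ties <- if (n %% 2 == 0) sum(votes == n / 2) else 0L
  out <- mask_stack(array(as.integer(fused), dim = dim(fused)),
                    spacing = masks[[1]]$spacing, id = "ensemble")
  attr(out, "n_ties") <- n_ties
  out
}

#' Volumetric Dice coefficient
#'
#' Overlap concordance of two binary masks computed over the whole 3D
#' stack (not slice-averaged): `2 |A intersect B| / (|A| + |B|)`.
#'
#' @param a,b congruent binary [mask_stack()]s (or 3D 0/1 arrays); at
#'   least one must be nonempty.
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' a <- mask_stack(array(c(1, 1, 0, 0), c(4, 1, 1)), c(1, 1, 1))
#' b <- mask_stack(array(c(1, 0, 1, 0), c(4, 1, 1)), c(1, 1, 1))
#' volumetric_dice(a, b)
volumetric_dice <- function(a, b) {
  xa <- as_mask_array(a)
  xb <- as_mask_array(b)
  assert_that(identical(dim(xa), dim(xb)), "masks must have identical shapes")
  assert_that(all(xa %in% c(0, 1)) && all(xb %in% c(0, 1)),
              "masks must be binary")
  na <- sum(xa); nb <- sum(xb)
  if (na + nb == 0) {
    stop("both masks are empty; the Dice coefficient is undefined",
         call. = FALSE)
  }
  2 * sum(xa * xb) / (na + nb)
}

#' Concordance report: raters, consensus and ensemble
#'
#' Computes the volumetric Dice of the ensemble prediction against each
#' rater, all pairwise interrater Dice values, and the ensemble against the
#' rater consensus (pixelwise majority vote of the raters).
#'
#' @param raters list of >= 2 congruent binary [mask_stack()]s.
#' @param ensemble a congruent binary [mask_stack()].
#' @return A `concordance_report`: a tibble with columns `a`, `b`,
#'   `comparison` (`ensemble_vs_rater`, `interrater`,
#'   `ensemble_vs_consensus`) and `vdc`, with attribute `tie_policy` set
#'   when the consensus vote had an even member count.
#' @export
evaluate_concordance <- function(raters, ensemble) {
  assert_that(is.list(raters) && length(raters) >= 2,
              "need at least 2 raters")
  rows <- list()
  for (i in seq_along(raters)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      a = "ensemble", b = raters[[i]]$id, comparison = "ensemble_vs_rater",
      vdc = volumetric_dice(ensemble, raters[[i]])
    )
  }
  for (i in seq_len(length(raters) - 1)) {
    for (j in (i + 1):length(raters)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        a = raters[[i]]$id, b = raters[[j]]$id, comparison = "interrater",
        vdc = volumetric_dice(raters[[i]], raters[[j]])
      )
    }
  }
  consensus <- majority_vote(raters)
  rows[[length(rows) + 1]] <- tibble::tibble(
    a = "ensemble", b = "consensus", comparison = "ensemble_vs_consensus",
    vdc = volumetric_dice(ensemble, consensus)
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("concordance_report", class(out))
  if (length(raters) %% 2 == 0) {
    attr(out, "tie_policy") <-
      sprintf("even rater count: %d tied voxels set to background in the consensus",
              attr(consensus, "n_ties"))
  }
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  NextMethod()
  if (!is.null(attr(x, "tie_policy"))) {
    cat("note:", attr(x, "tie_policy"), "\n")
  }
  invisible(x)
}
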