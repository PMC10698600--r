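# shared fixtures, all generated in code

# sphere (left) + ellipsoid (right) phantom on an isotropic grid
sphere_phantom <- function(r = 20, spacing = 1, noise_sd = 0, seed = 5, ...) {
  s <- spacing
  generate_phantom(phantom_spec(
    grid_shape = round(c(64, 96, 64) / s),
    spacing = c(s, s, s),
    left_semi_axes = c(r, r, r), right_semi_axes = c(15, 12, 18),
    left_center = c(32, 28, 32), right_center = c(32, 70, 32),
    noise_sd = noise_sd, seed = seed, ...
  ))
}

# small anisotropic two-lung phantom suitable for fast U-Net training
training_phantom <- function(seed) {
  generate_phantom(phantom_spec(
    grid_shape = c(64, 64, 14), spacing = c(2, 2.5, 5),
    left_semi_axes = c(22 + (seed %% 3) * 2, 16, 18),
    right_semi_axes = c(24, 18 + (seed %% 2) * 2, 19),
    left_center = c(64, 48, 35), right_center = c(64, 110, 35),
    noise_sd = 0.05, seed = seed
  ))
}

# very small phantom for fast degenerate-training checks
tiny_phantom <- function(seed = 1) {
  generate_phantom(phantom_spec(
    grid_shape = c(16, 16, 6), spacing = c(4, 4, 8),
    left_semi_axes = c(12, 10, 6), right_semi_axes = c(12, 10, 6),
    left_center = c(32, 20, 24), right_center = c(32, 44, 24),
    noise_sd = 0.05, seed = seed
  ))
}

# tiny binary mask_stack from an array
mk_mask <- function(arr, spacing = c(1, 1, 1), id = "m") {
  mask_stack(array(as.integer(arr), dim = dim(arr)), spacing = spacing, id = id)
}

# reference R flood fill (26-connectivity) used as labeling oracle
flood_fill_sizes <- function(m) {
  d <- dim(m)
  lab <- array(0L, dim = d)
  nxt <- 0L
  sizes <- integer(0)
  idx_all <- which(m == 1L)
  for (v in idx_all) {
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    queue <- v
    lab[v] <- nxt
    n <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      n <- n + 1L
      k <- (cur - 1L) %/% (d[1] * d[2])
      rem <- (cur - 1L) %% (d[1] * d[2])
      j <- rem %/% d[1]
      i <- rem %% d[1]
      for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] ||
            kk < 0 || kk >= d[3]) next
        w <- 1L + ii + d[1] * (jj + d[2] * kk)
        if (m[w] == 1L && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
    sizes <- c(sizes, n)
  }
  sort(sizes, decreasing = TRUE)
}
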