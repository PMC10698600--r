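# internal helpers

# derive a child seed from a base seed; stays well below 2^31
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# robust per-volume intensity scaling to [0, 1] via 1st/99th percentiles
robust_unit_scale <- function(x) {
  q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) {
    return(array(0, dim = dim(x)))
  }
  y <- (x - q[1]) / (q[2] - q[1])
  y[y < 0] <- 0
  y[y > 1] <- 1
  y
}

sample_entropy_bits <- function(x, n_bins = 32L) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(0)
  h <- tabulate(pmin(
    n_bins,
    1L + floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins)
  ), nbins = n_bins)
  p <- h[h > 0] / sum(h)
  -sum(p * log2(p))
}

moment_skewness <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean(((x - mean(x)) / s)^3)
}

moment_kurtosis_excess <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean(((x - mean(x)) / s)^4) - 3
}
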