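# Shared fixtures: a tiny GAN configuration, synthetic training clips, and a
# lazily trained-and-cached checkpoint reused across test files.

tiny_cfg <- function(...) {
  gan_config(z_dim = 8, n_layers = 2, out_len = 256, base_channels = 8,
             kernel_len = 25, stride = 4, phase_shuffle_n = 2,
             lr = 1e-3, batch_size = 8, n_critic = 5, seed = 7, ...)
}

# short damped-sine pulses: enough structure for a toy GAN to latch onto
tiny_clips <- function(n = 24, len = 256, rate = 16000, seed = 5) {
  convabr:::with_seed(seed, lapply(seq_len(n), function(i) {
    f <- stats::runif(1, 400, 2000)
    ph <- stats::runif(1, 0, 2 * pi)
    t <- (seq_len(len) - 1) / rate
    waveform(0.9 * sin(2 * pi * f * t + ph) * exp(-t * 300), rate,
             label = sprintf("clip%02d", i))
  }))
}

.fixture_cache <- new.env(parent = emptyenv())

tiny_checkpoint <- function(steps = 30) {
  key <- paste0("ckpt_", steps)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- train_gan(tiny_clips(), tiny_cfg(), steps = steps)
  }
  .fixture_cache[[key]]
}

# Exhaustive top-down DTW oracle (memoized recursion, independent of the
# package's bottom-up dynamic program).
dtw_oracle <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    if (i == 0 || j == 0) return(Inf)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- abs(a[i] - b[j]) + min(rec(i - 1, j - 1), rec(i - 1, j),
                                  rec(i, j - 1))
    memo[[key]] <- val
    val
  }
  rec(length(a), length(b))
}

# Independent time-domain normalized-autocorrelation F0 estimator over a
# dense lag grid (no FFT, no shared code with track_f0).
oracle_f0 <- function(x, rate, fmin = 70, fmax = 140) {
  x <- x - mean(x)
  lags <- floor(rate / fmax):ceiling(rate / fmin)
  n <- length(x)
  r <- vapply(lags, function(l) {
    a <- x[1:(n - l)]
    b <- x[(1 + l):n]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) 0 else sum(a * b) / den
  }, numeric(1))
  i <- which.max(r)
  lag <- lags[i]
  if (i > 1 && i < length(r)) {
    den <- r[i - 1] - 2 * r[i] + r[i + 1]
    if (den < 0) lag <- lag + 0.5 * (r[i - 1] - r[i + 1]) / den
  }
  rate / lag
}
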