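#' Spectrogram configuration
#'
#' Parameters of the short-time Fourier transform used by the latent-recovery
#' loss: magnitude STFT with a 256-sample Hann window and 128-sample hop by
#' default (at 16 kHz).
#'
#' @param window_len Window length in samples.
#' @param hop Hop in samples (`0 < hop <= window_len`).
#' @param window Window name; `"hann"` or `"rect"`.
#' @param scale `"magnitude"` or `"log-magnitude"`.
#' @return Object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(window_len = 256, hop = 128, window = "hann",
                               scale = c("magnitude", "log-magnitude")) {
  scale <- match.arg(scale)
  if (!(hop > 0 && hop <= window_len)) {
    stop("spectrogram_config: need 0 < hop <= window_len")
  }
  structure(list(window_len = as.integer(window_len), hop = as.integer(hop),
                 window = window, scale = scale),
            class = "spectrogram_config")
}

spec_window <- function(cfg) {
  n <- cfg$window_len
  switch(cfg$window,
         hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n),
         rect = rep(1, n),
         stop("unknown window: ", cfg$window))
}

# Complex STFT of a signal: window_len x n_frames matrix (all DFT bins).
stft <- function(x, cfg) {
  n <- cfg$window_len
  if (length(x) < n) x <- c(x, numeric(n - length(x)))
  starts <- seq(1L, length(x) - n + 1L, by = cfg$hop)
  frames <- vapply(starts, function(s) x[s:(s + n - 1L)], numeric(n))
  F <- stats::mvfft(frames * spec_window(cfg))
  attr(F, "starts") <- starts
  F
}

#' Magnitude spectrogram
#'
#' @param x Numeric vector or `waveform`.
#' @param cfg A [spectrogram_config()].
#' @return `window_len x n_frames` matrix of magnitudes (log1p-compressed for
#'   `scale = "log-magnitude"`).
#' @export
spectrogram <- function(x, cfg = spectrogram_config()) {
  if (inherits(x, "waveform")) x <- x$samples
  M <- Mod(stft(x, cfg))
  if (cfg$scale == "log-magnitude") M <- log1p(M)
  M
}

# L1 spectrogram loss (mean |S(target) - S(x)| over all time-frequency bins)
# and its gradient w.r.t. x. The adjoint of the windowed DFT is the
# unnormalized inverse DFT times the window, overlap-added across frames.
spec_l1_loss_grad <- function(x, target_mag, cfg, want_grad = TRUE) {
  n <- cfg$window_len
  F <- stft(x, cfg)
  mag <- Mod(F)
  use_log <- cfg$scale == "log-magnitude"
  m <- if (use_log) log1p(mag) else mag
  diff <- m - target_mag
  loss <- mean(abs(diff))
  if (!want_grad) return(list(loss = loss))
  dmag <- sign(diff) / length(diff)
  if (use_log) dmag <- dmag / (1 + mag)
  C <- dmag * F / pmax(mag, 1e-300)
  gframes <- Re(stats::mvfft(C, inverse = TRUE)) * spec_window(cfg)
  grad <- numeric(max(length(x), n))
  starts <- attr(F, "starts")
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + n - 1L)
    grad[idx] <- grad[idx] + gframes[, j]
  }
  list(loss = loss, grad = grad[seq_along(x)])
}

#' Zero-pad a target stimulus to the generator's window
#'
#' Places `left_pad` zeros before the stimulus and right-pads with zeros to
#' `out_len` samples. Training clips are right-padded only, but generation
#' quality is sensitive to the left pad; 1000 samples is the default used for
#' both language models.
#'
#' @param s A `waveform`.
#' @param left_pad Left padding in samples.
#' @param out_len Total output length in samples.
#' @return A `waveform` of `out_len` samples with attribute `"left_pad"`.
#' @export
pad_target <- function(s, left_pad = 1000, out_len = 16384) {
  stopifnot(inherits(s, "waveform"))
  if (left_pad < 0) stop("pad_target: left_pad must be >= 0")
  if (left_pad + length(s$samples) > out_len) {
    stop("pad_target: stimulus too long: left_pad + length exceeds out_len")
  }
  out <- waveform(c(numeric(left_pad), s$samples,
                    numeric(out_len - left_pad - length(s$samples))),
                  s$rate, label = s$label)
  attr(out, "left_pad") <- as.integer(left_pad)
  out
}

#' Loss of a latent vector against a target spectrogram
#'
#' The objective minimized by [recover_latent()]: mean absolute error between
#' the magnitude spectrograms of the target and of `G(z)`.
#'
#' @param G A generator.
#' @param z Latent vector.
#' @param target A `waveform` of `cfg$out_len` samples (see [pad_target()]).
#' @param spec_cfg A [spectrogram_config()].
#' @return Scalar loss.
#' @export
recovery_loss <- function(G, z, target, spec_cfg = spectrogram_config()) {
  tx <- if (inherits(target, "waveform")) target$samples else as.numeric(target)
  tm <- spectrogram(tx, spec_cfg)
  y <- as.vector(forward_net(G, as.numeric(z), keep = "none")$out)
  spec_l1_loss_grad(y, tm, spec_cfg, want_grad = FALSE)$loss
}

#' Recover latent vectors matching a target stimulus
#'
#' Finds `z*` minimizing the L1 distance between the magnitude spectrograms
#' of the target and of `G(z*)`, by Adam gradient descent with stochastic
#' clipping: after every update, any latent component outside \[-1, 1\] is
#' resampled uniformly in \[-1, 1\]. Restarts are initialized uniformly on
#' \[-1, 1\]^z_dim (restart `i` uses `seed + i - 1`) and returned sorted by
#' final loss; restarts with non-finite loss are flagged failed and sorted
#' last.
#'
#' @param G A generator.
#' @param target A `waveform` of `cfg$out_len` samples, already padded (see
#'   [pad_target()]).
#' @param n_restarts Number of random restarts.
#' @param steps Optimization steps per restart (default 10,000, the full-run
#'   setting; desk-scale tests use far fewer).
#' @param lr,beta1,beta2 Adam step size and moment decays (defaults 1e-2,
#'   0.9, 0.99).
#' @param spec_cfg A [spectrogram_config()].
#' @param seed Master seed.
#' @param init Optional `z_dim x n_restarts` matrix (or single vector) of
#'   initial latent vectors, overriding the uniform initialization.
#' @return List of recovery results sorted by `final_loss`, each a list with
#'   `z_star`, `final_loss`, `loss_trajectory` (loss before each update, so
#'   element 1 is the loss at the initial point), `n_steps`, `left_pad`,
#'   `seed`, `failed`.
#' @export
recover_latent <- function(G, target, n_restarts = 20, steps = 10000,
                           lr = 1e-2, beta1 = 0.9, beta2 = 0.99,
                           spec_cfg = spectrogram_config(), seed = 1,
                           init = NULL) {
  stopifnot(inherits(G, "gan_network"), G$type == "generator")
  if (steps < 1) stop("recover_latent: steps must be >= 1")
  tx <- if (inherits(target, "waveform")) target$samples else as.numeric(target)
  if (length(tx) != G$cfg$out_len) {
    stop("recover_latent: target must be padded to out_len = ", G$cfg$out_len,
         " samples (see pad_target)")
  }
  tm <- spectrogram(tx, spec_cfg)
  zd <- G$cfg$z_dim
  if (!is.null(init)) {
    init <- matrix(init, nrow = zd)
    if (ncol(init) != n_restarts) {
      stop("recover_latent: init must provide one column per restart")
    }
  }
  results <- lapply(seq_len(n_restarts), function(i) {
    with_seed(seed + i - 1, {
      z <- if (is.null(init)) stats::runif(zd, -1, 1) else init[, i]
      m <- numeric(zd)
      v <- numeric(zd)
      traj <- numeric(steps)
      failed <- FALSE
      for (t in seq_len(steps)) {
        fwd <- forward_net(G, z, keep = "full")
        lg <- spec_l1_loss_grad(as.vector(fwd$out), tm, spec_cfg)
        traj[t] <- lg$loss
        if (!is.finite(lg$loss)) {
          failed <- TRUE
          break
        }
        gz <- as.vector(backward_net(G, fwd,
                                     matrix(lg$grad, 1))$dinput)
        m <- beta1 * m + (1 - beta1) * gz
        v <- beta2 * v + (1 - beta2) * gz^2
        z <- z - lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + 1e-8)
        out_of_range <- abs(z) > 1
        if (any(out_of_range)) {
          z[out_of_range] <- stats::runif(sum(out_of_range), -1, 1)
        }
      }
      final <- if (failed) Inf else
        recovery_loss(G, z, tx, spec_cfg)
      list(z_star = z, final_loss = final, loss_trajectory = traj,
           n_steps = steps, left_pad = attr(target, "left_pad") %||% NA_integer_,
           seed = seed + i - 1, failed = failed)
    })
  })
  results[order(vapply(results, `[[`, numeric(1), "final_loss"))]
}
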