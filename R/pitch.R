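#' Autocorrelation F0 track
#'
#' Frame-based fundamental-frequency estimation by normalized autocorrelation
#' over a dense lag grid, with parabolic refinement of the best lag. A frame is
#' marked voiced when its normalized autocorrelation peak exceeds
#' `voiced_threshold` and its RMS exceeds `energy_threshold` times the
#' waveform's overall RMS.
#'
#' @param w A `waveform`.
#' @param fmin,fmax F0 search range in Hz.
#' @param frame Analysis window length in seconds (default spans at least two
#'   and a half periods of `fmin`).
#' @param hop Hop between frame centers in seconds.
#' @param voiced_threshold Normalized autocorrelation threshold for voicing.
#' @param energy_threshold Relative RMS threshold for voicing.
#' @return A data.frame with columns `time` (frame center, s), `f0` (Hz, `NA`
#'   when unvoiced), `strength` (normalized autocorrelation peak), `voiced`.
#' @export
track_f0 <- function(w, fmin = 70, fmax = 140, frame = 2.5 / fmin,
                     hop = 0.005, voiced_threshold = 0.5,
                     energy_threshold = 0.1) {
  x <- w$samples
  rate <- w$rate
  n_frame <- max(3L, round(frame * rate))
  n_hop <- max(1L, round(hop * rate))
  lag_min <- max(2L, floor(rate / fmax))
  lag_max <- ceiling(rate / fmin)
  if (lag_max >= n_frame) n_frame <- lag_max + lag_min
  starts <- seq(1L, max(1L, length(x) - n_frame + 1L), by = n_hop)
  rms_all <- sqrt(mean(x^2))
  nfft <- 2^ceiling(log2(2L * n_frame))
  lags <- lag_min:lag_max
  out <- lapply(starts, function(s) {
    seg <- x[s:(s + n_frame - 1L)]
    seg <- seg - mean(seg)
    e0 <- sum(seg^2)
    time <- (s - 1 + n_frame / 2) / rate
    if (e0 == 0 || sqrt(e0 / n_frame) < energy_threshold * rms_all) {
      return(data.frame(time = time, f0 = NA_real_, strength = 0,
                        voiced = FALSE))
    }
    # FFT autocorrelation with unbiased (lag-shrinkage) normalization
    ac <- Re(stats::fft(Mod(stats::fft(c(seg, numeric(nfft - n_frame))))^2,
                        inverse = TRUE)) / nfft
    r <- (ac[lags + 1L] / ac[1L]) * (n_frame / (n_frame - lags))
    i <- which.max(r)
    lag <- lags[i]
    # parabolic refinement of the autocorrelation peak on the lag grid
    if (i > 1 && i < length(r)) {
      denom <- r[i - 1] - 2 * r[i] + r[i + 1]
      if (denom < 0) lag <- lag + 0.5 * (r[i - 1] - r[i + 1]) / denom
    }
    data.frame(time = time, f0 = rate / lag, strength = r[i],
               voiced = r[i] >= voiced_threshold)
  })
  do.call(rbind, out)
}

#' F0 at a given time from a track
#'
#' Linear interpolation of the voiced portion of an F0 track; constant
#' extrapolation beyond the first/last voiced frame.
#'
#' @param track A data.frame from [track_f0()].
#' @param t Times in seconds.
#' @return F0 values in Hz (`NA` if the track has no voiced frames).
#' @export
f0_at <- function(track, t) {
  v <- track[track$voiced & !is.na(track$f0), , drop = FALSE]
  if (nrow(v) == 0) return(rep(NA_real_, length(t)))
  if (nrow(v) == 1) return(rep(v$f0, length(t)))
  stats::approx(v$time, v$f0, xout = t, rule = 2)$y
}
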