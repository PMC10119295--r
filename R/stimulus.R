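#' Specification of the CV stimulus
#'
#' Parameters of the synthetic stop+vowel syllable: a brief broadband noise
#' burst, a silent gap whose duration is the voice-onset time (VOT), and a
#' voiced vowel /a/ whose fundamental frequency interpolates linearly from
#' `f0_start` at voicing onset to `f0_end` at the end of the syllable. The
#' default spec is a 100 ms syllable with a 2 ms burst, +10 ms VOT and an F0
#' trajectory falling from 95 to 90 Hz, i.e. a token heard as /ba/ by English
#' listeners and /pa/ by Spanish listeners.
#'
#' @param total_dur Total syllable duration in seconds.
#' @param burst_dur Noise-burst duration in seconds.
#' @param vot Voice-onset time: silent gap after the burst, in seconds.
#' @param f0_start,f0_end Fundamental frequency (Hz) at voicing onset and at
#'   the syllable end.
#' @param vowel_formants List of `c(center_hz, bandwidth_hz)` pairs for the
#'   cascaded vowel resonators. Defaults approximate /a/; the exact Klatt
#'   values are not fixed by the experimental description, so they are
#'   configurable.
#' @param sample_rate Sampling rate in Hz. Must be at least twice the highest
#'   formant center.
#' @param ramp Raised-cosine onset/offset ramp duration for the vowel, seconds.
#' @param amplitude Peak amplitude of the final waveform (the raw synthesis is
#'   peak-normalized, then scaled by `amplitude`, so synthesis is linear in
#'   this gain).
#' @param burst_gain Burst peak amplitude relative to the vowel peak.
#' @return A validated object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(total_dur = 0.100, burst_dur = 0.002, vot = 0.010,
                          f0_start = 95, f0_end = 90,
                          vowel_formants = list(c(700, 80), c(1220, 90),
                                                c(2600, 120)),
                          sample_rate = 16000, ramp = 0.005,
                          amplitude = 0.9, burst_gain = 0.3) {
  spec <- structure(list(total_dur = total_dur, burst_dur = burst_dur,
                         vot = vot, f0_start = f0_start, f0_end = f0_end,
                         vowel_formants = vowel_formants,
                         sample_rate = sample_rate, ramp = ramp,
                         amplitude = amplitude, burst_gain = burst_gain),
                    class = "stimulus_spec")
  validate_stimulus_spec(spec)
  spec
}

validate_stimulus_spec <- function(spec) {
  if (!(spec$total_dur > spec$burst_dur + spec$vot)) {
    stop("stimulus_spec: invariant violated: total_dur > burst_dur + vot")
  }
  if (!(spec$f0_start > 0 && spec$f0_end > 0)) {
    stop("stimulus_spec: invariant violated: f0_start, f0_end > 0")
  }
  if (spec$vot < 0) stop("stimulus_spec: invariant violated: vot >= 0")
  fmax <- max(vapply(spec$vowel_formants, function(f) f[[1]], numeric(1)))
  if (!(spec$sample_rate >= 2 * fmax)) {
    stop("stimulus_spec: invariant violated: sample_rate >= 2 x highest formant center")
  }
  invisible(spec)
}

# Second-order resonator (two-pole) applied in cascade: the standard digital
# formant filter y[n] = 2 r cos(theta) y[n-1] - r^2 y[n-2] + x[n].
resonator_filter <- function(x, center, bw, rate) {
  r <- exp(-pi * bw / rate)
  theta <- 2 * pi * center / rate
  a <- c(2 * r * cos(theta), -r^2)
  as.numeric(stats::filter(x, a, method = "recursive"))
}

#' Synthesize the CV stimulus
#'
#' Simplified source-filter synthesis of a stop+vowel syllable: a white-noise
#' burst (high-pass emphasized, raised-cosine windowed), an exactly-zero silent
#' gap of duration `vot`, and a glottal impulse train whose instantaneous F0
#' interpolates linearly from `f0_start` at voicing onset to `f0_end` at
#' `total_dur`, passed through cascaded second-order resonators for the vowel
#' formants. Burst and vowel segments are rendered independently so the silent
#' gap contains no filter ringing. The raw result is peak-normalized then
#' scaled by `spec$amplitude`.
#'
#' @param spec A [stimulus_spec()].
#' @param seed Seed for the burst noise; the synthesis is bit-reproducible
#'   given `(spec, seed)` and does not disturb the caller's RNG state.
#' @return A `waveform` of duration `spec$total_dur`.
#' @export
synthesize_stimulus <- function(spec, seed = 1L) {
  validate_stimulus_spec(spec)
  rate <- spec$sample_rate
  n_total <- round(spec$total_dur * rate)
  n_burst <- round(spec$burst_dur * rate)
  n_gap <- round(spec$vot * rate)
  onset <- spec$burst_dur + spec$vot
  n_vowel <- n_total - n_burst - n_gap

  # Burst: first-differenced white noise (broadband, high-frequency weighted)
  # windowed with a raised cosine so it dies exactly at the gap.
  burst <- numeric(n_burst)
  if (n_burst > 0) {
    noise <- with_seed(seed, stats::rnorm(n_burst + 1))
    burst <- diff(noise)
    burst <- burst * 0.5 * (1 - cos(2 * pi * seq_len(n_burst) / (n_burst + 1)))
    if (max(abs(burst)) > 0) burst <- burst / max(abs(burst))
  }

  # Voiced source: impulses at glottal epochs found by integrating the linear
  # F0 trajectory over the voiced span.
  dur_voiced <- spec$total_dur - onset
  f0_at <- function(tau) {  # tau: time since voicing onset
    spec$f0_start + (spec$f0_end - spec$f0_start) * tau / dur_voiced
  }
  epochs <- numeric(0)
  tau <- 0
  while (tau < dur_voiced) {
    epochs <- c(epochs, tau)
    tau <- tau + 1 / f0_at(tau)
  }
  src <- numeric(n_vowel)
  idx <- pmin(n_vowel, 1L + round(epochs * rate))
  src[idx] <- 1
  vowel <- src
  for (f in spec$vowel_formants) {
    vowel <- resonator_filter(vowel, f[[1]], f[[2]], rate)
  }
  # raised-cosine onset/offset ramps to avoid clicks
  n_ramp <- min(round(spec$ramp * rate), n_vowel %/% 2)
  if (n_ramp > 0) {
    up <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 0.5) / n_ramp))
    vowel[seq_len(n_ramp)] <- vowel[seq_len(n_ramp)] * up
    tail_idx <- (n_vowel - n_ramp + 1):n_vowel
    vowel[tail_idx] <- vowel[tail_idx] * rev(up)
  }
  if (max(abs(vowel)) > 0) vowel <- vowel / max(abs(vowel))

  x <- c(spec$burst_gain * burst, numeric(n_gap), vowel)
  x <- x / max(abs(x)) * spec$amplitude
  w <- waveform(x, rate, label = sprintf("cv_stimulus_vot%dms",
                                         round(spec$vot * 1000)))
  attr(w, "voicing_onset") <- onset
  attr(w, "spec") <- spec
  w
}
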