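#' Toy network specification with analytically known group delay
#'
#' Describes a small single-channel generator built from stride-1 causal
#' convolution layers with explicit kernels, whose probe-to-output delay is
#' known in closed form: a causal kernel whose dominant tap sits at position
#' `p` (1-based) delays its input by `p - 1` samples, and delays compose
#' additively across layers (exactly for identity activations; for ReLU on
#' non-negative signals the activation is transparent).
#'
#' @param kernels List of numeric kernel vectors, one per layer.
#' @param activations Character vector (recycled): `"identity"` or `"relu"`.
#' @return Object of class `toy_net_spec` with the declared per-layer and
#'   total group delays (samples).
#' @export
toy_net_spec <- function(kernels, activations = "identity") {
  if (!length(kernels)) stop("toy_net_spec: need at least one kernel")
  activations <- rep_len(activations, length(kernels))
  if (!all(activations %in% c("identity", "relu"))) {
    stop("toy_net_spec: activations must be identity or relu")
  }
  delays <- vapply(kernels, function(k) which.max(abs(k)) - 1L, integer(1))
  structure(list(kernels = kernels, activations = activations,
                 delays = delays, total_delay = sum(delays)),
            class = "toy_net_spec")
}

#' Build a toy generator from a spec
#'
#' The resulting network is a `gan_network` loadable by the probe machinery:
#' its "latent vector" is the input signal itself (passed through an identity
#' dense layer to a single feature map), followed by the spec's stride-1
#' causal convolution layers. Probing at layer `k` and comparing against the
#' output measures the composed delay of layers `k+1 .. n`.
#'
#' @param spec A [toy_net_spec()].
#' @param input_len Signal length in samples.
#' @param sample_rate Rate attached to generated waveforms.
#' @return A `gan_network` of type `"generator"`.
#' @export
make_toy_generator <- function(spec, input_len, sample_rate = 16000) {
  stopifnot(inherits(spec, "toy_net_spec"))
  n <- length(spec$kernels)
  cfg <- gan_config(z_dim = input_len, n_layers = n, out_len = input_len,
                    base_channels = 1, kernel_len = max(lengths(spec$kernels)),
                    stride = 1, phase_shuffle_n = 0,
                    sample_rate = sample_rate)
  layers <- list(list(type = "dense", act = "identity",
                      W = diag(input_len), b = numeric(input_len),
                      out_shape = c(1L, input_len)))
  for (l in seq_len(n)) {
    kern <- spec$kernels[[l]]
    layers[[l + 1L]] <- list(type = "tconv", k = length(kern), stride = 1L,
                             cin = 1L, cout = 1L, pad = "causal",
                             act = spec$activations[l],
                             W = matrix(kern, ncol = 1), b = 0)
  }
  structure(list(cfg = cfg, type = "generator", layers = layers,
                 toy_spec = spec),
            class = "gan_network")
}

#' Specification of a simulated cABR-like trace
#'
#' Phenomenological model of an averaged brainstem response to the CV
#' stimulus: a sharp burst transient followed by one smooth activity pulse
#' per glottal period, with per-period peak-latency offsets under
#' experimenter control and additive Gaussian noise. Period pulses are
#' compactly supported raised-sine bumps, so with zero noise every peak sits
#' exactly at its specified time. This is an analysis fixture, not a
#' biophysical brainstem model.
#'
#' @param rate Sampling rate, Hz.
#' @param dur Trace duration, s.
#' @param burst_time Onset of the burst transient, s.
#' @param voicing_onset First glottal epoch, s.
#' @param f0_start,f0_end Linear F0 trajectory over the voiced span, Hz.
#' @param period_offsets Numeric vector of per-period peak-latency offsets
#'   in seconds, indexed by vocalic period `n` (recycled; named entries not
#'   supported -- pass a full vector, e.g. `offsets_for(9e-4, period = 2)`).
#' @param pulse_width Width of each period's activity pulse, s (its peak
#'   lags the epoch by `pulse_width / 2`).
#' @param burst_width,burst_amp Width (s) and amplitude of the burst pulse.
#' @param period_amp Amplitude of the period pulses.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed RNG seed for the noise.
#' @return Object of class `cabr_sim_spec`.
#' @export
cabr_sim_spec <- function(rate = 16000, dur = 0.140, burst_time = 0.002,
                          voicing_onset = 0.014, f0_start = 95, f0_end = 90,
                          period_offsets = numeric(12), pulse_width = 0.006,
                          burst_width = 0.002, burst_amp = 1.3,
                          period_amp = 1, noise_sd = 0.02, seed = 1) {
  if (!all(is.finite(period_offsets))) {
    stop("cabr_sim_spec: period offsets must be finite")
  }
  if (rate <= 2 * max(f0_start, f0_end)) {
    stop("cabr_sim_spec: rate must exceed twice the F0")
  }
  structure(list(rate = rate, dur = dur, burst_time = burst_time,
                 voicing_onset = voicing_onset, f0_start = f0_start,
                 f0_end = f0_end, period_offsets = period_offsets,
                 pulse_width = pulse_width, burst_width = burst_width,
                 burst_amp = burst_amp, period_amp = period_amp,
                 noise_sd = noise_sd, seed = seed),
            class = "cabr_sim_spec")
}

#' Per-period offset vector helper
#'
#' @param value Offset in seconds.
#' @param period Vocalic period index receiving the offset.
#' @param n_periods Length of the returned vector.
#' @return Numeric vector, zero except `value` at `period`.
#' @export
offsets_for <- function(value, period, n_periods = 12) {
  out <- numeric(n_periods)
  out[period] <- value
  out
}

# raised-sine bump of unit height with compact support [0, width], peak at
# width / 2
sine_bump <- function(t, width) {
  ifelse(t >= 0 & t <= width, sin(pi * t / width)^2, 0)
}

#' Simulate a cABR-like trace
#'
#' @param spec A [cabr_sim_spec()].
#' @return A `waveform` with attributes `"epochs"` (glottal epoch times),
#'   `"peak_times"` (exact per-period peak times including offsets),
#'   `"annotation"` (a period annotation data.frame with the burst as row
#'   `n = 0`), and `"spec"`.
#' @export
simulate_cabr <- function(spec) {
  stopifnot(inherits(spec, "cabr_sim_spec"))
  n <- round(spec$dur * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  voiced_span <- spec$dur - spec$voicing_onset
  f0_fun <- function(tau) {
    spec$f0_start + (spec$f0_end - spec$f0_start) * tau / voiced_span
  }
  epochs <- numeric(0)
  tau <- 0
  while (tau + spec$pulse_width < voiced_span) {
    epochs <- c(epochs, spec$voicing_onset + tau)
    tau <- tau + 1 / f0_fun(tau)
  }
  offsets <- rep_len(spec$period_offsets, length(epochs))
  x <- numeric(n)
  peak_times <- numeric(length(epochs))
  for (i in seq_along(epochs)) {
    s_i <- epochs[i] + offsets[i]
    x <- x + spec$period_amp * sine_bump(t - s_i, spec$pulse_width)
    peak_times[i] <- s_i + spec$pulse_width / 2
  }
  burst_peak <- NULL
  if (spec$burst_amp > 0) {
    x <- x + spec$burst_amp * sine_bump(t - spec$burst_time, spec$burst_width)
    burst_peak <- spec$burst_time + spec$burst_width / 2
  }
  if (spec$noise_sd > 0) {
    x <- x + with_seed(spec$seed, stats::rnorm(n, 0, spec$noise_sd))
  }
  w <- waveform(x, spec$rate, label = "simulated_cabr")
  periods <- vapply(seq_along(epochs),
                    function(i) 1 / f0_fun(epochs[i] - spec$voicing_onset),
                    numeric(1))
  ann <- data.frame(n = seq_along(epochs),
                    start = pmax(0, peak_times - 0.45 * periods),
                    end = pmin(spec$dur, peak_times + 0.55 * periods))
  if (!is.null(burst_peak)) {
    ann <- rbind(data.frame(n = 0L, start = spec$burst_time,
                            end = spec$burst_time + spec$burst_width +
                              0.001),
                 ann)
  }
  attr(w, "epochs") <- epochs
  attr(w, "peak_times") <- peak_times
  attr(w, "burst_peak") <- burst_peak
  attr(w, "annotation") <- ann
  attr(w, "spec") <- spec
  w
}

#' Synthesize a mini annotated corpus of CV words
#'
#' A deterministic-per-seed corpus of one-word utterances covering the six
#' stops (`p,t,k` with a 60 ms VOT; `b,d,g` with 5 ms), each paired with the
#' vowel `aa`, with slight per-token duration jitter. Alignments are exact by
#' construction, so slicing counts and labels are known.
#'
#' @param n_per_stop Tokens per stop.
#' @param seed RNG seed.
#' @param rate Sampling rate, Hz.
#' @return List of [aligned_utterance()] objects (corpus `"synthetic"`).
#' @export
make_mini_corpus <- function(n_per_stop = 5, seed = 1, rate = 16000) {
  stops <- c("p", "t", "k", "b", "d", "g")
  utts <- list()
  with_seed(seed, {
    for (stop_lab in stops) {
      vot <- if (stop_lab %in% c("p", "t", "k")) 0.060 else 0.005
      for (tok in seq_len(n_per_stop)) {
        dur <- 0.100 + stats::runif(1, -0.01, 0.01) + vot
        sp <- stimulus_spec(total_dur = dur, vot = vot, sample_rate = rate)
        word <- synthesize_stimulus(sp, seed = sample.int(1e6, 1))
        tail_sil <- numeric(round(0.020 * rate))
        audio <- waveform(c(word$samples, tail_sil), rate,
                          label = paste0(stop_lab, "a"))
        word_end <- wave_duration(word)
        stop_end <- sp$burst_dur + sp$vot
        utts[[length(utts) + 1L]] <- aligned_utterance(
          audio,
          words = data.frame(label = paste0(stop_lab, "a"), start = 0,
                             end = word_end),
          phones = data.frame(label = c(stop_lab, "aa"),
                              start = c(0, stop_end),
                              end = c(stop_end, word_end)),
          corpus = "synthetic")
      }
    }
  })
  utts
}

#' Simulate a peak-latency dataset with a known language effect
#'
#' Draws peak records directly (no waveforms): for every language,
#' replication, output and period, `delta_t` is a period-specific baseline
#' plus, for the second language, minus the injected English-minus-Spanish
#' effect at that period, plus Gaussian noise. Used for statistical
#' parameter-recovery and false-discovery-rate checks.
#'
#' @param n_per_cell Outputs per (language, replication) cell.
#' @param effect Numeric vector of true English-minus-Spanish differences in
#'   seconds, indexed by period `n + 1` for periods `0..length(effect)-1`
#'   (e.g. `offsets_for(1e-3, period = 3, n_periods = 12)` injects 1 ms at
#'   period 2).
#' @param sd Residual standard deviation of `delta_t`, s.
#' @param periods Period indices to generate.
#' @param replications Number of replications.
#' @param seed RNG seed.
#' @return data.frame of peak records (`language`, `replication`,
#'   `output_id`, `n`, `delta_t`).
#' @export
simulate_latency_dataset <- function(n_per_cell = 20,
                                     effect = numeric(12), sd = 3e-4,
                                     periods = 0:11, replications = 2,
                                     seed = 1) {
  base <- -5e-4 + 1e-4 * sin(periods)  # arbitrary smooth per-period baseline
  grid <- expand.grid(language = c("english", "spanish"),
                      replication = seq_len(replications),
                      output = seq_len(n_per_cell),
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      eff <- if (g$language == "spanish") {
        -rep_len(effect, max(periods) + 1L)[periods + 1L]
      } else {
        numeric(length(periods))
      }
      data.frame(language = g$language, replication = g$replication,
                 output_id = sprintf("%s_r%d_%02d", g$language,
                                     g$replication, g$output),
                 n = periods,
                 delta_t = base + eff + stats::rnorm(length(periods), 0, sd),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Full-pipeline language experiment on simulated traces
#'
#' End-to-end exercise of the analysis surface: for each language and
#' replication it simulates `n_outputs` audio traces (no language offsets)
#' and matching convolutional-layer-like traces whose per-period peaks are
#' shifted by the language's offsets, annotates periods automatically from
#' the audio, and measures per-period peak latencies. Feeding the result to
#' [fit_and_contrast()] tests whether an injected cross-language latency
#' shift is recovered.
#'
#' @param n_outputs Outputs per (language, replication) cell.
#' @param offsets_spanish Per-period probe-peak offsets (s) for the Spanish
#'   condition (e.g. `offsets_for(9e-4, period = 2)` delays the Spanish
#'   period-2 probe peak by 0.9 ms, making `delta_t` more negative there).
#' @param offsets_english Same for English (default none).
#' @param noise_sd Trace noise standard deviation.
#' @param replications Number of replications per language.
#' @param seed Master seed; every trace derives its own sub-seed.
#' @return data.frame of peak records ready for [fit_and_contrast()].
#' @export
simulate_language_experiment <- function(n_outputs = 10,
                                         offsets_spanish = offsets_for(9e-4, 2),
                                         offsets_english = numeric(12),
                                         noise_sd = 0.02,
                                         replications = 2, seed = 1) {
  outputs <- list()
  probes <- list()
  anns <- list()
  language <- character(0)
  replication <- integer(0)
  sub <- 0L
  for (lang in c("english", "spanish")) {
    offs <- if (lang == "spanish") offsets_spanish else offsets_english
    for (rep_i in seq_len(replications)) {
      for (out_i in seq_len(n_outputs)) {
        sub <- sub + 1L
        audio <- simulate_cabr(cabr_sim_spec(
          noise_sd = noise_sd, seed = seed * 10000 + 2L * sub))
        probe <- simulate_cabr(cabr_sim_spec(
          period_offsets = offs, noise_sd = noise_sd,
          seed = seed * 10000 + 2L * sub + 1L))
        outputs[[sub]] <- audio
        probes[[sub]] <- data.frame(time = wave_times(probe),
                                    value = probe$samples)
        anns[[sub]] <- annotate_periods(audio)
        language <- c(language, lang)
        replication <- c(replication, rep_i)
      }
    }
  }
  latency_table(outputs, probes, anns, use_abs = TRUE,
                language = language, replication = replication,
                output_id = seq_len(sub))
}
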