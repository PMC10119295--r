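---
title: "Comparing convolutional layer activations with auditory brainstem responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing convolutional layer activations with auditory brainstem responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convabr)
```

## The method

The complex auditory brainstem response (cABR) is a scalp-recorded EEG
potential that reflects early subcortical encoding of complex sounds. It is
obtained by averaging electrical activity over thousands of stimulus
presentations, and to a speech syllable it shows an onset component locked to
the stop release burst and a frequency-following response (FFR) locked to the
glottal periods of the vowel. This package implements an analysis framework
built on an analogous averaging operation inside artificial networks: for a
1D convolutional generative adversarial network (GAN) trained on raw speech,
the post-activation feature maps $C_1, \dots, C_{\lVert C \rVert}$ of one
convolutional layer are averaged into a single time series

$$ t \;=\; \frac{1}{\lVert C\rVert} \sum_{i=1}^{\lVert C\rVert} C_i , $$

which can be compared directly — with no learned transformation between the
signals — against a cABR trace evoked by the same stimulus. The comparison
currency is *peak latency*: within each annotated glottal period $n$ (the
release burst is period 0), the timing difference

$$ \Delta t_n \;=\; t_{n_\text{out}} - t_{n_\text{conv}} $$

between the amplitude peak of the audio signal and the peak of the layer
probe. Because listeners of different languages encode voice-onset time (VOT)
differently — the same bilabial stop token is heard as /ba/ by English
listeners and /pa/ by Spanish listeners — the framework trains one model per
language on word-initial stop+vowel (#CV) slices of a corpus of that
language, and asks whether $\Delta t_n$ differs between language conditions
in the same direction and at the same millisecond scale as the cABR latency
differences between monolingual listener groups.

The pipeline has five stages, each a module of this package:

1. **Stimulus synthesis** (`stimulus_spec()`, `synthesize_stimulus()`): a
   controllable source-filter rendition of the CV syllable — 2 ms noise
   burst, an exactly-silent VOT gap, and a vowel /a/ whose F0 falls linearly
   from 95 to 90 Hz over the voiced span; 100 ms total by default.
2. **Corpus preparation** (`slice_cv()`, `count_stops()`): #CV slicing of
   time-aligned corpora (TIMIT-style `.phn`/`.wrd` or Praat TextGrids),
   producing fixed-length training clips and per-stop count tables.
3. **Networks** (`gan_config()`, `build_generator()`,
   `build_discriminator()`, `train_gan()`): a WaveGAN-style generator
   (latent vector of 100, dense projection, five transpose-convolution
   layers of kernel 25 and stride 4, ReLU inside and tanh at the audio
   layer, 16,384-sample output) and mirrored discriminator (strided
   convolutions, leaky ReLU 0.2, phase shuffle, scalar Wasserstein score),
   trained with the WGAN-GP objective.
4. **Latent recovery** (`pad_target()`, `recover_latent()`): finding
   $z^\ast = \arg\min_z \lVert \mathcal S(s) - \mathcal S(G(z))\rVert_1$
   for a target stimulus $s$ under a magnitude-spectrogram map
   $\mathcal S$, by Adam gradient descent with *stochastic clipping*
   (out-of-range latent components are resampled uniformly).
5. **Analysis** (`get_feature_maps()`, `average_feature_maps()`,
   `probe_generator()`, `probe_discriminator()`, `annotate_periods()`,
   `peak_latencies()`, `latency_table()`, `align_at_burst()`,
   `dtw_correlate()`, `fit_and_contrast()`): layer probes, period
   annotation, per-period latencies, burst-aligned DTW/correlation
   comparison, and the language-contrast statistics.

## Implementation of the networks

No deep-learning framework is part of this package's dependency set; the 1D
convolution, transpose convolution, dense and activation layers are
implemented directly on matrix products (im2col/col2im pairings), with
hand-derived backward passes. Three gradient paths are exercised:

* parameter gradients for training both networks;
* input gradients of the discriminator, needed for the gradient penalty
  $\lambda\,(\lVert\nabla_x D(\hat x)\rVert_2 - 1)^2$ at random
  interpolates $\hat x$;
* the penalty's own parameter gradient, computed exactly by a
  forward-over-reverse (double-backward) pass: with activation masks fixed,
  the derivative of the penalty w.r.t. a layer's weights is the outer
  product of that layer's pre-activation adjoint from the seed-1 backward
  pass with the tangent stream obtained by pushing
  $u = \partial P / \partial g$ forward through the linearized network.

All three are verified against central-difference oracles in the test suite.
Training is fully seeded and bitwise reproducible on CPU.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `vot` | 0.010 | s | the +10 ms token sits near the English /b/–/p/ boundary |
| `f0_start`, `f0_end` | 95, 90 | Hz | falling vowel F0 of the experimental stimulus |
| `vowel_formants` | 700/1220/2600 | Hz | nominal /a/ targets; the original synthesis parameters are not published, so these are configurable |
| `sample_rate` | 16,000 | Hz | TIMIT rate; 16,384 samples ≈ 1.02 s model window |
| `z_dim`, `n_layers`, `out_len` | 100, 5, 16,384 | — | standard WaveGAN layout |
| `kernel_len`, `stride` | 25, 4 | samples | standard WaveGAN layout |
| `leaky_slope` | 0.2 | — | discriminator leaky ReLU |
| `phase_shuffle_n` | 2 | samples | WaveGAN default; training-only regularizer |
| `gp_lambda`, `n_critic` | 10, 5 | — | WGAN-GP defaults |
| recovery `lr`, `beta1`, `beta2`, `steps` | 1e-2, 0.9, 0.99, 10,000 | — | the published recovery settings |
| `left_pad` | 1000 | samples | generation quality is sensitive to left padding; 1000 works for both language models |
| STFT `window_len`, `hop` | 256, 128 | samples | 16 ms Hann windows at 16 kHz; the source work does not print its STFT parameters, so these are the package's own choice |
| DTW display scaling | 33.3 or 50 | — | overlay scaling only; Pearson's r is invariant to it |

## Period annotation

The original analysis annotated vocalic periods manually in Praat. For
testability this package automates the annotation
(`annotate_periods()`) and provides a TextGrid path
(`annotation_from_textgrid()`) that reproduces the manual workflow exactly.
The automatic procedure: an FFT-autocorrelation F0 track (dense lag grid,
parabolic lag refinement, unbiased lag normalization) locates the voiced
region; the strongest waveform peak in the middle of that region anchors a
period grid laid out by integrating the F0 trajectory in both directions;
every predicted peak is then re-anchored on the local waveform maximum so
that accumulated F0-track drift cannot push true peaks toward interval
edges. A candidate period must carry a genuine interior local maximum of at
least 15% of the anchor amplitude (an edge maximum is accepted only where
the window is clipped by the signal boundary, e.g. a pulse train starting at
$t = 0$); leading candidates separated from the vowel by a silent stretch
far below the typical inter-peak floor — the release burst before the VOT
gap — are dropped from the period count. The burst is then detected
separately as a short-time energy transient exceeding 6 dB above the
pre-voicing noise floor and annotated as period 0. Boundaries are placed a
quarter period before each peak, so peaks are interior to their intervals.

Peak timing within an interval uses the discrete argmax refined by a
parabola through the maximum and its two neighbours. Ties take the leftmost
sample; boundary maxima and flat stretches return the discrete (leftmost)
time, flagged; the refinement can never move a peak by more than one sample.
Following the original procedure the audio signal is rectified
(`use_abs = TRUE`) before peak picking, since a rectified-activation probe
is non-negative and peaks of both polarities must be captured; a no-abs mode
is provided.

## Statistics

`fit_and_contrast()` fits ordinary least squares to $\Delta t_n$ with
language (treatment-coded, English reference), period (treatment-coded,
period 1 reference) and replication (sum-coded), with all interactions, and
reports per-period English−Spanish contrasts marginalized over replications
(via emmeans), two-sided t tests on the OLS residual degrees of freedom, and
Benjamini–Hochberg FDR-adjusted p values. Marginalizing over replication
(rather than conditioning on it) is a deliberate reading of the pooled
analysis; on replication-balanced designs the pooled contrast equals the
mean of per-replication contrasts, which the tests assert. Periods 12 and
above are excluded before fitting (`exclusion_filter()`) as too rarely
attested. Empty (language, period) cells raise an error naming the cells
rather than returning inestimable contrasts.

The sign convention follows $\Delta t_n = t_{n_\text{out}} -
t_{n_\text{conv}}$ literally: a probe whose peaks lag the audio makes
$\Delta t_n$ negative, and the English−Spanish contrast is positive when the
Spanish-condition probe is the later one.

## Synthetic data

The synthetic-fixtures module generates every input the pipeline needs
without downloads:

* `simulate_cabr()` — a phenomenological cABR-like trace: a sharp burst
  bump plus one compactly-supported raised-sine activity pulse per glottal
  epoch (epochs from the 95→90 Hz trajectory), per-period peak-latency
  offsets under experimenter control, and additive Gaussian noise
  (sd 0.02 of the unit pulse amplitude by default, a realistic
  residual-noise level for an averaged evoked response). With zero noise
  every peak sits exactly at its specified time. It is *not* a biophysical
  brainstem model: it has no cochlear filtering, no adaptation, and a
  noise spectrum that is white rather than EEG-like, so passing tests show
  that the analysis surface recovers injected latency structure, not that
  it would survive every property of real EEG.
* `make_toy_generator()` — single-channel stride-1 causal networks with
  explicit kernels whose probe-to-output group delay is known analytically;
  these are the oracles for the probe machinery.
* `make_mini_corpus()` — synthesized CV words for all six stops with exact
  alignments (voiceless stops get 60 ms VOT, voiced 5 ms), for slicing and
  counting tests.
* `simulate_latency_dataset()` / `simulate_language_experiment()` — latency
  datasets with injected cross-language effects, the second via the full
  trace → annotation → peak pipeline.

## Numerical choices and problem sizes

* Latent recovery evaluates the loss before each update, so the first
  trajectory entry is the loss at the initial point and initializing at the
  true latent is an exact fixed point. Failed (non-finite) restarts are
  flagged and sorted last, never silently dropped.
* Stochastic clipping resamples only the offending components, preserving
  the rest of the Adam state.
* Upsampled probes anchor layer sample $j$ at audio sample
  $(j-1) \cdot \text{factor} + 1$ (left-aligned); linear interpolation
  preserves endpoints and cannot overshoot.
* DTW uses unit step costs on absolute differences with steps (1,0), (0,1),
  (1,1), unconstrained by default with an optional Sakoe–Chiba band. The
  windowed correlation is computed on the warped pairing by default; an
  `"aligned"` mode computes it on the unwarped pointwise pairing, and the
  mode is recorded in the result, since the wording of the original
  description admits both readings.
* Phase shuffle is a training regularizer only; probes run in evaluation
  mode, otherwise latencies would be randomized by up to
  `phase_shuffle_n` samples.
* Degenerate inputs: silence yields an empty annotation with a reason;
  all-zero stop counts report a missing percentage; empty feature-map
  stacks, out-of-range layers, inconsistent configurations and truncated
  WAV files raise immediate errors.

The test suite exercises the full architecture at the published size
(16,384-sample generator, 64 feature maps in the probed layer) for shape and
probe contracts, and trains desk-scale models (latent dimension 8, two
layers, 256-sample window, ~30 steps) for the optimization contracts; the
statistical contracts run on 100 simulated experiments of 8 outputs per
language and replication and 1,000 null simulations for false-discovery
control. These sizes are the package's chosen test conditions; the same code
paths scale to the full configuration.

## Known limitations

* Full-scale GAN training to perceptual-quality speech is supported by the
  code path but is far outside desk scale; desk-scale models learn only
  coarse spectral structure, which is sufficient for the recovery and probe
  contracts tested here.
* The automatic period annotation assumes a single sustained voiced region
  with F0 inside the search range; creaky or diplophonic signals would need
  the TextGrid override.
* The pipeline isolates an injected 0.9 ms period-2 latency shift (the
  cABR-scale effect) with the effect detected in every simulated
  experiment; in roughly one run in ten, one additional period crosses the
  FDR threshold, which is the expected familywise behaviour of
  Benjamini–Hochberg at $\alpha = 0.05$ over twelve per-period contrasts
  and should be kept in mind when reading any single experiment.
* Group-level cABR smoothing analyses (GAMMs with autocorrelation
  correction) and dipole localization are out of scope; the package exports
  tidy traces for external smoothing software instead.
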