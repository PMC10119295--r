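# convabr

Comparing early-auditory brain responses with intermediate convolutional
layers of GANs trained on raw speech.

## The problem

The complex auditory brainstem response (cABR) — a scalp-recorded EEG
potential obtained by averaging thousands of trials — encodes a speech
syllable with an onset peak locked to the stop release burst and a
frequency-following response locked to the glottal periods of the vowel.
Native language shapes it: to a bilabial stop with +10 ms voice-onset time
(heard as /ba/ by English listeners, /pa/ by Spanish listeners), the peak
latency of English and Spanish monolinguals differs by under a millisecond
in a systematic direction.

`convabr` is a toolbox for asking whether the same kind of encoding arises
inside 1D convolutional GANs trained on raw speech of those two languages.
Its core observation is that the cABR and a convolutional layer can be
summarized by the *same operation* — averaging activity across units:

```
t = (1 / ||C||) * sum_i C_i          # average of a layer's feature maps
```

which makes the two signals directly comparable without any learned
transformation. The analysis then measures, per annotated glottal period n
(burst = period 0), the peak-latency difference

```
delta_t_n = t_n(out) - t_n(conv)
```

between the audio signal and the layer probe, and tests per-period
English-Spanish contrasts with an OLS model (language x period x
replication, all interactions; contrasts marginalized over replication;
Benjamini-Hochberg FDR adjustment).

The package provides, in pure R:

- a source-filter synthesizer for the CV stimulus (2 ms burst, silent VOT
  gap, vowel /a/ with F0 falling 95 to 90 Hz) and WAV I/O;
- #CV corpus slicing from TIMIT-style or TextGrid alignments, with
  per-stop count tables;
- a WaveGAN-style generator/discriminator pair (transpose/strided 1D
  convolutions, phase shuffle) with a from-scratch WGAN-GP training loop,
  including an exact double-backward for the gradient penalty;
- latent-vector recovery toward a target stimulus by Adam on a
  spectrogram L1 loss with stochastic clipping;
- feature-map-averaging probes of any convolutional layer, upsampled to
  audio rate;
- automatic burst/period annotation, parabolic-interpolation peak timing,
  and latency tables;
- burst-aligned rescaling/resampling, dynamic time warping and windowed
  Pearson correlation against cABR-style traces;
- the contrast statistics, and synthetic fixtures (cABR-like trace
  simulator, toy generators with analytic group delays, a mini aligned
  corpus) that exercise every stage without downloads.

## Worked example

Synthesize the stimulus, annotate its periods, and run a simulated
two-language latency experiment through the full analysis:

```r
library(convabr)

stim <- synthesize_stimulus(stimulus_spec())
stim
#> <waveform> 1600 samples @ 16000 Hz (100.0 ms) [cv_stimulus_vot10ms]

ann <- annotate_periods(stim)
head(ann, 4)
#>   n      start        end
#> 1 0 0.00000000 0.00300000
#> 2 1 0.01229045 0.02072510
#> 3 2 0.02072510 0.03134353
#> 4 3 0.03134353 0.04195441
sum(ann$n >= 1)
#> [1] 9
```

The burst is period 0 (it ends before voicing begins at 12 ms) and the
falling 95-90 Hz vowel carries 9 vocalic periods. Next, a full-pipeline
experiment: traces for two "languages" where the Spanish-condition probe
peak is delayed by 0.9 ms at period 2 only (the scale and locus of the
brainstem finding), measured blind by the annotation and peak machinery:

```r
df <- simulate_language_experiment(n_outputs = 4, seed = 42)
ct <- fit_and_contrast(df)
ct[, c("period", "estimate", "se", "df", "t_ratio", "p_value", "p_fdr")]
#>    period  estimate       se  df t_ratio  p_value    p_fdr
#> 1       0 -1.32e-05 9.04e-05 144 -0.1459 8.84e-01 9.61e-01
#> 2       1 -7.98e-05 9.04e-05 144 -0.8829 3.79e-01 6.49e-01
#> 3       2  7.87e-04 9.04e-05 144  8.7097 6.54e-15 7.84e-14
#> 4       3  8.79e-05 9.04e-05 144  0.9730 3.32e-01 6.49e-01
#> 5       4 -3.23e-05 9.04e-05 144 -0.3569 7.22e-01 9.61e-01
#> ...
```

The period-2 contrast recovers the injected effect (0.787 ms estimated vs
0.9 ms injected with 4 outputs per cell; more outputs tighten it) at
p_fdr < 1e-13 while every other period stays null — the signature the
method is designed to isolate. `estimate` is the English-minus-Spanish
latency difference in seconds, positive when the Spanish probe peak is the
later one.

Training and recovery run the same way at any scale:

```r
cfg  <- gan_config(z_dim = 8, n_layers = 2, out_len = 256,
                   base_channels = 8, lr = 1e-3, batch_size = 8, seed = 7)
ck   <- train_gan(clips, cfg, steps = 200)
tgt  <- pad_target(stim, left_pad = 1000, out_len = cfg$out_len)
best <- recover_latent(ck$G, tgt, n_restarts = 20, steps = 2000)[[1]]
pr   <- probe_generator(ck$G, best$z_star)   # output + layer probe
```

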