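Package: convabr
Title: Comparing Convolutional Layer Activations with Auditory Brainstem Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for comparing early-auditory brain responses (cABR/FFR)
    with intermediate convolutional layers of generative adversarial networks
    trained on raw speech. Provides a controllable source-filter synthesizer for
    a stop+vowel (CV) stimulus with adjustable voice-onset time, slicing of
    word-initial stop+vowel sequences from time-aligned corpora, a 1D
    convolutional GAN (WaveGAN-style generator and discriminator with phase
    shuffle) trained with a Wasserstein objective and gradient penalty, latent
    vector recovery toward a target stimulus by gradient descent with stochastic
    clipping on a spectrogram L1 loss, feature-map-averaging probes of
    convolutional layers, per-period peak-latency analysis with parabolic
    interpolation, burst-aligned signal comparison with dynamic time warping and
    windowed correlation, and linear-model contrasts of peak latency between
    language conditions with false-discovery-rate adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
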