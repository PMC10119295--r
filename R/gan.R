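#' GAN configuration
#'
#' Architecture and training hyperparameters for the 1D convolutional GAN.
#' The defaults reproduce the standard WaveGAN layout: a 100-dimensional
#' latent vector projected to a `16 x 1024` tensor and upsampled through 5
#' transpose convolutional layers (kernel 25, stride 4) to 16,384 audio
#' samples; the discriminator mirrors this with strided convolutions, leaky
#' ReLU (slope 0.2) and phase shuffle `n = 2`. Training uses the Wasserstein
#' objective with gradient penalty (weight 10), 5 discriminator updates per
#' generator update and Adam(1e-4, 0.5, 0.9).
#'
#' Tiny desk-scale configurations (e.g. `z_dim = 8, n_layers = 2, out_len =
#' 256, base_channels = 8`) share the same code path.
#'
#' @param z_dim Latent dimensionality.
#' @param n_layers Number of (transpose) convolutional layers.
#' @param out_len Audio output length in samples; must equal
#'   `initial_len * stride^n_layers` for an integer `initial_len >= 1`.
#' @param base_channels Channel count of the layer adjacent to the audio
#'   (generator layer `n_layers - 1`, discriminator layer 1).
#' @param kernel_len Convolution kernel length in samples.
#' @param stride Up/downsampling factor per layer.
#' @param leaky_slope Negative slope of the discriminator's leaky ReLU.
#' @param phase_shuffle_n Maximum phase-shuffle shift in samples (0 disables).
#' @param gp_lambda Gradient-penalty weight.
#' @param lr,beta1,beta2 Adam step size and moment decays for training.
#' @param n_critic Discriminator updates per generator update.
#' @param batch_size Minibatch size.
#' @param sample_rate Audio sampling rate attached to generated waveforms.
#' @param seed Seed for weight initialization and training randomness.
#' @return Validated object of class `gan_config`.
#' @export
gan_config <- function(z_dim = 100, n_layers = 5, out_len = 16384,
                       base_channels = 64, kernel_len = 25, stride = 4,
                       leaky_slope = 0.2, phase_shuffle_n = 2, gp_lambda = 10,
                       lr = 1e-4, beta1 = 0.5, beta2 = 0.9, n_critic = 5,
                       batch_size = 16, sample_rate = 16000, seed = 1) {
  if (z_dim < 1) stop("gan_config: z_dim must be >= 1")
  if (phase_shuffle_n < 0) stop("gan_config: phase_shuffle_n must be >= 0")
  init_len <- out_len / stride^n_layers
  if (init_len != round(init_len) || init_len < 1) {
    stop("gan_config: out_len must be initial_len * stride^n_layers ",
         "for integer initial_len >= 1")
  }
  structure(list(z_dim = as.integer(z_dim), n_layers = as.integer(n_layers),
                 out_len = as.integer(out_len),
                 base_channels = as.integer(base_channels),
                 kernel_len = as.integer(kernel_len),
                 stride = as.integer(stride), leaky_slope = leaky_slope,
                 phase_shuffle_n = as.integer(phase_shuffle_n),
                 gp_lambda = gp_lambda, lr = lr, beta1 = beta1, beta2 = beta2,
                 n_critic = as.integer(n_critic),
                 batch_size = as.integer(batch_size),
                 sample_rate = sample_rate, seed = seed,
                 init_len = as.integer(init_len)),
            class = "gan_config")
}

init_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Build the generator network
#'
#' A dense projection of the latent vector to an `initial_len` feature tensor
#' (ReLU), followed by `n_layers` transpose convolutions with stride
#' `cfg$stride`, ReLU activations on intermediate layers and tanh on the
#' final single-channel audio layer. Channel counts halve per layer down to
#' `base_channels`, then 1.
#'
#' @param cfg A [gan_config()].
#' @param seed Weight-initialization seed; `NULL` draws from the current RNG
#'   stream (used inside the seeded training loop).
#' @return Object of class `gan_network` with `type = "generator"`.
#' @export
build_generator <- function(cfg, seed = cfg$seed) {
  build <- function() {
    c0 <- cfg$base_channels * 2^(cfg$n_layers - 1)
    ch <- if (cfg$n_layers == 1) 1L else
      c(cfg$base_channels * 2^((cfg$n_layers - 2):0), 1L)
    layers <- list(list(
      type = "dense", act = "relu",
      W = init_mat(c0 * cfg$init_len, cfg$z_dim),
      b = numeric(c0 * cfg$init_len),
      out_shape = c(c0, cfg$init_len)))
    cin <- c0
    for (l in seq_len(cfg$n_layers)) {
      cout <- ch[l]
      layers[[l + 1L]] <- list(
        type = "tconv", k = cfg$kernel_len, stride = cfg$stride,
        cin = cin, cout = cout, pad = "same",
        act = if (l < cfg$n_layers) "relu" else "tanh",
        W = init_mat(cout * cfg$kernel_len, cin),
        b = numeric(cout))
      cin <- cout
    }
    structure(list(cfg = cfg, type = "generator", layers = layers),
              class = "gan_network")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Build the discriminator network
#'
#' `n_layers` strided 1D convolutions (leaky ReLU; phase shuffle after every
#' layer but the last when training) followed by a dense layer producing a
#' scalar Wasserstein score. Channel counts double per layer from
#' `base_channels`.
#'
#' @inheritParams build_generator
#' @return Object of class `gan_network` with `type = "discriminator"`.
#' @export
build_discriminator <- function(cfg, seed = cfg$seed + 1) {
  build <- function() {
    ch <- cfg$base_channels * 2^(0:(cfg$n_layers - 1))
    layers <- list()
    cin <- 1L
    for (l in seq_len(cfg$n_layers)) {
      layers[[l]] <- list(
        type = "conv", k = cfg$kernel_len, stride = cfg$stride,
        cin = cin, cout = ch[l], act = "lrelu", slope = cfg$leaky_slope,
        ps_n = if (l < cfg$n_layers) cfg$phase_shuffle_n else 0L,
        W = init_mat(ch[l], cin * cfg$kernel_len),
        b = numeric(ch[l]))
      cin <- ch[l]
    }
    layers[[cfg$n_layers + 1L]] <- list(
      type = "flatten_dense", act = "identity",
      W = init_mat(1L, cin * cfg$init_len), b = 0)
    structure(list(cfg = cfg, type = "discriminator", layers = layers),
              class = "gan_network")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' @export
print.gan_network <- function(x, ...) {
  cat(sprintf("<gan_network: %s> %d layers, z_dim %d, out_len %d\n",
              x$type, x$cfg$n_layers, x$cfg$z_dim, x$cfg$out_len))
  invisible(x)
}

# Full forward pass. `input` is a latent vector (generator) or a 1 x L matrix
# / numeric vector of audio samples (discriminator). `train` enables phase
# shuffle; `keep` controls how much is cached ("none", "acts" for probing,
# "full" for backprop).
forward_net <- function(net, input, train = FALSE, keep = c("none", "acts", "full")) {
  keep <- match.arg(keep)
  x <- input
  if (net$type == "discriminator" && !is.matrix(x)) x <- matrix(x, nrow = 1)
  caches <- vector("list", length(net$layers))
  acts <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[l]], x, train = train)
    x <- fw$out
    if (keep == "full") caches[[l]] <- fw$cache
    if (keep != "none") {
      acts[[l]] <- if (net$layers[[l]]$type == "conv" &&
                       !is.null(fw$cache$post)) fw$cache$post else fw$out
      if (keep == "acts") caches[[l]] <- NULL
    }
  }
  list(out = x, caches = caches, acts = acts, input = input)
}

# Full backward pass from a gradient w.r.t. the network output. Returns
# parameter gradients, the gradient w.r.t. the input, and the per-layer
# pre-activation adjoints (needed by the gradient-penalty double backward).
backward_net <- function(net, fwd, dout, need_input = TRUE) {
  nl <- length(net$layers)
  grads <- vector("list", nl)
  adjoints <- vector("list", nl)
  g <- dout
  for (l in rev(seq_len(nl))) {
    need <- need_input || l > 1L
    bw <- layer_backward(net$layers[[l]], fwd$caches[[l]], g, need_input = need)
    grads[[l]] <- list(dW = bw$dW, db = bw$db)
    adjoints[[l]] <- bw$a
    g <- bw$dx
  }
  list(grads = grads, dinput = g, adjoints = adjoints)
}

# Gradient-penalty double backward. Given the cached forward pass at an
# interpolate, the pre-activation adjoints of the seed-1 backward pass (which
# produced g = dD/dx), and the tangent seed u = dPenalty/dg, propagate u
# forward through the linearized network and pair each layer's adjoint with
# the tangent input to obtain dPenalty/dW. Under fixed activation masks the
# penalty has no bias gradient.
gp_weight_grads <- function(net, fwd, adjoints, u) {
  nl <- length(net$layers)
  grads <- vector("list", nl)
  t_in <- u
  for (l in seq_len(nl)) {
    layer <- net$layers[[l]]
    tg <- layer_tangent(layer, fwd$caches[[l]], t_in)
    a <- adjoints[[l]]
    dW <- if (layer$type == "conv") a %*% t(tg$pair)
          else if (layer$type == "dense") as.vector(a) %o% tg$pair
          else matrix(as.vector(a) * tg$pair, 1)
    grads[[l]] <- list(dW = dW,
                       db = if (is.matrix(a)) numeric(nrow(a)) else
                         numeric(length(a)))
    t_in <- tg$out
  }
  list(grads = grads, s = tg$out)
}

#' Generate audio from a latent vector
#'
#' Deterministic forward pass of the generator; output samples lie in
#' \[-1, 1\] (tanh).
#'
#' @param G A generator from [build_generator()].
#' @param z Latent vector of length `cfg$z_dim` with components in \[-1, 1\].
#' @return A `waveform` of `cfg$out_len` samples at `cfg$sample_rate`.
#' @export
generate <- function(G, z) {
  stopifnot(inherits(G, "gan_network"), G$type == "generator")
  if (length(z) != G$cfg$z_dim) stop("generate: z must have length z_dim")
  out <- forward_net(G, as.numeric(z), train = FALSE, keep = "none")$out
  waveform(as.vector(out), G$cfg$sample_rate, label = "generated")
}

#' Discriminator score of a waveform
#'
#' Evaluation-mode forward pass (phase shuffle disabled) returning the scalar
#' Wasserstein score.
#'
#' @param D A discriminator from [build_discriminator()].
#' @param w A `waveform` or numeric vector of `cfg$out_len` samples.
#' @return Scalar score.
#' @export
discriminator_score <- function(D, w) {
  stopifnot(inherits(D, "gan_network"), D$type == "discriminator")
  x <- if (inherits(w, "waveform")) w$samples else as.numeric(w)
  if (length(x) != D$cfg$out_len) {
    stop("discriminator_score: input must have out_len samples")
  }
  as.numeric(forward_net(D, x, train = FALSE, keep = "none")$out)
}

#' Extract post-activation feature maps of a convolutional layer
#'
#' For the generator, `layer = 0` denotes the reshaped dense projection and
#' `1..n_layers` the transpose convolutional layers; for the discriminator,
#' `1..n_layers` the convolutional layers. Phase shuffle is disabled
#' (evaluation mode), so the extraction is deterministic.
#'
#' @param net A `gan_network`.
#' @param input Latent vector (generator) or waveform/samples (discriminator).
#' @param layer Convolutional layer index.
#' @return Object of class `feature_map_stack`: list with `maps`
#'   (`n_maps x L` matrix, post-activation), `layer_index`, `owner`.
#' @export
get_feature_maps <- function(net, input, layer) {
  stopifnot(inherits(net, "gan_network"))
  lo <- if (net$type == "generator") 0L else 1L
  if (layer < lo || layer > net$cfg$n_layers) {
    stop("get_feature_maps: layer out of range [", lo, ", ",
         net$cfg$n_layers, "]")
  }
  x <- if (inherits(input, "waveform")) input$samples else as.numeric(input)
  fwd <- forward_net(net, x, train = FALSE, keep = "acts")
  pos <- if (net$type == "generator") layer + 1L else layer
  maps <- fwd$acts[[pos]]
  if (!is.matrix(maps)) maps <- matrix(maps, nrow = 1)
  structure(list(maps = maps, layer_index = as.integer(layer),
                 owner = net$type),
            class = "feature_map_stack")
}
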