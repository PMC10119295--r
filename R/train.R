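# Adam optimizer state over the per-layer (W, b) parameter lists.

adam_init <- function(net) {
  lapply(net$layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, state, grads, lr, b1, b2, t, eps = 1e-8) {
  bc1 <- 1 - b1^t
  bc2 <- 1 - b2^t
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- b1 * s$mW + (1 - b1) * g$dW
    s$vW <- b2 * s$vW + (1 - b2) * g$dW^2
    s$mb <- b1 * s$mb + (1 - b1) * g$db
    s$vb <- b2 * s$vb + (1 - b2) * g$db^2
    net$layers[[l]]$W <- net$layers[[l]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}

grads_zero <- function(net) {
  lapply(net$layers, function(l) list(dW = l$W * 0, db = l$b * 0))
}

grads_add <- function(a, b) {
  for (l in seq_along(a)) {
    a[[l]]$dW <- a[[l]]$dW + b[[l]]$dW
    a[[l]]$db <- a[[l]]$db + b[[l]]$db
  }
  a
}

# Gradient of D at input x (evaluated with phase shuffle active, as in
# training) plus everything needed for the penalty's parameter gradient.
input_gradient <- function(D, x, train = TRUE) {
  fwd <- forward_net(D, x, train = train, keep = "full")
  bw <- backward_net(D, fwd, 1, need_input = TRUE)
  list(g = as.vector(bw$dinput), fwd = fwd, adjoints = bw$adjoints,
       score = as.numeric(fwd$out))
}

#' Train the GAN with the Wasserstein objective and gradient penalty
#'
#' WGAN-GP training of a WaveGAN-style generator/discriminator pair on a set
#' of fixed-length clips: `n_critic` discriminator updates (Wasserstein loss
#' plus `gp_lambda` times the squared excess of the input-gradient norm at
#' random interpolates over 1) per generator update, both with Adam. The
#' penalty's parameter gradient is computed exactly by a double-backward
#' (forward-over-reverse) pass. Fully seeded: the same `cfg$seed` yields a
#' bitwise-identical loss trajectory on CPU.
#'
#' @param clips A `clip_set` from [slice_cv()], or a list of `waveform`s of
#'   `cfg$out_len` samples.
#' @param cfg A [gan_config()].
#' @param steps Number of generator updates (>= 1).
#' @param verbose Print losses every 10 steps.
#' @return Object of class `gan_checkpoint`: list with `G`, `D`, optimizer
#'   states, `cfg`, `steps`, and a data.frame `losses` with per-step
#'   `d_loss`, `g_loss`, `gp`.
#' @export
train_gan <- function(clips, cfg, steps, verbose = FALSE) {
  if (inherits(clips, "clip_set")) clips <- clips$clips
  if (length(clips) < 1) stop("train_gan: need at least one clip")
  if (steps < 1) stop("train_gan: steps must be >= 1")
  X <- vapply(clips, function(w) {
    x <- if (inherits(w, "waveform")) w$samples else as.numeric(w)
    if (length(x) != cfg$out_len) {
      stop("train_gan: all clips must have out_len = ", cfg$out_len,
           " samples")
    }
    x
  }, numeric(cfg$out_len))
  set.seed(cfg$seed)
  G <- build_generator(cfg, seed = NULL)
  D <- build_discriminator(cfg, seed = NULL)
  optG <- adam_init(G)
  optD <- adam_init(D)
  B <- min(cfg$batch_size, ncol(X))
  losses <- data.frame(step = seq_len(steps), d_loss = NA_real_,
                       g_loss = NA_real_, gp = NA_real_)
  td <- 0L
  tg <- 0L
  for (step in seq_len(steps)) {
    for (crit in seq_len(cfg$n_critic)) {
      dg <- grads_zero(D)
      z <- matrix(stats::runif(B * cfg$z_dim, -1, 1), cfg$z_dim, B)
      d_loss <- 0
      gp_term <- 0
      for (i in seq_len(B)) {
        real <- X[, sample.int(ncol(X), 1L)]
        fake <- as.vector(forward_net(G, z[, i], keep = "none")$out)
        f_r <- forward_net(D, real, train = TRUE, keep = "full")
        dg <- grads_add(dg, backward_net(D, f_r, -1 / B,
                                         need_input = FALSE)$grads)
        f_f <- forward_net(D, fake, train = TRUE, keep = "full")
        dg <- grads_add(dg, backward_net(D, f_f, 1 / B,
                                         need_input = FALSE)$grads)
        d_loss <- d_loss + (as.numeric(f_f$out) - as.numeric(f_r$out)) / B
        eps <- stats::runif(1)
        xhat <- eps * real + (1 - eps) * fake
        ig <- input_gradient(D, xhat)
        nrm <- sqrt(sum(ig$g^2))
        gp_term <- gp_term + cfg$gp_lambda * (nrm - 1)^2 / B
        if (nrm > 0) {
          u <- (2 * cfg$gp_lambda / B) * (nrm - 1) / nrm * ig$g
          dg <- grads_add(dg, gp_weight_grads(D, ig$fwd, ig$adjoints,
                                              matrix(u, 1))$grads)
        }
      }
      d_loss <- d_loss + gp_term
      if (!is.finite(d_loss)) {
        stop(sprintf("train_gan: non-finite discriminator loss at step %d (critic %d); try a lower learning rate", step, crit))
      }
      td <- td + 1L
      upd <- adam_step(D, optD, dg, cfg$lr, cfg$beta1, cfg$beta2, td)
      D <- upd$net
      optD <- upd$state
    }
    gg <- grads_zero(G)
    z <- matrix(stats::runif(B * cfg$z_dim, -1, 1), cfg$z_dim, B)
    g_loss <- 0
    for (i in seq_len(B)) {
      fG <- forward_net(G, z[, i], keep = "full")
      fD <- forward_net(D, as.vector(fG$out), train = TRUE, keep = "full")
      g_loss <- g_loss - as.numeric(fD$out) / B
      dx <- backward_net(D, fD, -1 / B, need_input = TRUE)$dinput
      gg <- grads_add(gg, backward_net(G, fG, dx, need_input = FALSE)$grads)
    }
    if (!is.finite(g_loss)) {
      stop(sprintf("train_gan: non-finite generator loss at step %d", step))
    }
    tg <- tg + 1L
    upd <- adam_step(G, optG, gg, cfg$lr, cfg$beta1, cfg$beta2, tg)
    G <- upd$net
    optG <- upd$state
    losses$d_loss[step] <- d_loss
    losses$g_loss[step] <- g_loss
    losses$gp[step] <- gp_term
    if (verbose && step %% 10L == 0L) {
      message(sprintf("step %d: d_loss %.4f  g_loss %.4f  gp %.4f",
                      step, d_loss, g_loss, gp_term))
    }
  }
  structure(list(G = G, D = D, optG = optG, optD = optD, cfg = cfg,
                 steps = as.integer(steps), losses = losses, seed = cfg$seed,
                 version = 1L),
            class = "gan_checkpoint")
}

#' @export
print.gan_checkpoint <- function(x, ...) {
  cat(sprintf("<gan_checkpoint> %d steps, z_dim %d, out_len %d, seed %s\n",
              x$steps, x$cfg$z_dim, x$cfg$out_len, format(x$seed)))
  invisible(x)
}

#' Save / load a training checkpoint
#'
#' Single-file serialized networks + optimizer state + config + seed.
#'
#' @param ckpt A `gan_checkpoint`.
#' @param path File path.
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "gan_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "gan_checkpoint")) {
    stop("load_checkpoint: not a gan_checkpoint: ", path)
  }
  ckpt
}
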