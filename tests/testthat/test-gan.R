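test_that("tiny configuration obeys the stride arithmetic", {
  cfg <- gan_config(z_dim = 4, n_layers = 2, out_len = 64, base_channels = 4,
                    kernel_len = 9, stride = 4)
  G <- build_generator(cfg, seed = 1)
  w <- generate(G, runif(4, -1, 1))
  expect_identical(length(w$samples), 64L)
  # layer l output length = init_len * stride^l
  expect_identical(ncol(get_feature_maps(G, runif(4, -1, 1), 1)$maps), 16L)
  D <- build_discriminator(cfg, seed = 2)
  expect_identical(ncol(get_feature_maps(D, w, 1)$maps), 16L)
  expect_length(discriminator_score(D, w), 1L)
  expect_error(gan_config(z_dim = 4, n_layers = 2, out_len = 60, stride = 4),
               "initial_len")
  expect_error(get_feature_maps(G, runif(4, -1, 1), 5), "out of range")
})

test_that("generator output is bounded and deterministic given (weights, z)", {
  G <- tiny_checkpoint()$G
  for (i in 1:5) {
    z <- runif(G$cfg$z_dim, -1, 1)
    w1 <- generate(G, z)
    w2 <- generate(G, z)
    expect_true(all(abs(w1$samples) <= 1))
    expect_identical(w1$samples, w2$samples)
  }
})

test_that("discriminator score is finite for arbitrary bounded inputs", {
  D <- tiny_checkpoint()$D
  set.seed(11)
  for (i in 1:5) {
    x <- runif(D$cfg$out_len, -1, 1)
    expect_true(is.finite(discriminator_score(D, x)))
  }
  expect_true(is.finite(discriminator_score(D, numeric(D$cfg$out_len))))
})

test_that("phase shuffle preserves length and values and is uniform over shifts", {
  m <- matrix(as.numeric(1:8), nrow = 1)
  expect_identical(phase_shuffle(m, 0)[1, ], m[1, ])
  # n = 1 on a length-8 map: one of 3 shifts, uniform within 3 sigma
  set.seed(42)
  shifts <- integer(10000)
  for (i in seq_len(10000)) {
    out <- phase_shuffle(m, 1)
    shifts[i] <- attr(out, "shifts")
    # interior values are preserved up to boundary reflection
    expect_true(all(out[1, 2:7] %in% 1:8))
  }
  counts <- table(factor(shifts, levels = -1:1))
  sigma <- sqrt(10000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 10000 / 3) < 3 * sigma))
  expect_error(phase_shuffle(m, -1), ">= 0")
})

test_that("gradient-penalty input gradient matches a finite-difference estimate", {
  ck <- tiny_checkpoint()
  D <- ck$D
  set.seed(3)
  x <- runif(D$cfg$out_len, -1, 1)
  ig <- convabr:::input_gradient(D, x, train = FALSE)
  nrm <- sqrt(sum(ig$g^2))
  # directional derivative along g/|g| equals |g| for the exact gradient
  u <- ig$g / nrm
  e <- 1e-5
  sc <- function(xx) discriminator_score(D, xx)
  fd <- (sc(x + e * u) - sc(x - e * u)) / (2 * e)
  expect_lt(abs(fd - nrm) / nrm, 1e-2)
})

test_that("training runs to completion with finite losses and is seed-deterministic", {
  ck <- tiny_checkpoint()
  expect_true(all(is.finite(ck$losses$d_loss)))
  expect_true(all(is.finite(ck$losses$g_loss)))
  expect_identical(nrow(ck$losses), as.integer(ck$steps))
  ck1 <- train_gan(tiny_clips(), tiny_cfg(), steps = 4)
  ck2 <- train_gan(tiny_clips(), tiny_cfg(), steps = 4)
  expect_identical(ck1$losses, ck2$losses)
  expect_identical(ck1$G$layers[[2]]$W, ck2$G$layers[[2]]$W)
})

test_that("checkpoints round-trip through save and load", {
  ck <- tiny_checkpoint()
  p <- tempfile(fileext = ".rds")
  save_checkpoint(ck, p)
  back <- load_checkpoint(p)
  z <- runif(ck$cfg$z_dim, -1, 1)
  expect_identical(generate(back$G, z)$samples, generate(ck$G, z)$samples)
  unlink(p)
})
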