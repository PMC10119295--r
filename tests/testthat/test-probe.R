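test_that("feature-map averaging equals the brute-force column mean", {
  set.seed(5)
  M <- matrix(rnorm(64 * 512), 64, 512)
  pr <- average_feature_maps(M)
  oracle <- apply(M, 2, function(col) sum(col) / length(col))
  expect_equal(pr$values, oracle, tolerance = 1e-12)
  # single map: probe equals the map; identical maps: probe equals any one
  expect_equal(average_feature_maps(M[1, , drop = FALSE])$values, M[1, ])
  same <- matrix(rep(M[3, ], 64), 64, byrow = TRUE)
  expect_equal(average_feature_maps(same)$values, M[3, ])
  expect_error(average_feature_maps(matrix(numeric(0), 0, 0)), "empty")
})

test_that("averaging is linear in the raw stacks", {
  set.seed(6)
  A <- matrix(rnorm(8 * 32), 8, 32)
  B <- matrix(rnorm(8 * 32), 8, 32)
  lhs <- average_feature_maps(2 * A + 3 * B)$values
  rhs <- 2 * average_feature_maps(A)$values + 3 * average_feature_maps(B)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("generator probes are non-negative post-ReLU", {
  ck <- tiny_checkpoint()
  set.seed(7)
  for (i in 1:3) {
    pr <- probe_generator(ck$G, runif(ck$cfg$z_dim, -1, 1))
    expect_true(all(pr$probe$values >= 0))
    expect_true(all(pr$probe$upsampled >= 0))
  }
})

test_that("upsampling interpolates linearly without overshoot", {
  v <- c(0, 1, 4, 2)
  expect_identical(upsample_probe(v, 1), v)
  up <- upsample_probe(v, 4)
  expect_identical(length(up), 16L)
  # anchored left: sample j of the layer at upsampled position (j-1)*factor+1
  expect_equal(up[c(1, 5, 9, 13)], v)
  expect_equal(max(up), max(v))
  expect_equal(min(up), min(v))
  # monotone segment stays monotone
  expect_true(all(diff(up[1:9]) >= 0))
  # stride arithmetic of the 5-layer config: conv4 length 4096 upsamples x4
  # to the 16,384-sample audio rate
  up4 <- upsample_probe(seq_len(4096) * 1.0, 4)
  expect_identical(length(up4), 16384L)
  expect_error(upsample_probe(v, 0), "positive integer")
})

test_that("toy-generator probe delays equal the declared group delays", {
  bump <- exp(-((1:128) - 40)^2 / 18)
  # identity kernel: zero delay
  G0 <- make_toy_generator(toy_net_spec(list(1)), 128)
  pr0 <- probe_generator(G0, bump, layer = 0)
  expect_identical(which.max(pr0$output$samples) -
                     which.max(pr0$probe$upsampled), 0L)
  # single delay-by-16 kernel
  Gd <- make_toy_generator(toy_net_spec(list(c(rep(0, 16), 1))), 128)
  prd <- probe_generator(Gd, bump, layer = 0)
  expect_identical(which.max(prd$output$samples) -
                     which.max(prd$probe$upsampled), 16L)
  # cascade of delays d1, d2 composes additively; ReLU on a non-negative
  # signal is transparent
  spec <- toy_net_spec(list(c(rep(0, 5), 1), c(rep(0, 7), 1)),
                       activations = c("relu", "identity"))
  expect_identical(spec$total_delay, 12L)
  Gc <- make_toy_generator(spec, 128)
  # probe after layer 1 sees only layer 2's delay
  pr1 <- probe_generator(Gc, bump, layer = 1)
  expect_identical(which.max(pr1$output$samples) -
                     which.max(pr1$probe$upsampled), 7L)
  pr2 <- probe_generator(Gc, bump, layer = 0)
  expect_identical(which.max(pr2$output$samples) -
                     which.max(pr2$probe$upsampled), 12L)
})

test_that("toy probe peaks match a brute-force direct convolution oracle", {
  set.seed(9)
  x <- pmax(0, rnorm(64))
  kern <- c(0.2, 0.1, 1, 0.3)
  G <- make_toy_generator(toy_net_spec(list(kern)), 64)
  out <- probe_generator(G, x, layer = 0)$output$samples
  # O(n^2) causal convolution oracle
  oracle <- vapply(seq_len(64), function(t) {
    acc <- 0
    for (j in seq_along(kern)) {
      if (t - j + 1 >= 1) acc <- acc + kern[j] * x[t - j + 1]
    }
    acc
  }, numeric(1))
  expect_equal(as.vector(out), oracle, tolerance = 1e-12)
})

test_that("discriminator probe of silence is constant and probing is deterministic", {
  ck <- tiny_checkpoint()
  sil <- waveform(numeric(ck$cfg$out_len) + 0, ck$cfg$sample_rate)
  pr <- probe_discriminator(ck$D, sil, layer = 1)
  # shift invariance on constant input: bias-determined constant trace away
  # from the padded edges
  core <- pr$values[3:(length(pr$values) - 3)]
  expect_lt(diff(range(core)), 1e-12)
  stim <- waveform(runif(ck$cfg$out_len, -1, 1), ck$cfg$sample_rate)
  p1 <- probe_discriminator(ck$D, stim)
  p2 <- probe_discriminator(ck$D, stim)
  expect_identical(p1$values, p2$values)
  expect_identical(p1$upsampled, p2$upsampled)
})
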