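mk_trace <- function(v, rate = 5000, t0 = 0) {
  data.frame(time = t0 + (seq_along(v) - 1) / rate, value = v)
}

test_that("burst alignment recovers constructed delays exactly", {
  sim <- simulate_cabr(cabr_sim_spec(noise_sd = 0))
  a <- mk_trace(sim$samples, rate = sim$rate)
  al0 <- align_at_burst(a, a)
  expect_identical(al0$shift, 0)
  # b = a delayed by 7 ms
  d <- round(0.007 * sim$rate)
  b <- mk_trace(c(numeric(d), sim$samples), rate = sim$rate)
  al <- align_at_burst(a, b)
  expect_equal(al$shift, 0.007, tolerance = 1e-9)
  # after alignment, burst peaks coincide within one sample
  pa <- al$a$time[which.max(abs(al$a$value))]
  pb <- al$b$time[which.max(abs(al$b$value))]
  expect_lt(abs(pa - pb), 1 / sim$rate)
})

test_that("rescaling subtracts the silence baseline and resampling is exact on ramps", {
  ramp <- mk_trace(seq(0, 1, length.out = 101), rate = 100)
  out <- rescale_and_resample(ramp, target_times = ramp$time, scale_factor = 1,
                              silence_window = c(-1, 0))
  expect_equal(out$value, ramp$value, tolerance = 1e-12)
  # downsampling a linear ramp under linear interpolation is exact
  down <- rescale_and_resample(ramp, target_rate = 20, scale_factor = 1,
                               silence_window = c(-1, 0))
  expect_equal(down$value, down$time, tolerance = 1e-12)
  # baseline: a constant offset over the silence window is removed
  shifted <- mk_trace(ramp$value + 3, rate = 100)
  out2 <- rescale_and_resample(shifted, target_times = ramp$time,
                               scale_factor = 2, silence_window = c(0, 0.005))
  expect_equal(out2$value, 2 * ramp$value, tolerance = 1e-12)
  expect_error(rescale_and_resample(ramp, scale_factor = 0,
                                    target_rate = 10), "scale_factor")
})

test_that("Pearson r is invariant to the display scaling", {
  set.seed(3)
  a <- mk_trace(rnorm(60))
  b <- mk_trace(rnorm(60) + a$value)
  r1 <- dtw_correlate(a, b, windows = list(c(0, 0.011)))$r_per_window$r
  b50 <- mk_trace(50 * b$value)
  r50 <- dtw_correlate(a, b50, windows = list(c(0, 0.011)),
                       mode = "aligned")$r_per_window$r
  r1a <- dtw_correlate(a, b, windows = list(c(0, 0.011)),
                       mode = "aligned")$r_per_window$r
  expect_equal(r50, r1a, tolerance = 1e-12)
  expect_true(abs(r1) <= 1)
})

test_that("DTW of a series with itself is zero along the diagonal with r = 1", {
  set.seed(4)
  a <- mk_trace(rnorm(40))
  res <- dtw_correlate(a, a, windows = list(c(0, 0.0078)))
  expect_identical(res$dtw_distance, 0)
  expect_equal(res$r_per_window$r, 1)
  expect_equal(res$path[, 1], res$path[, 2])
})

test_that("DTW cost equals the exhaustive oracle on short seeded pairs", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(2:10, 1)
    m <- sample(2:10, 1)
    a <- round(rnorm(n), 2)
    b <- round(rnorm(m), 2)
    al <- dtw_align(a, b)
    expect_equal(al$distance, dtw_oracle(a, b), tolerance = 1e-12)
    # symmetry and path endpoints/monotonicity
    expect_equal(dtw_align(b, a)$distance, al$distance, tolerance = 1e-12)
    expect_identical(al$path[1, ], c(1L, 1L))
    expect_identical(al$path[nrow(al$path), ], c(n, m))
    expect_true(all(diff(al$path[, 1]) >= 0))
    expect_true(all(diff(al$path[, 2]) >= 0))
  }
})

test_that("windows outside the overlap raise an error", {
  a <- mk_trace(rnorm(20))
  expect_error(dtw_correlate(a, a, windows = list(c(0, 1))), "outside")
})

test_that("the full comparison pipeline recovers high correlation for a smoothed copy", {
  sim <- simulate_cabr(cabr_sim_spec(noise_sd = 0.01, seed = 21))
  cabr <- mk_trace(sim$samples, rate = sim$rate)
  # probe: smoothed + decimated + scaled-down rendition of the same response
  sm <- stats::filter(sim$samples, rep(1 / 9, 9), sides = 2)
  sm[is.na(sm)] <- 0
  probe_full <- mk_trace(as.numeric(sm) / 40 + 0.002, rate = sim$rate)
  probe <- rescale_and_resample(probe_full, target_times = cabr$time,
                                scale_factor = 40,
                                silence_window = c(0.006, 0.012))
  al <- align_at_burst(cabr, probe)
  res <- dtw_correlate(al$a, al$b,
                       windows = list(c(0.005, 0.120)), mode = "warped")
  expect_gte(res$r_per_window$r, 0.95)
})
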