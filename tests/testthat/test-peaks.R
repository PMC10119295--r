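test_that("parabolic interpolation is exact on sampled parabolas", {
  t <- 0:7
  y <- -(t - 3.3)^2
  expect_equal(peak_time(y, rate = 1, interval = c(0, 8)), 3.3,
               tolerance = 1e-12)
  y2 <- 5 - 2 * (t - 4.7)^2
  expect_equal(peak_time(y2, rate = 1, interval = c(0, 8)), 4.7,
               tolerance = 1e-12)
})

test_that("per-period sinusoid peaks are within a quarter sample of the crest", {
  rate <- 16000
  f <- 95
  t <- seq(0, 0.1, by = 1 / rate)
  y <- sin(2 * pi * f * t)
  # dense-grid oracle at 1 MHz
  for (k in 0:8) {
    iv <- c(k / f, (k + 1) / f)
    td <- seq(iv[1], min(iv[2], 0.1), by = 1e-6)
    oracle <- td[which.max(sin(2 * pi * f * td))]
    est <- peak_time(y, rate, iv)
    expect_lt(abs(est - oracle), 1 / (4 * rate))
  }
})

test_that("ties break to the leftmost maximum and boundaries stay discrete", {
  y <- c(0, 1, 1, 0, 0)
  expect_equal(as.numeric(peak_time(y, 1, c(0, 5))), 1)
  # maximum at the selection boundary: discrete time returned
  y2 <- c(5, 4, 3, 2, 1)
  expect_equal(as.numeric(peak_time(y2, 1, c(0, 5))), 0)
  # flat series: leftmost, flagged
  pf <- peak_time(rep(2, 5), 1, c(0, 5))
  expect_equal(as.numeric(pf), 0)
  expect_true(isTRUE(attr(pf, "flat")))
  expect_error(peak_time(y, 1, c(0, 0.002)), "3 samples")
})

test_that("refinement never moves the peak more than one sample", {
  set.seed(12)
  for (i in 1:50) {
    y <- rnorm(50)
    est <- as.numeric(peak_time(y, 1, c(0, 50)))
    expect_lte(abs(est - (which.max(y) - 1)), 1)
  }
})

test_that("stimulus annotation finds the burst and 8-9 vocalic periods", {
  s <- synthesize_stimulus(stimulus_spec())
  ann <- annotate_periods(s)
  expect_true(0L %in% ann$n)
  expect_true(sum(ann$n >= 1) %in% 8:9)
  # burst precedes voicing
  expect_lt(ann$end[ann$n == 0], ann$start[ann$n == 1])
})

test_that("a 100 Hz pulse train yields exactly 10 periods of 10 ms", {
  pt <- waveform(as.numeric(((0:1599) %% 160) == 0), 16000)
  ann <- annotate_periods(pt)
  expect_identical(sum(ann$n >= 1), 10L)
  expect_equal(median(ann$end - ann$start), 0.010, tolerance = 1e-3)
})

test_that("silence yields an empty annotation with a reason", {
  ann <- annotate_periods(waveform(numeric(1600), 16000))
  expect_identical(nrow(ann), 0L)
  expect_match(attr(ann, "reason"), "no periodicity")
})

test_that("a probe delayed by 1 ms gives delta_t of +1 ms at every period", {
  sim <- simulate_cabr(cabr_sim_spec(noise_sd = 0))
  d <- round(0.001 * sim$rate)
  delayed <- data.frame(time = wave_times(sim),
                        value = c(numeric(d),
                                  sim$samples[1:(length(sim$samples) - d)]))
  ann <- attr(sim, "annotation")
  rec <- peak_latencies(sim, delayed, ann[ann$n >= 1 & ann$n <= 10, ])
  expect_equal(rec$delta_t, rep(-0.001, nrow(rec)), tolerance = 2e-5)
  # probe identical to |output|: delta_t exactly zero
  same <- data.frame(time = wave_times(sim), value = abs(sim$samples))
  rec0 <- peak_latencies(sim, same, ann[ann$n >= 1, ])
  expect_equal(rec0$delta_t, rep(0, nrow(rec0)), tolerance = 1e-12)
})

test_that("delta_t is antisymmetric and invariant to a common time shift", {
  sim <- simulate_cabr(cabr_sim_spec(noise_sd = 0.01, seed = 9))
  ann <- attr(sim, "annotation")
  ann <- ann[ann$n >= 1 & ann$n <= 8, ]
  pr <- simulate_cabr(cabr_sim_spec(period_offsets = offsets_for(5e-4, 3),
                                    noise_sd = 0.01, seed = 10))
  tr_sim <- data.frame(time = wave_times(sim), value = abs(sim$samples))
  tr_pr <- data.frame(time = wave_times(pr), value = abs(pr$samples))
  a_fwd <- peak_latencies(sim, tr_pr, ann)
  b_rev <- peak_latencies(pr, tr_sim, ann)
  expect_equal(a_fwd$delta_t, -b_rev$delta_t, tolerance = 1e-9)
  # shifting both signals by tau leaves delta_t unchanged
  tau <- 0.002
  sim2 <- waveform(c(numeric(round(tau * sim$rate)), sim$samples), sim$rate)
  pr2 <- data.frame(time = tr_pr$time + tau, value = tr_pr$value)
  ann2 <- transform(ann, start = start + tau, end = end + tau)
  shifted <- peak_latencies(sim2, pr2, ann2)
  expect_equal(shifted$delta_t, a_fwd$delta_t, tolerance = 1e-9)
})

test_that("periods from 12 upward are flagged excluded", {
  ann <- data.frame(n = c(10, 11, 12, 13),
                    start = c(0.10, 0.11, 0.12, 0.13),
                    end = c(0.11, 0.12, 0.13, 0.14))
  sim <- simulate_cabr(cabr_sim_spec(dur = 0.160, noise_sd = 0))
  tr <- data.frame(time = wave_times(sim), value = abs(sim$samples))
  rec <- peak_latencies(sim, tr, ann)
  expect_identical(rec$excluded, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("TextGrid annotations reproduce the manual workflow", {
  ann <- data.frame(n = 0:3, start = c(0, 0.012, 0.022, 0.033),
                    end = c(0.004, 0.022, 0.033, 0.043))
  p <- tempfile(fileext = ".TextGrid")
  write_textgrid(list(periods = data.frame(label = as.character(ann$n),
                                           start = ann$start,
                                           end = ann$end)), p)
  back <- annotation_from_textgrid(p)
  expect_equal(back$n, ann$n)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  unlink(p)
})
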