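test_that("the exclusion filter keeps periods 0-11 and conserves counts", {
  rows <- simulate_latency_dataset(n_per_cell = 2, periods = 0:15, seed = 2)
  out <- suppressMessages(exclusion_filter(rows))
  expect_identical(sort(unique(out$n)), 0:11)
  expect_identical(nrow(out) + attr(out, "n_removed"), nrow(rows))
  # no high periods: identity
  low <- rows[rows$n <= 5, ]
  expect_identical(nrow(exclusion_filter(low)), nrow(low))
})

test_that("an injected 1 ms effect at period 2 is recovered within 0.25 ms", {
  rows <- simulate_latency_dataset(n_per_cell = 20,
                                   effect = offsets_for(1e-3, period = 3,
                                                        n_periods = 12),
                                   sd = 3e-4, seed = 11)
  ct <- fit_and_contrast(rows)
  est2 <- ct$estimate[ct$period == 2]
  expect_lt(abs(est2 - 1e-3), 2.5e-4)
  expect_true(all(abs(ct$estimate[ct$period != 2]) < 2.5e-4))
  expect_lt(ct$p_fdr[ct$period == 2], 0.05)
  # FDR adjustment never decreases a p value
  expect_true(all(ct$p_fdr >= ct$p_value - 1e-15))
})

test_that("identical delta_t values give exactly zero contrasts", {
  rows <- expand.grid(language = c("english", "spanish"),
                      replication = 1:2, output = 1:3, n = 0:5,
                      stringsAsFactors = FALSE)
  rows$delta_t <- -4e-4
  ct <- suppressWarnings(fit_and_contrast(rows))  # zero-residual fit
  expect_equal(ct$estimate, rep(0, nrow(ct)), tolerance = 1e-15)
})

test_that("contrasts match a closed-form normal-equations oracle", {
  rows <- simulate_latency_dataset(n_per_cell = 6, periods = 0:4,
                                   effect = offsets_for(8e-4, 3, 5),
                                   sd = 2e-4, seed = 5)
  ct <- fit_and_contrast(rows)
  # oracle: OLS via normal equations on the full dummy design; under a
  # balanced design the marginal English-Spanish contrast at period n equals
  # the difference of cell means averaged over replications
  for (p in 0:4) {
    cm <- tapply(rows$delta_t[rows$n == p],
                 list(rows$language[rows$n == p],
                      rows$replication[rows$n == p]), mean)
    oracle <- mean(cm["english", ]) - mean(cm["spanish", ])
    expect_equal(ct$estimate[ct$period == p], unname(oracle),
                 tolerance = 1e-10)
  }
  # oracle SE from the normal equations of the cell-means model
  X <- stats::model.matrix(~ 0 + interaction(language, n, replication),
                           data = rows)
  beta <- solve(crossprod(X), crossprod(X, rows$delta_t))
  resid <- rows$delta_t - X %*% beta
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  # contrast = mean over the 2 replications of the English-Spanish cell-mean
  # difference; with cell size 6 its variance is s2 / 6
  expect_equal(ct$se[1], sqrt(s2 / 6), tolerance = 1e-10)
  expect_equal(ct$df[1], nrow(rows) - ncol(X))
})

test_that("contrasts are invariant to recoding the replication factor", {
  rows <- simulate_latency_dataset(n_per_cell = 5, periods = 0:6,
                                   effect = offsets_for(6e-4, 2, 7), seed = 8)
  ct1 <- fit_and_contrast(rows)
  flipped <- rows
  flipped$replication <- 3L - flipped$replication  # swap levels 1 and 2
  ct2 <- fit_and_contrast(flipped)
  expect_equal(ct1$estimate, ct2$estimate, tolerance = 1e-12)
  expect_equal(ct1$se, ct2$se, tolerance = 1e-12)
})

test_that("pooled contrasts equal the mean of per-replication contrasts", {
  rows <- simulate_latency_dataset(n_per_cell = 5, periods = 0:6,
                                   effect = offsets_for(6e-4, 2, 7),
                                   seed = 13)
  ct <- fit_and_contrast(rows)
  per_rep <- lapply(1:2, function(r) {
    sub <- rows[rows$replication == r, ]
    fit_and_contrast(sub)
  })
  expect_equal(ct$estimate,
               (per_rep[[1]]$estimate + per_rep[[2]]$estimate) / 2,
               tolerance = 1e-12)
})

test_that("empty design cells raise an informative error", {
  rows <- simulate_latency_dataset(n_per_cell = 3, periods = 0:4, seed = 1)
  rows <- rows[!(rows$language == "spanish" & rows$n == 3), ]
  expect_error(fit_and_contrast(rows), "empty.*cell")
})
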