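make_utt <- function(words, phones, dur = 1, rate = 16000) {
  aligned_utterance(waveform(stats::rnorm(dur * rate) * 0.1, rate),
                    words = words, phones = phones, corpus = "test")
}

test_that("slice_cv extracts word-initial stop+vowel sequences only", {
  words <- data.frame(label = c("ba", "ana", "ta"),
                      start = c(0.0, 0.3, 0.6), end = c(0.2, 0.5, 0.8))
  phones <- data.frame(label = c("b", "aa", "aa", "n", "ax", "t", "iy"),
                       start = c(0.0, 0.05, 0.3, 0.38, 0.42, 0.6, 0.65),
                       end = c(0.05, 0.2, 0.38, 0.42, 0.5, 0.65, 0.8))
  cs <- slice_cv(make_utt(words, phones), window_len = 4096)
  expect_identical(length(cs$clips), 2L)
  expect_identical(cs$meta$stop, c("b", "t"))
  expect_identical(cs$meta$word, c("ba", "ta"))
  # all clips padded to the window
  expect_true(all(vapply(cs$clips, length, integer(1)) == 4096L))
})

test_that("word-internal stops yield no clip", {
  words <- data.frame(label = "apa", start = 0, end = 0.3)
  phones <- data.frame(label = c("aa", "p", "aa"),
                       start = c(0, 0.1, 0.15), end = c(0.1, 0.15, 0.3))
  cs <- slice_cv(make_utt(words, phones), window_len = 2048)
  expect_identical(length(cs$clips), 0L)
})

test_that("TIMIT closures are merged with their release at closure onset", {
  dir <- tempfile()
  dir.create(dir)
  phn <- file.path(dir, "utt.phn")
  writeLines(c("0 800 bcl", "800 1600 b", "1600 4800 aa"), phn)
  wrd <- file.path(dir, "utt.wrd")
  writeLines("0 4800 ba", wrd)
  phones <- read_timit_alignment(phn)
  words <- read_timit_alignment(wrd)
  expect_equal(phones$start, c(0, 0.05, 0.1))
  utt <- make_utt(words, phones, dur = 0.3)
  cs <- slice_cv(utt, window_len = 8192)
  expect_identical(length(cs$clips), 1L)
  expect_identical(cs$meta$stop, "b")
  # clip spans closure onset to vowel end: 0.3 s of signal then padding
  expect_gt(max(abs(cs$clips[[1]]$samples[1:100])), 0)
  expect_error(read_timit_alignment(file.path(dir, "missing.phn")), "missing")
})

test_that("mini corpus slices to exactly 6 stops x n tokens with 50% voiced", {
  utts <- make_mini_corpus(n_per_stop = 5, seed = 3)
  cs <- slice_cv(utts)
  expect_identical(length(cs$clips), 30L)
  tab <- count_stops(cs)
  expect_true(all(tab[, c("p", "t", "k", "b", "d", "g")] == 5))
  expect_equal(tab$pct_voiced, 50.0)
  # slicing is deterministic and clip count is bounded by word count
  cs2 <- slice_cv(make_mini_corpus(n_per_stop = 5, seed = 3))
  expect_equal(cs$meta, cs2$meta)
  expect_lte(length(cs$clips), length(utts))
})

test_that("stop-count tabulation reproduces the published corpus totals", {
  timit <- count_stops(c(p = 1018, t = 1799, k = 2112,
                         b = 1789, d = 2530, g = 673))
  expect_identical(timit$voiceless, 4929)
  expect_identical(timit$voiced, 4992)
  expect_identical(timit$pct_voiced, 50.3)
  dimex <- count_stops(c(p = 3015, t = 1808, k = 5558,
                         b = 1477, d = 8023, g = 478))
  expect_identical(dimex$voiceless, 10381)
  expect_identical(dimex$voiced, 9978)
  expect_identical(dimex$pct_voiced, 49.0)
  zero <- count_stops(c(p = 0, t = 0, k = 0, b = 0, d = 0, g = 0))
  expect_true(is.na(zero$pct_voiced))
})

test_that("TextGrid alignments round-trip through the writer and reader", {
  tiers <- list(
    words = data.frame(label = c("ba", "ta"), start = c(0, 0.5),
                       end = c(0.4, 0.9)),
    phones = data.frame(label = c("b", "aa", "t", "aa"),
                        start = c(0, 0.05, 0.5, 0.56),
                        end = c(0.05, 0.4, 0.56, 0.9)))
  p <- tempfile(fileext = ".TextGrid")
  write_textgrid(tiers, p)
  back <- read_textgrid(p)
  expect_identical(names(back), c("words", "phones"))
  expect_equal(back$phones$start, tiers$phones$start)
  expect_equal(back$phones$end, tiers$phones$end)
  expect_identical(back$phones$label, tiers$phones$label)
  unlink(p)
})

test_that("slicing errors on a missing alignment tier", {
  utt <- make_utt(data.frame(label = "ba", start = 0, end = 0.2),
                  data.frame(label = character(), start = numeric(),
                             end = numeric()))
  expect_error(slice_cv(utt), "phone alignment")
})
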