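#' Time-aligned utterance
#'
#' Audio plus word- and phone-level alignments, the unit consumed by
#' [slice_cv()]. Intervals are half-open `[start, end)` in seconds.
#'
#' @param audio A `waveform`.
#' @param words data.frame with columns `label`, `start`, `end` (seconds).
#' @param phones data.frame with columns `label`, `start`, `end` (seconds).
#' @param corpus Corpus name carried into clip metadata.
#' @return An object of class `aligned_utterance`.
#' @export
aligned_utterance <- function(audio, words, phones, corpus = "unknown") {
  stopifnot(inherits(audio, "waveform"))
  for (df in list(words, phones)) {
    stopifnot(all(c("label", "start", "end") %in% names(df)))
    if (nrow(df) > 1 && any(diff(df$start) < 0)) {
      stop("aligned_utterance: intervals must be ordered by start")
    }
    if (any(df$end < df$start)) {
      stop("aligned_utterance: interval end before start")
    }
    if (any(df$end > wave_duration(audio) + 1e-9)) {
      stop("aligned_utterance: interval beyond audio duration")
    }
  }
  structure(list(audio = audio, words = words, phones = phones,
                 corpus = corpus),
            class = "aligned_utterance")
}

# TIMIT closure labels merged into their release stop: the clip starts at
# closure onset.
timit_closures <- c(bcl = "b", dcl = "d", gcl = "g",
                    pcl = "p", tcl = "t", kcl = "k")

#' TIMIT ARPAbet vowel labels
#' @export
timit_vowels <- c("iy", "ih", "eh", "ey", "ae", "aa", "aw", "ay", "ah", "ao",
                  "oy", "ow", "uh", "uw", "ux", "er", "ax", "ix", "axr",
                  "ax-h")

#' Read a TIMIT-style alignment file
#'
#' Reads the `.phn`/`.wrd` format: one interval per line, two sample indices
#' followed by a label, whitespace-separated. Sample indices are converted to
#' seconds at `rate`.
#'
#' @param path File path.
#' @param rate Sampling rate of the associated audio, Hz.
#' @return data.frame with `label`, `start`, `end` in seconds.
#' @export
read_timit_alignment <- function(path, rate = 16000) {
  if (!file.exists(path)) stop("read_timit_alignment: missing file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("read_timit_alignment: malformed line in ", path)
  data.frame(
    label = vapply(parts, `[[`, character(1), 3),
    start = vapply(parts, function(p) as.numeric(p[[1]]), numeric(1)) / rate,
    end = vapply(parts, function(p) as.numeric(p[[2]]), numeric(1)) / rate,
    stringsAsFactors = FALSE
  )
}

# Merge TIMIT closure+release sequences into a single stop interval starting
# at closure onset.
merge_closures <- function(phones) {
  if (nrow(phones) < 2) return(phones)
  keep <- rep(TRUE, nrow(phones))
  for (i in seq_len(nrow(phones) - 1)) {
    lab <- phones$label[i]
    if (lab %in% names(timit_closures) &&
        phones$label[i + 1] == timit_closures[[lab]]) {
      phones$start[i + 1] <- phones$start[i]
      keep[i] <- FALSE
    }
  }
  ph <- phones[keep, , drop = FALSE]
  ph$label <- ifelse(ph$label %in% names(timit_closures),
                     unname(timit_closures[ph$label]), ph$label)
  rownames(ph) <- NULL
  ph
}

#' Slice word-initial stop+vowel sequences from aligned utterances
#'
#' Extracts one clip per word whose first phone is a stop in `stop_set` and
#' whose second phone is a vowel in `vowel_set` (a `#CV` sequence, `#` a word
#' boundary). The clip spans `[word start, vowel end)`, is peak-normalized to
#' 0.9, and right-zero-padded (or truncated, with a warning) to `window_len`
#' samples. TIMIT closure labels are merged with their release before
#' matching.
#'
#' @param utts List of [aligned_utterance()] objects.
#' @param stop_set Stop labels to match word-initially.
#' @param vowel_set Vowel labels defining `V`.
#' @param window_len Model window length in samples.
#' @return An object of class `clip_set`: list with `clips` (list of
#'   `waveform`s, all `window_len` samples) and `meta` (data.frame with
#'   `corpus`, `word`, `stop`, `vowel`, `duration`).
#' @export
slice_cv <- function(utts, stop_set = c("p", "t", "k", "b", "d", "g"),
                     vowel_set = timit_vowels, window_len = 16384) {
  if (inherits(utts, "aligned_utterance")) utts <- list(utts)
  clips <- list()
  meta <- list()
  for (utt in utts) {
    if (is.null(utt$phones) || nrow(utt$phones) == 0) {
      stop("slice_cv: utterance has no phone alignment tier")
    }
    phones <- merge_closures(utt$phones)
    for (wi in seq_len(nrow(utt$words))) {
      ws <- utt$words$start[wi]; we <- utt$words$end[wi]
      inside <- which(phones$start >= ws - 1e-9 & phones$end <= we + 1e-9)
      if (length(inside) < 2) next
      p1 <- phones[inside[1], ]; p2 <- phones[inside[2], ]
      if (!(p1$label %in% stop_set) || !(p2$label %in% vowel_set)) next
      rate <- utt$audio$rate
      i0 <- 1L + round(p1$start * rate)
      i1 <- round(p2$end * rate)
      seg <- utt$audio$samples[i0:min(i1, length(utt$audio$samples))]
      if (length(seg) > window_len) {
        warning(sprintf("slice_cv: clip '%s' (%d samples) truncated to %d",
                        utt$words$label[wi], length(seg), window_len))
        seg <- seg[seq_len(window_len)]
      }
      peak <- max(abs(seg))
      if (peak > 0) seg <- seg / peak * 0.9
      seg <- c(seg, numeric(window_len - length(seg)))
      clips[[length(clips) + 1L]] <-
        waveform(seg, rate, label = utt$words$label[wi])
      meta[[length(meta) + 1L]] <- data.frame(
        corpus = utt$corpus, word = utt$words$label[wi],
        stop = p1$label, vowel = p2$label,
        duration = p2$end - p1$start, stringsAsFactors = FALSE)
    }
  }
  structure(list(clips = clips,
                 meta = if (length(meta)) do.call(rbind, meta) else
                   data.frame(corpus = character(), word = character(),
                              stop = character(), vowel = character(),
                              duration = numeric())),
            class = "clip_set")
}

#' @export
print.clip_set <- function(x, ...) {
  cat(sprintf("<clip_set> %d clips\n", length(x$clips)))
  if (nrow(x$meta)) print(table(x$meta$stop))
  invisible(x)
}

#' Tabulate stop counts
#'
#' Per-stop counts with voiceless (`p+t+k`) and voiced (`b+d+g`) totals and
#' the percentage voiced (rounded to 1 decimal). Accepts either a `clip_set`
#' from [slice_cv()] or a named numeric vector of counts.
#'
#' @param x A `clip_set`, or a named numeric vector with names among
#'   `p,t,k,b,d,g`.
#' @return One-row data.frame with columns `p,t,k,b,d,g`, `voiceless`,
#'   `voiced`, `pct_voiced` (`NA` when there are no clips).
#' @export
count_stops <- function(x) {
  if (inherits(x, "clip_set")) {
    tab <- table(factor(x$meta$stop, levels = c("p", "t", "k", "b", "d", "g")))
    counts <- as.numeric(tab)
    names(counts) <- names(tab)
  } else {
    counts <- stats::setNames(numeric(6), c("p", "t", "k", "b", "d", "g"))
    counts[names(x)] <- as.numeric(x)
  }
  voiceless <- sum(counts[c("p", "t", "k")])
  voiced <- sum(counts[c("b", "d", "g")])
  pct <- if (voiceless + voiced == 0) NA_real_ else
    round(100 * voiced / (voiced + voiceless), 1)
  out <- as.data.frame(as.list(counts))
  out$voiceless <- voiceless
  out$voiced <- voiced
  out$pct_voiced <- pct
  out
}
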