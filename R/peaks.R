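#' Peak time within an interval, with parabolic interpolation
#'
#' Finds the discrete argmax of `values` within the half-open time interval
#' `[interval[1], interval[2])` and refines it by fitting a parabola to the
#' maximum and its two neighbours. Ties take the leftmost maximum; at a
#' boundary maximum the discrete time is returned; a flat selection returns
#' its leftmost sample and is flagged with attribute `"flat"`. The refinement
#' can move the peak at most one sample.
#'
#' @param values Numeric vector sampled uniformly at `rate`, sample `i` at
#'   time `t0 + (i - 1) / rate`.
#' @param rate Sampling rate in Hz.
#' @param interval `c(start, end)` in seconds.
#' @param t0 Time of the first sample (s).
#' @return Peak time in seconds.
#' @export
peak_time <- function(values, rate, interval, t0 = 0) {
  idx <- which((t0 + (seq_along(values) - 1) / rate) >= interval[1] &
               (t0 + (seq_along(values) - 1) / rate) < interval[2])
  if (length(idx) < 3) {
    stop("peak_time: interval must contain at least 3 samples")
  }
  y <- values[idx]
  k <- which.max(y)
  flat <- length(unique(y)) == 1L
  # equal adjacent maxima: keep the leftmost discrete sample (tie-break)
  tie <- k < length(y) && y[k + 1] == y[k]
  delta <- 0
  if (!flat && !tie && k > 1 && k < length(y)) {
    denom <- y[k - 1] - 2 * y[k] + y[k + 1]
    if (denom < 0) {
      delta <- 0.5 * (y[k - 1] - y[k + 1]) / denom
      delta <- max(-1, min(1, delta))
    }
  }
  out <- t0 + (idx[k] - 1 + delta) / rate
  if (flat) attr(out, "flat") <- TRUE
  out
}

peak_time_trace <- function(trace, interval) {
  rate <- 1 / stats::median(diff(trace$time))
  peak_time(trace$value, rate, interval, t0 = trace$time[1])
}

#' Annotate the burst and vocalic periods of a waveform
#'
#' Automatic period annotation: an autocorrelation F0 track locates the
#' voiced region; glottal-period times are laid out from the strongest
#' waveform peak by integrating the F0 trajectory in both directions;
#' period boundaries are placed a quarter period before each predicted peak
#' (so every period's peak is interior to its interval). The burst, if
#' present, is detected as a short-time energy transient exceeding 6 dB
#' above the pre-voicing noise floor, and annotated as the 0th period;
#' vocalic periods are numbered from 1. The procedure is deterministic.
#'
#' A manual annotation (e.g. from a Praat TextGrid interval tier with labels
#' "0", "1", ...) can be substituted via [annotation_from_textgrid()].
#'
#' @param w A `waveform`.
#' @param f0_range `c(fmin, fmax)` search range in Hz.
#' @param min_rel_amp Minimum local amplitude, relative to the anchor peak,
#'   for a predicted period to be retained.
#' @return data.frame with columns `n`, `start`, `end` (seconds); empty with
#'   attribute `"reason"` when no periodicity is detected.
#' @export
annotate_periods <- function(w, f0_range = c(70, 140), min_rel_amp = 0.15) {
  empty <- function(reason) {
    out <- data.frame(n = integer(), start = numeric(), end = numeric())
    attr(out, "reason") <- reason
    out
  }
  track <- track_f0(w, fmin = f0_range[1], fmax = f0_range[2])
  voiced <- track$voiced
  if (!any(voiced)) return(empty("no periodicity"))
  runs <- rle(voiced)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  vr <- which(runs$values)
  best <- vr[which.max(runs$lengths[vr])]
  fr0 <- starts[best]
  fr1 <- ends[best]
  v_start <- max(0, track$time[fr0] - 1.5 / f0_range[1])
  v_end <- min(wave_duration(w), track$time[fr1] + 1.5 / f0_range[1])
  x <- abs(w$samples)
  tt <- wave_times(w)
  sel <- tt >= v_start & tt < v_end
  if (sum(sel) < 3) return(empty("voiced region too short"))
  # anchor on the strongest peak in the middle of the voiced region, well
  # away from the burst transient
  mid <- tt >= v_start + (v_end - v_start) / 3 &
    tt < v_end - (v_end - v_start) / 3
  if (sum(mid & sel) >= 3) sel <- mid & sel
  anchor_i <- which(sel)[which.max(x[sel])]
  anchor_t <- tt[anchor_i]
  anchor_amp <- x[anchor_i]
  # A period candidate must carry a real peak near its predicted position:
  # either an interior local maximum of the window, or (for signals whose
  # peak sits on the window edge, e.g. the first sample of a pulse train) an
  # amplitude comparable to the anchor. A decaying tail of a neighbouring
  # transient leaking over the window edge fails both.
  has_peak <- function(t, T) {
    s <- which(tt >= t - 0.25 * T & tt < t + 0.25 * T)
    if (length(s) == 0) return(FALSE)
    amp <- max(x[s])
    if (amp < min_rel_amp * anchor_amp) return(FALSE)
    k <- which.max(x[s])
    interior <- k > 1 && k < length(s)
    clipped <- t - 0.25 * T < 0 || t + 0.25 * T > tt[length(tt)]
    interior || (clipped && amp >= 2 * min_rel_amp * anchor_amp)
  }
  period_at <- function(t) 1 / f0_at(track, t)
  # predicted period peaks: step from the anchor in both directions
  peaks <- anchor_t
  t <- anchor_t
  repeat {
    T <- period_at(t - 0.5 * period_at(t))
    t_prev <- t - T
    if (t_prev < v_start - 0.5 * T) break
    if (!has_peak(t_prev, T)) break
    peaks <- c(t_prev, peaks)
    t <- t_prev
  }
  t <- anchor_t
  repeat {
    T <- period_at(t + 0.5 * period_at(t))
    t_next <- t + T
    if (t_next > v_end + 0.25 * T) break
    if (!has_peak(t_next, T)) break
    peaks <- c(peaks, t_next)
    t <- t_next
  }
  # A leading transient separated from the vowel by a silent stretch (the
  # release burst before the VOT gap) is not a vocalic period: drop leading
  # peaks whose gap to the next peak is far more silent than is typical of
  # the inter-peak gaps (a uniformly sparse signal such as a pulse train is
  # unaffected, since all its gaps look alike).
  if (length(peaks) >= 3) {
    gap_floor <- function(i) {
      Ti <- period_at(peaks[i])
      s <- tt >= peaks[i] + 0.25 * Ti & tt < peaks[i + 1] - 0.25 * Ti
      if (sum(s) < 2) NA_real_ else {
        win <- max(1L, round(0.001 * w$rate))
        e <- x[s]
        n_sub <- length(e) %/% win
        if (n_sub < 1) min(e) else
          min(vapply(seq_len(n_sub), function(j)
            max(e[((j - 1) * win + 1):(j * win)]), numeric(1)))
      }
    }
    floors <- vapply(seq_len(length(peaks) - 1L), gap_floor, numeric(1))
    med <- stats::median(floors, na.rm = TRUE)
    while (length(peaks) >= 3 && is.finite(floors[1]) && is.finite(med) &&
           floors[1] < 0.15 * med) {
      peaks <- peaks[-1]
      floors <- floors[-1]
    }
  }
  # re-anchor every predicted peak on the actual local waveform maximum, so
  # accumulated F0-track drift does not push true peaks toward interval edges
  peaks <- vapply(peaks, function(p) {
    T <- period_at(p)
    s <- which(tt >= p - 0.3 * T & tt < p + 0.3 * T)
    if (length(s) == 0) p else tt[s[which.max(x[s])]]
  }, numeric(1))
  peaks <- peaks[c(TRUE, diff(peaks) > 0)]
  Tn <- vapply(peaks, period_at, numeric(1))
  bounds <- pmax(0, peaks - 0.25 * Tn)
  bounds <- c(bounds, min(wave_duration(w),
                          peaks[length(peaks)] + 0.75 * Tn[length(Tn)]))
  ann <- data.frame(n = seq_along(peaks), start = bounds[-length(bounds)],
                    end = bounds[-1])
  # burst: short-time energy transient 6 dB above the noise floor before the
  # first vocalic period
  pre_end <- ann$start[1]
  if (pre_end > 0.002) {
    win <- max(1L, round(0.001 * w$rate))
    n_win <- floor(pre_end * w$rate / win)
    if (n_win >= 2) {
      e <- vapply(seq_len(n_win), function(i) {
        sqrt(mean(w$samples[((i - 1) * win + 1):(i * win)]^2))
      }, numeric(1))
      floor_e <- stats::quantile(e, 0.25, names = FALSE)
      thresh <- max(2 * floor_e, 0.02 * anchor_amp)
      hot <- which(e > thresh)
      if (length(hot) > 0) {
        b_start <- (hot[1] - 1) * win / w$rate
        b_end <- min(hot[length(hot)] * win / w$rate + 0.001, pre_end)
        ann <- rbind(data.frame(n = 0L, start = b_start, end = b_end), ann)
      }
    }
  }
  rownames(ann) <- NULL
  attr(ann, "f0_track") <- track
  attr(ann, "anchor") <- anchor_t
  ann
}

#' Read a period annotation from a TextGrid tier
#'
#' Reproduces the manual-annotation workflow: a TextGrid interval tier named
#' `tier` (default `"periods"`) with integer labels `"0"`, `"1"`, ... (the
#' burst being `"0"`) becomes a period annotation; unlabeled intervals are
#' skipped.
#'
#' @param path TextGrid file path (or a tier list from [read_textgrid()]).
#' @param tier Tier name.
#' @return data.frame with columns `n`, `start`, `end`.
#' @export
annotation_from_textgrid <- function(path, tier = "periods") {
  tiers <- if (is.character(path)) read_textgrid(path) else path
  if (!tier %in% names(tiers)) {
    stop("annotation_from_textgrid: no tier named '", tier, "'")
  }
  tg <- tiers[[tier]]
  tg <- tg[grepl("^\\s*\\d+\\s*$", tg$label), , drop = FALSE]
  out <- data.frame(n = as.integer(tg$label), start = tg$start, end = tg$end)
  out[order(out$n), , drop = FALSE]
}

#' Per-period peak latencies for one output/probe pair
#'
#' For each annotated period `n`, measures the peak time of the (absolute
#' valued, by default) audio signal and of the layer probe within the same
#' interval, and their difference `delta_t = t_out - t_conv`. Taking absolute
#' values captures peaks of both polarities, since a rectified-activation
#' probe is non-negative. Periods with `n >= 12` are flagged `excluded`.
#'
#' @param output A `waveform` (the generated output or stimulus).
#' @param probe A `probe_series` upsampled to audio rate, or a
#'   data.frame trace with `time`/`value` on the same clock as `output`.
#' @param annotation Period annotation data.frame (`n`, `start`, `end`).
#' @param use_abs Take `abs()` of the audio before peak picking.
#' @param language,replication,output_id Metadata copied onto each row.
#' @return data.frame of peak records: `language`, `replication`,
#'   `output_id`, `n`, `t_out`, `t_conv`, `delta_t`, `excluded`.
#' @export
peak_latencies <- function(output, probe, annotation, use_abs = TRUE,
                           language = NA_character_,
                           replication = NA_integer_,
                           output_id = NA_character_) {
  stopifnot(inherits(output, "waveform"))
  if (inherits(probe, "probe_series")) {
    pv <- probe$upsampled %||% probe$values
    p_rate <- if (!is.na(probe$rate)) probe$rate else output$rate
    p_t0 <- 0
  } else {
    pv <- probe$value
    p_rate <- 1 / stats::median(diff(probe$time))
    p_t0 <- probe$time[1]
  }
  sig <- if (use_abs) abs(output$samples) else output$samples
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    iv <- c(annotation$start[i], annotation$end[i])
    t_out <- as.numeric(peak_time(sig, output$rate, iv))
    t_conv <- as.numeric(peak_time(pv, p_rate, iv, t0 = p_t0))
    data.frame(language = language, replication = replication,
               output_id = output_id, n = annotation$n[i],
               t_out = t_out, t_conv = t_conv,
               delta_t = t_out - t_conv,
               excluded = annotation$n[i] >= 12L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the pooled latency dataset for matched triples
#'
#' Applies [peak_latencies()] to matched (output, probe, annotation) triples
#' and binds the records, carrying per-triple metadata.
#'
#' @param outputs List of `waveform`s.
#' @param probes List of probes (see [peak_latencies()]).
#' @param annotations List of annotation data.frames; triples whose
#'   annotation is empty (no periodicity detected) are skipped with a
#'   message, mirroring the exclusion of outputs without identifiable
#'   periodic structure.
#' @param use_abs Take absolute values of the audio.
#' @param language,replication,output_id Vectors of per-triple metadata.
#' @return data.frame of peak records.
#' @export
latency_table <- function(outputs, probes, annotations, use_abs = TRUE,
                          language = NA, replication = NA,
                          output_id = seq_along(outputs)) {
  n <- length(outputs)
  stopifnot(length(probes) == n, length(annotations) == n)
  language <- rep_len(language, n)
  replication <- rep_len(replication, n)
  output_id <- rep_len(output_id, n)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(n)) {
    if (nrow(annotations[[i]]) == 0) {
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- peak_latencies(
      outputs[[i]], probes[[i]], annotations[[i]], use_abs = use_abs,
      language = language[i], replication = replication[i],
      output_id = as.character(output_id[i]))
  }
  if (skipped > 0) {
    message("latency_table: skipped ", skipped,
            " output(s) without identifiable periodic structure")
  }
  if (length(rows) == 0) {
    return(data.frame(language = character(), replication = integer(),
                      output_id = character(), n = integer(),
                      t_out = numeric(), t_conv = numeric(),
                      delta_t = numeric(), excluded = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
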