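#' Construct a waveform
#'
#' A waveform is the basic audio container used throughout the package: a
#' numeric sample vector together with its sampling rate in Hz and a free-text
#' label. It holds the synthesized stimulus, training clips, and generator
#' outputs alike.
#'
#' @param samples Numeric vector of audio samples (finite values).
#' @param rate Sampling rate in Hz (positive scalar).
#' @param label Free-text label carried along for bookkeeping.
#' @return An object of class `waveform`: a list with elements `samples`,
#'   `rate`, `label`.
#' @export
waveform <- function(samples, rate, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("waveform: 'samples' must have length >= 1")
  if (!all(is.finite(samples))) stop("waveform: 'samples' must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("waveform: 'rate' must be a positive scalar")
  }
  structure(list(samples = samples, rate = rate, label = as.character(label)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.1f ms)%s\n",
              length(x$samples), x$rate, 1000 * length(x$samples) / x$rate,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param w A `waveform`.
#' @return Duration in seconds.
#' @export
wave_duration <- function(w) length(w$samples) / w$rate

#' Sample times of a waveform
#'
#' Sample `i` (1-based) is anchored at time `(i - 1) / rate` seconds.
#' @param w A `waveform`.
#' @return Numeric vector of per-sample times in seconds.
#' @export
wave_times <- function(w) (seq_along(w$samples) - 1) / w$rate

#' Write a waveform to a WAV file
#'
#' Writes mono RIFF/WAVE, either 16-bit PCM (`"pcm16"`) or 32-bit IEEE float
#' (`"float32"`). PCM samples are clipped to \[-1, 1\] and quantized.
#'
#' @param w A `waveform`.
#' @param path Output file path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  stopifnot(inherits(w, "waveform"))
  n <- length(w$samples)
  rate <- as.integer(round(w$rate))
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    bits <- 16L; fmt_code <- 1L; bytes_per <- 2L
  } else {
    bits <- 32L; fmt_code <- 3L; bytes_per <- 4L
  }
  data_bytes <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")      # block align
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    x <- pmin(1, pmax(-1, w$samples))
    q <- as.integer(round(x * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(w$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Reads 16-bit PCM or 32-bit float RIFF/WAVE files written by [write_wav()]
#' (or any conforming mono file). Unsupported encodings and truncated files
#' raise a format error.
#'
#' @param path File path.
#' @param label Label to attach to the returned waveform.
#' @return A `waveform`.
#' @export
read_wav <- function(path, label = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file: ", path)
  fmt_code <- NA_integer_; channels <- NA_integer_; rate <- NA_integer_
  bits <- NA_integer_; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0) stop("read_wav: truncated file: ", path)
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "raw", sz)
      if (length(fmt) < 16) stop("read_wav: truncated fmt chunk: ", path)
      u16 <- function(i) sum(as.integer(fmt[i:(i + 1)]) * c(1L, 256L))
      u32 <- function(i) sum(as.numeric(fmt[i:(i + 3)]) * 256^(0:3))
      fmt_code <- u16(1); channels <- u16(3); rate <- u32(5); bits <- u16(15)
    } else if (identical(id, "data")) {
      if (is.na(fmt_code)) stop("read_wav: data chunk before fmt chunk: ", path)
      if (!fmt_code %in% c(1L, 3L)) {
        stop("read_wav: unsupported encoding (format code ", fmt_code, ")")
      }
      if (fmt_code == 1L && bits != 16L) {
        stop("read_wav: only 16-bit PCM supported, got ", bits, " bits")
      }
      if (fmt_code == 3L && bits != 32L) {
        stop("read_wav: only 32-bit float supported, got ", bits, " bits")
      }
      bytes_per <- bits %/% 8L
      n <- sz %/% bytes_per
      if (fmt_code == 1L) {
        q <- readBin(con, "integer", n, size = 2, signed = TRUE,
                     endian = "little")
        if (length(q) < n) stop("read_wav: truncated data chunk: ", path)
        samples <- q / 32767
      } else {
        samples <- readBin(con, "numeric", n, size = 4, endian = "little")
        if (length(samples) < n) stop("read_wav: truncated data chunk: ", path)
      }
      break
    } else {
      skipped <- readBin(con, "raw", sz + (sz %% 2L))
      if (length(skipped) < sz) stop("read_wav: truncated file: ", path)
    }
  }
  if (is.null(samples)) stop("read_wav: no data chunk found: ", path)
  if (!is.na(channels) && channels != 1L) {
    stop("read_wav: only mono files supported, got ", channels, " channels")
  }
  waveform(samples, rate, label)
}

#' Root-mean-square amplitude over a time interval
#' @param w A `waveform`.
#' @param from,to Interval \[from, to) in seconds; defaults to the whole wave.
#' @return RMS amplitude.
#' @export
wave_rms <- function(w, from = 0, to = wave_duration(w)) {
  t <- wave_times(w)
  sel <- t >= from & t < to
  if (!any(sel)) return(NA_real_)
  sqrt(mean(w$samples[sel]^2))
}
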