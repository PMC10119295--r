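#' Align two traces at their burst peaks
#'
#' Time-shifts both traces so that their burst peaks sit at `t = 0` and trims
#' them to the overlapping support. Burst peak times default to the time of
#' the largest absolute value of each trace.
#'
#' @param a,b data.frames with columns `time` (s) and `value`.
#' @param burst_a,burst_b Optional burst-peak times (s); detected when `NULL`.
#' @return List with shifted/trimmed `a` and `b` and `shift`, the recovered
#'   offset `burst_b - burst_a` in seconds.
#' @export
align_at_burst <- function(a, b, burst_a = NULL, burst_b = NULL) {
  find_burst <- function(tr) tr$time[which.max(abs(tr$value))]
  if (is.null(burst_a)) burst_a <- find_burst(a)
  if (is.null(burst_b)) burst_b <- find_burst(b)
  a2 <- data.frame(time = a$time - burst_a, value = a$value)
  b2 <- data.frame(time = b$time - burst_b, value = b$value)
  lo <- max(min(a2$time), min(b2$time))
  hi <- min(max(a2$time), max(b2$time))
  list(a = a2[a2$time >= lo & a2$time <= hi, , drop = FALSE],
       b = b2[b2$time >= lo & b2$time <= hi, , drop = FALSE],
       shift = burst_b - burst_a)
}

#' Rescale a probe trace and resample it onto a target time grid
#'
#' Subtracts the silence baseline (mean value over `silence_window`),
#' multiplies by `scale_factor` (the convolutional signal is far smaller
#' than a cABR trace in microvolts; typical factors are 33.3 or 50 -- note
#' that Pearson correlation is invariant to this positive scaling, so the
#' factor matters for visual overlay, not for `r`), and linearly
#' interpolates onto the target grid.
#'
#' @param probe data.frame trace (`time`, `value`).
#' @param target_times Numeric vector of output sample times (s), e.g. the
#'   cABR trace's grid; alternatively supply `target_rate`.
#' @param scale_factor Positive multiplier applied after baselining.
#' @param silence_window `c(start, end)` in seconds of a silent stretch used
#'   for the baseline; defaults to the first 5 ms.
#' @param target_rate Used to build a grid over the probe's span when
#'   `target_times` is missing.
#' @return data.frame trace on the target grid.
#' @export
rescale_and_resample <- function(probe, target_times = NULL,
                                 scale_factor = 50,
                                 silence_window = c(0, 0.005),
                                 target_rate = NULL) {
  if (scale_factor <= 0) stop("rescale_and_resample: scale_factor must be > 0")
  if (is.null(target_times)) {
    if (is.null(target_rate)) {
      stop("rescale_and_resample: supply target_times or target_rate")
    }
    target_times <- seq(min(probe$time), max(probe$time), by = 1 / target_rate)
  }
  sel <- probe$time >= silence_window[1] & probe$time < silence_window[2]
  baseline <- if (any(sel)) mean(probe$value[sel]) else 0
  v <- (probe$value - baseline) * scale_factor
  data.frame(time = target_times,
             value = stats::approx(probe$time, v, xout = target_times,
                                   rule = 2)$y)
}

#' Dynamic time warping of two series
#'
#' Classic DTW with unit step costs on the absolute difference and steps
#' (1,0), (0,1), (1,1). Optionally constrained to a Sakoe-Chiba band.
#'
#' @param a,b Numeric vectors.
#' @param band Optional half-width (in indices) of a Sakoe-Chiba band;
#'   `Inf` (default) is unconstrained.
#' @return List with `distance` (cumulative cost), and `path`, a two-column
#'   integer matrix of aligned index pairs, monotone in both columns, from
#'   `(1, 1)` to `(length(a), length(b))`.
#' @export
dtw_align <- function(a, b, band = Inf) {
  n <- length(a)
  m <- length(b)
  if (n == 0 || m == 0) stop("dtw_align: empty series")
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    j_lo <- if (is.finite(band)) max(1L, i - band) else 1L
    j_hi <- if (is.finite(band)) min(m, i + band) else m
    ci <- abs(a[i] - b[j_lo:j_hi])
    for (jj in seq_along(ci)) {
      j <- j_lo + jj - 1L
      D[i + 1L, j + 1L] <- ci[jj] +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  # backtrack
  path <- matrix(0L, n + m, 2L)
  i <- n
  j <- m
  k <- 0L
  while (i >= 1L && j >= 1L) {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    opts <- c(D[i, j], D[i, j + 1L], D[i + 1L, j])  # diag, up, left
    mv <- which.min(opts)
    if (mv == 1L) { i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) i <- i - 1L
    else j <- j - 1L
  }
  list(distance = D[n + 1L, m + 1L], path = path[k:1, , drop = FALSE])
}

#' DTW-based comparison of a probe against a cABR-style trace
#'
#' Performs DTW on two burst-aligned, equal-rate traces and computes
#' Pearson's product-moment correlation within analysis windows. In
#' `"warped"` mode (default) the correlation is computed over the DTW-paired
#' samples whose `a`-time falls in the window; in `"aligned"` mode over the
#' pointwise pairing within the window (no warping).
#'
#' @param a,b data.frame traces (`time`, `value`) on equal-rate grids,
#'   typically from [align_at_burst()] and [rescale_and_resample()].
#' @param windows List of `c(start, end)` windows in seconds (relative to
#'   the traces' common clock, i.e. burst peak at 0 after alignment).
#' @param mode `"warped"` or `"aligned"`.
#' @param band Optional Sakoe-Chiba half-width passed to [dtw_align()].
#' @return Object of class `comparison_result`: list with `r_per_window`
#'   (data.frame `start`, `end`, `r`), `dtw_distance`, `path`, `mode`.
#' @export
dtw_correlate <- function(a, b, windows = list(), mode = c("warped", "aligned"),
                          band = Inf) {
  mode <- match.arg(mode)
  da <- stats::median(diff(a$time))
  db <- stats::median(diff(b$time))
  if (abs(da - db) > 1e-9 * da) {
    stop("dtw_correlate: traces must share a sampling rate; resample first")
  }
  lo <- max(min(a$time), min(b$time))
  hi <- min(max(a$time), max(b$time))
  al <- dtw_align(a$value, b$value, band = band)
  rw <- lapply(windows, function(win) {
    if (win[1] < lo - da / 2 || win[2] > hi + da / 2) {
      stop(sprintf("dtw_correlate: window [%g, %g] outside trace overlap [%g, %g]",
                   win[1], win[2], lo, hi))
    }
    if (mode == "warped") {
      ta <- a$time[al$path[, 1]]
      keep <- ta >= win[1] & ta < win[2]
      r <- stats::cor(a$value[al$path[keep, 1]], b$value[al$path[keep, 2]])
    } else {
      ka <- a$time >= win[1] & a$time < win[2]
      kb <- b$time >= win[1] & b$time < win[2]
      nn <- min(sum(ka), sum(kb))
      r <- stats::cor(a$value[which(ka)[seq_len(nn)]],
                      b$value[which(kb)[seq_len(nn)]])
    }
    data.frame(start = win[1], end = win[2], r = r)
  })
  structure(list(r_per_window = if (length(rw)) do.call(rbind, rw) else
                   data.frame(start = numeric(), end = numeric(),
                              r = numeric()),
                 dtw_distance = al$distance, path = al$path, mode = mode),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> DTW distance %.4g (%s mode)\n",
              x$dtw_distance, x$mode))
  if (nrow(x$r_per_window)) {
    for (i in seq_len(nrow(x$r_per_window))) {
      cat(sprintf("  window [%g, %g] s: r = %.3f\n",
                  x$r_per_window$start[i], x$r_per_window$end[i],
                  x$r_per_window$r[i]))
    }
  }
  invisible(x)
}
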