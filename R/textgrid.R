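#' Read a Praat TextGrid (long format, interval tiers)
#'
#' Minimal parser for long-format TextGrids with IntervalTier tiers; point
#' tiers are skipped. Returns one data.frame of intervals per tier.
#'
#' @param path File path.
#' @return Named list of data.frames with columns `label`, `start`, `end`.
#' @export
read_textgrid <- function(path) {
  if (!file.exists(path)) stop("read_textgrid: missing file: ", path)
  lines <- readLines(path, warn = FALSE)
  num_after <- function(line) {
    as.numeric(sub(".*=\\s*", "", line))
  }
  str_after <- function(line) {
    m <- regmatches(line, regexpr('"[^"]*"', line))
    if (length(m) == 0) "" else gsub('"', "", m)
  }
  tiers <- list()
  i <- 1L
  cur_name <- NULL
  cur <- NULL
  is_interval <- FALSE
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("class\\s*=", ln)) {
      if (!is.null(cur_name) && is_interval) tiers[[cur_name]] <- cur
      is_interval <- grepl("IntervalTier", ln)
      cur <- data.frame(label = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE)
      cur_name <- NULL
    } else if (grepl("name\\s*=", ln) && is.null(cur_name)) {
      cur_name <- str_after(ln)
    } else if (is_interval && grepl("intervals\\s*\\[", ln)) {
      xmin <- num_after(lines[i + 1])
      xmax <- num_after(lines[i + 2])
      text <- str_after(lines[i + 3])
      cur <- rbind(cur, data.frame(label = text, start = xmin, end = xmax,
                                   stringsAsFactors = FALSE))
      i <- i + 3L
    }
    i <- i + 1L
  }
  if (!is.null(cur_name) && is_interval) tiers[[cur_name]] <- cur
  tiers
}

#' Write a Praat TextGrid (long format)
#'
#' @param tiers Named list of data.frames with columns `label`, `start`,
#'   `end`; each becomes one IntervalTier.
#' @param path Output file path.
#' @param xmin,xmax Global time range; defaults span all intervals.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(tiers, path, xmin = NULL, xmax = NULL) {
  all_start <- unlist(lapply(tiers, function(t) t$start))
  all_end <- unlist(lapply(tiers, function(t) t$end))
  if (is.null(xmin)) xmin <- if (length(all_start)) min(all_start) else 0
  if (is.null(xmax)) xmax <- if (length(all_end)) max(all_end) else 1
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('File type = "ooTextFile"')
  w('Object class = "TextGrid"')
  w("")
  w("xmin = %.17g", xmin)
  w("xmax = %.17g", xmax)
  w("tiers? <exists>")
  w("size = %d", length(tiers))
  w("item []:")
  for (k in seq_along(tiers)) {
    tier <- tiers[[k]]
    w("    item [%d]:", k)
    w('        class = "IntervalTier"')
    w('        name = "%s"', names(tiers)[k])
    w("        xmin = %.17g", xmin)
    w("        xmax = %.17g", xmax)
    w("        intervals: size = %d", nrow(tier))
    for (j in seq_len(nrow(tier))) {
      w("        intervals [%d]:", j)
      w("            xmin = %.17g", tier$start[j])
      w("            xmax = %.17g", tier$end[j])
      w('            text = "%s"', tier$label[j])
    }
  }
  invisible(path)
}
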