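#' Exclude high periods from a latency dataset
#'
#' Removes records with period `n >= 12`, which are too rarely attested for
#' stable estimation; the removal count is reported.
#'
#' @param rows data.frame of peak records (see [latency_table()]).
#' @param max_period Highest retained period index.
#' @return Filtered data.frame with attribute `"n_removed"`.
#' @export
exclusion_filter <- function(rows, max_period = 11L) {
  keep <- rows$n <= max_period
  removed <- sum(!keep)
  if (removed > 0) {
    message("exclusion_filter: removed ", removed, " record(s) with n > ",
            max_period)
  }
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- removed
  out
}

#' Fit the peak-latency model and compute per-period language contrasts
#'
#' Ordinary least squares on `delta_t` with three predictors -- language
#' (treatment-coded, English reference), period (treatment-coded, period 1
#' reference) and replication (sum-coded) -- and all two- and three-way
#' interactions. Pairwise English-minus-Spanish contrasts at each period,
#' marginalized over replications, are obtained with emmeans; two-sided t
#' tests use the OLS residual degrees of freedom, and Benjamini-Hochberg
#' FDR-adjusted p values are reported alongside the raw ones.
#'
#' Records with `n >= 12` are excluded before fitting (see
#' [exclusion_filter()]).
#'
#' @param rows data.frame of peak records with columns `language`
#'   (two levels; `"english"`/`"spanish"`), `replication`, `n`, `delta_t`.
#' @return data.frame (class `contrast_table`) with one row per period:
#'   `contrast`, `period`, `estimate` (s), `se`, `df`, `t_ratio`, `p_value`,
#'   `p_fdr`.
#' @export
fit_and_contrast <- function(rows) {
  rows <- suppressMessages(exclusion_filter(rows))
  if ("excluded" %in% names(rows)) rows <- rows[!rows$excluded, , drop = FALSE]
  langs <- sort(unique(as.character(rows$language)))
  if (length(langs) != 2) {
    stop("fit_and_contrast: need exactly two language levels, got ",
         length(langs))
  }
  if ("english" %in% langs) langs <- c("english", setdiff(langs, "english"))
  d <- data.frame(
    delta_t = rows$delta_t,
    language = factor(rows$language, levels = langs),
    period = factor(rows$n, levels = sort(unique(rows$n))),
    replication = factor(rows$replication)
  )
  if ("1" %in% levels(d$period)) d$period <- stats::relevel(d$period, "1")
  cells <- table(d$language, d$period)
  empty <- which(cells == 0, arr.ind = TRUE)
  if (nrow(empty) > 0) {
    stop("fit_and_contrast: empty (language, period) cell(s): ",
         paste(sprintf("(%s, %s)", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "))
  }
  one_rep <- nlevels(d$replication) < 2
  form <- if (one_rep) delta_t ~ language * period else
    delta_t ~ language * period * replication
  ctr <- if (one_rep) NULL else list(replication = stats::contr.sum)
  fit <- stats::lm(form, data = d, contrasts = ctr)
  # marginalizing over replication despite interactions is deliberate (the
  # pooled-contrast analysis); silence the advisory note
  emm <- suppressMessages(emmeans::emmeans(fit, ~ language | period))
  prs <- summary(emmeans::contrast(emm, method = "pairwise"), adjust = "none")
  out <- data.frame(
    contrast = paste(langs[1], "-", langs[2]),
    period = as.integer(as.character(prs$period)),
    estimate = prs$estimate,
    se = prs$SE,
    df = prs$df,
    t_ratio = prs$t.ratio,
    p_value = prs$p.value
  )
  out <- out[order(out$period), , drop = FALSE]
  out$p_fdr <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("contrast_table", "data.frame")
  attr(out, "fit") <- fit
  out
}
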