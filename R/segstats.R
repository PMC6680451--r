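#' Segment-length statistics for one keypress record
#'
#' A press marks a phrase *ending*, so the stretch from stimulus onset to
#' the first press is a segment and the stretch after the final press is
#' not. Segment boundaries are therefore `{0} + press times`; lengths are
#' the successive differences and the segment count equals the number of
#' presses. `mode = "intervals"` switches to inter-press intervals only
#' (n - 1 lengths for n presses), for sensitivity analyses.
#'
#' @param press_times Sorted press times in ms (normally baseline-corrected;
#'   see [correct_keypresses()]).
#' @param total_duration Optional stimulus duration (ms); unused by the
#'   default convention but kept for the record.
#' @param mode `"anchored"` (default, `{0}`-anchored) or `"intervals"`.
#' @return list with `n_segments`, `mean_len_ms`, `sd_len_ms` and
#'   `defined` (FALSE when there are no lengths to average; the mean/sd are
#'   `NA` then, and `sd` is additionally `NA` for a single length).
#' @export
segment_lengths <- function(press_times, total_duration = NULL,
                            mode = c("anchored", "intervals")) {
  mode <- match.arg(mode)
  if (length(press_times) > 1 && is.unsorted(press_times)) {
    stop("press times must be sorted", call. = FALSE)
  }
  lens <- if (mode == "anchored") diff(c(0, press_times)) else diff(press_times)
  n_seg <- length(press_times)
  list(n_segments = n_seg,
       mean_len_ms = if (length(lens)) mean(lens) else NA_real_,
       sd_len_ms = if (length(lens) > 1) stats::sd(lens) else NA_real_,
       defined = length(lens) > 0)
}

#' Segment statistics for a keypress log
#'
#' Applies [correct_keypresses()] and [segment_lengths()] and returns a
#' one-row data.frame keyed by participant, stimulus and version.
#'
#' @param log A [key_press_log()].
#' @param mode See [segment_lengths()].
#' @return One-row data.frame: `participant_id`, `instruction`,
#'   `stimulus_id`, `version`, `n_segments`, `mean_len_ms`, `sd_len_ms`.
#' @export
segment_stats <- function(log, mode = "anchored") {
  sl <- segment_lengths(correct_keypresses(log), mode = mode)
  data.frame(participant_id = log$participant_id, instruction = log$instruction,
             stimulus_id = log$stimulus_id, version = log$version,
             n_segments = sl$n_segments, mean_len_ms = sl$mean_len_ms,
             sd_len_ms = sl$sd_len_ms)
}

#' Aggregate segment statistics over conditions
#'
#' Per-condition (unweighted by default) means of the segment metrics, long
#' format: one row per condition x metric.
#'
#' @param stats data.frame of per-record segment statistics (as produced by
#'   [segment_stats()] row-bound over logs).
#' @param grouping Character vector of grouping column names present in
#'   `stats` (e.g. `c("version", "instruction")`).
#' @param metrics Metric columns to average.
#' @param weights Optional column name of case weights (weighted means
#'   otherwise differ from unweighted ones on unbalanced data).
#' @return data.frame with the grouping columns plus `metric` and `mean`.
#' @export
aggregate_segments <- function(stats,
                               grouping = c("version", "instruction"),
                               metrics = c("n_segments", "mean_len_ms", "sd_len_ms"),
                               weights = NULL) {
  if (!nrow(stats)) stop("no rows to aggregate", call. = FALSE)
  bad <- setdiff(c(grouping, metrics, weights), names(stats))
  if (length(bad)) stop("unknown grouping/metric column(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  g <- interaction(stats[grouping], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    rows <- stats[g == lv, , drop = FALSE]
    w <- if (is.null(weights)) rep(1, nrow(rows)) else rows[[weights]]
    vals <- vapply(metrics, function(m) {
      ok <- !is.na(rows[[m]])
      if (!any(ok)) return(NA_real_)
      sum(w[ok] * rows[[m]][ok]) / sum(w[ok])
    }, 0)
    cbind(rows[1, grouping, drop = FALSE],
          data.frame(metric = metrics, mean = unname(vals), row.names = NULL))
  }))
  rownames(out) <- NULL
  out
}
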