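#' The seven boundary-cue model labels
#'
#' Local cues: `pause`, `pitch_break`, `pause_pitch_break`. Global cues:
#' `pitch_rise`, `pitch_drop`. Mixed cues: `pause_pitch_rise`,
#' `pause_pitch_drop`.
#' @export
CUE_MODELS <- c("pause", "pitch_break", "pause_pitch_break",
                "pitch_rise", "pitch_drop",
                "pause_pitch_rise", "pause_pitch_drop")

#' Detection thresholds for the cue models
#'
#' All defaults are the rule constants of the segmentation models:
#' \itemize{
#'   \item `pause_min_ms` (200): a silence must be strictly longer than this
#'     to count as a pause.
#'   \item `break_gap_max_ms` (200): a pitch break requires its separating
#'     silence to be shorter than this (and longer than 0: two abutting
#'     events are a step, not a break across silence).
#'   \item `break_delta_sd` (1): pitch contrast of a break must exceed this
#'     many stimulus pitch SDs.
#'   \item `movement_range_fraction` (1/3): a pitch movement is "wide" when
#'     its span reaches this fraction of the global pitch range.
#'   \item `rise_min_ms` (500) / `drop_min_ms` (1000): a movement is
#'     "long-lasting" at or beyond these durations.
#'   \item `drop_low_end_sd` (0.5): a drop must additionally end at least
#'     this many SDs below the global mean pitch.
#'   \item `deflection_max_ms_rise` (250) / `deflection_max_ms_drop` (200):
#'     counter-directional deflections inside a movement are tolerated up to
#'     these elapsed durations.
#'   \item `within_movement_pause_max_ms` (200): silences up to this length
#'     are tolerated inside a movement.
#'   \item `min_movement_events` (2): minimum number of events in a
#'     movement run.
#' }
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A `cue_thresholds` list.
#' @export
cue_thresholds <- function(...) {
  th <- list(
    pause_min_ms = 200, break_gap_max_ms = 200, break_delta_sd = 1,
    movement_range_fraction = 1 / 3, rise_min_ms = 500, drop_min_ms = 1000,
    drop_low_end_sd = 0.5, deflection_max_ms_rise = 250,
    deflection_max_ms_drop = 200, within_movement_pause_max_ms = 200,
    min_movement_events = 2)
  dots <- list(...)
  bad <- setdiff(names(dots), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  th[names(dots)] <- dots
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive", call. = FALSE)
  structure(th, class = "cue_thresholds")
}

#' Detect pauses
#'
#' A pause is an inter-event silence strictly longer than
#' `thresholds$pause_min_ms`. The segmentation point associated with a pause
#' is its onset (the offset of the preceding event).
#'
#' @param stream A [pitch_stream()].
#' @param thresholds A [cue_thresholds()].
#' @return data.frame with columns `onset`, `offset` (one row per pause;
#'   possibly empty).
#' @export
detect_pauses <- function(stream, thresholds = cue_thresholds()) {
  ev <- stream$events
  n <- nrow(ev)
  if (n < 2) return(data.frame(onset = numeric(0), offset = numeric(0)))
  off <- ev$onset + ev$duration
  gap_on <- off[-n]
  gap_off <- ev$onset[-1]
  keep <- (gap_off - gap_on) > thresholds$pause_min_ms
  data.frame(onset = gap_on[keep], offset = gap_off[keep])
}

#' Detect pitch breaks
#'
#' Two consecutive events whose pitches differ by more than
#' `break_delta_sd` stimulus pitch SDs, separated by a silence shorter than
#' `break_gap_max_ms`, form a pitch break; the segmentation point is the
#' onset of the second event. If the same pitch contrast occurs across a
#' silence long enough to be a pause (`> pause_min_ms`), the candidate is a
#' pause-plus-pitch-break instead, with its point at the pause onset.
#' Contrasts across a silence of exactly the threshold length, or across no
#' silence at all (abutting events), yield neither.
#'
#' @param stream A [pitch_stream()].
#' @param stats [stimulus_stats()] computed on the same stream.
#' @param thresholds A [cue_thresholds()].
#' @return data.frame with columns `time`, `model` (`"pitch_break"` or
#'   `"pause_pitch_break"`), `extent_start`, `extent_end`.
#' @export
detect_pitch_breaks <- function(stream, stats = stimulus_stats(stream),
                                thresholds = cue_thresholds()) {
  ev <- stream$events
  n <- nrow(ev)
  empty <- data.frame(time = numeric(0), model = character(0),
                      extent_start = numeric(0), extent_end = numeric(0))
  if (n < 2) return(empty)
  off <- ev$onset + ev$duration
  gap <- ev$onset[-1] - off[-n]
  dp <- abs(diff(ev$pitch))
  contrast <- dp > thresholds$break_delta_sd * stats$sd_pitch_hz
  as_break <- contrast & gap > 0 & gap < thresholds$break_gap_max_ms
  as_pause_break <- contrast & gap > thresholds$pause_min_ms
  rbind(
    data.frame(time = ev$onset[-1][as_break],
               model = rep("pitch_break", sum(as_break)),
               extent_start = off[-n][as_break],
               extent_end = ev$onset[-1][as_break]),
    data.frame(time = off[-n][as_pause_break],
               model = rep("pause_pitch_break", sum(as_pause_break)),
               extent_start = off[-n][as_pause_break],
               extent_end = ev$onset[-1][as_pause_break]))
}

#' Detect pitch movements (rises or drops)
#'
#' Finds maximal runs of events that move monotonically in `direction`,
#' tolerating counter-directional (or flat) deflections whose elapsed time
#' does not exceed the direction-specific allowance (250 ms for rises,
#' 200 ms for drops) and internal silences up to
#' `within_movement_pause_max_ms`. A run qualifies as a movement when its
#' pitch span reaches `movement_range_fraction` of the global pitch range
#' *or* its duration reaches `rise_min_ms` / `drop_min_ms`. Drops must in
#' addition end at least `drop_low_end_sd` SDs below the global mean pitch,
#' whichever disjunct qualified them. The segmentation point is the offset
#' of the last in-direction event of the run.
#'
#' @param stream A [pitch_stream()].
#' @param stats [stimulus_stats()] computed on the same stream.
#' @param thresholds A [cue_thresholds()].
#' @param direction `"rise"` or `"drop"`.
#' @return data.frame with columns `time`, `extent_start`, `extent_end`,
#'   `span_hz`, `duration_ms`, `n_events`.
#' @export
detect_pitch_movements <- function(stream, stats = stimulus_stats(stream),
                                   thresholds = cue_thresholds(),
                                   direction = c("rise", "drop")) {
  direction <- match.arg(direction)
  ev <- stream$events
  n <- nrow(ev)
  d <- if (direction == "rise") 1 else -1
  defl_max <- if (direction == "rise") thresholds$deflection_max_ms_rise
              else thresholds$deflection_max_ms_drop
  min_dur <- if (direction == "rise") thresholds$rise_min_ms
             else thresholds$drop_min_ms
  off <- ev$onset + ev$duration
  runs <- list()
  close_run <- function(s, e) {
    if (is.na(e) || e <= s) return()
    if (e - s + 1 < thresholds$min_movement_events) return()
    span <- (ev$pitch[e] - ev$pitch[s]) * d
    dur <- off[e] - ev$onset[s]
    qualifies <- span >= thresholds$movement_range_fraction * stats$pitch_range_hz ||
      dur >= min_dur
    if (qualifies && direction == "drop") {
      qualifies <- ev$pitch[e] <=
        stats$mean_pitch_hz - thresholds$drop_low_end_sd * stats$sd_pitch_hz
    }
    if (qualifies) {
      runs[[length(runs) + 1L]] <<- data.frame(
        time = off[e], extent_start = ev$onset[s], extent_end = off[e],
        span_hz = span, duration_ms = dur, n_events = e - s + 1L)
    }
  }
  if (n >= 2) {
    s <- 1L; last_in_dir <- NA_integer_; defl_start <- NA_real_
    for (k in seq_len(n - 1L)) {
      gap <- ev$onset[k + 1L] - off[k]
      if (gap > thresholds$within_movement_pause_max_ms) {
        close_run(s, last_in_dir)
        s <- k + 1L; last_in_dir <- NA_integer_; defl_start <- NA_real_
        next
      }
      step <- (ev$pitch[k + 1L] - ev$pitch[k]) * d
      # sub-microhertz differences are numerical noise, not pitch movement
      if (step > 1e-6) {
        last_in_dir <- k + 1L
        defl_start <- NA_real_
      } else {
        if (is.na(last_in_dir)) {
          # no in-direction step yet: slide the start to the extremum
          s <- k + 1L
        } else {
          if (is.na(defl_start)) defl_start <- ev$onset[k + 1L]
          if (off[k + 1L] - defl_start > defl_max) {
            close_run(s, last_in_dir)
            s <- k + 1L; last_in_dir <- NA_integer_; defl_start <- NA_real_
          }
        }
      }
    }
    close_run(s, last_in_dir)
  }
  if (!length(runs)) {
    return(data.frame(time = numeric(0), extent_start = numeric(0),
                      extent_end = numeric(0), span_hz = numeric(0),
                      duration_ms = numeric(0), n_events = integer(0)))
  }
  do.call(rbind, runs)
}

#' Assemble the seven-model cue set for one stimulus version
#'
#' Runs all detectors, resolves coexisting cues into the seven mutually
#' exclusive models, and merges all model points into one sorted global
#' array of time values.
#'
#' Coexistence: a movement whose run offset is exactly a pause onset becomes
#' a pause-plus-movement with its point at the pause onset; a pitch contrast
#' across a pause becomes a pause-plus-break at the pause onset. When
#' several candidate labels fall on the same time the richest evidence wins:
#' pause+movement > pause+break > movement > break > pause (drops outrank
#' rises on the rare exact tie).
#'
#' @param stream A [pitch_stream()].
#' @param thresholds A [cue_thresholds()].
#' @param stats Optional precomputed [stimulus_stats()].
#' @return A `cue_model_set`: list with `stimulus_id`, `version`, `points`
#'   (data.frame `time`, `model`, `extent_start`, `extent_end`),
#'   `points_by_model` (named list of time vectors, one per model) and
#'   `global_array` (sorted unique times of all points).
#' @export
assemble_model_set <- function(stream, thresholds = cue_thresholds(),
                               stats = NULL) {
  if (is.null(stats)) stats <- stimulus_stats(stream)
  pauses <- detect_pauses(stream, thresholds)
  breaks <- detect_pitch_breaks(stream, stats, thresholds)
  cand <- list()
  if (nrow(pauses)) {
    cand$pause <- data.frame(time = pauses$onset, model = "pause",
                             extent_start = pauses$onset,
                             extent_end = pauses$offset, prio = 1)
  }
  if (nrow(breaks)) {
    cand$breaks <- data.frame(
      time = breaks$time, model = breaks$model,
      extent_start = breaks$extent_start, extent_end = breaks$extent_end,
      prio = ifelse(breaks$model == "pause_pitch_break", 4, 2))
  }
  for (direction in c("rise", "drop")) {
    mv <- detect_pitch_movements(stream, stats, thresholds, direction)
    if (!nrow(mv)) next
    at_pause <- mv$time %in% pauses$onset
    model <- ifelse(at_pause, paste0("pause_pitch_", direction),
                    paste0("pitch_", direction))
    # drops outrank rises on exact ties (more restrictive criteria)
    bump <- if (direction == "drop") 0.5 else 0
    cand[[direction]] <- data.frame(
      time = mv$time, model = model,
      extent_start = mv$extent_start, extent_end = mv$extent_end,
      prio = ifelse(at_pause, 5, 3) + bump)
  }
  pts <- if (length(cand)) do.call(rbind, cand) else
    data.frame(time = numeric(0), model = character(0),
               extent_start = numeric(0), extent_end = numeric(0),
               prio = numeric(0))
  if (nrow(pts)) {
    pts <- pts[order(pts$time, -pts$prio), , drop = FALSE]
    pts <- pts[!duplicated(pts$time), , drop = FALSE]   # keep highest priority
    rownames(pts) <- NULL
  }
  pts$prio <- NULL
  points_by_model <- lapply(stats::setNames(CUE_MODELS, CUE_MODELS),
                            function(m) pts$time[pts$model == m])
  structure(
    list(stimulus_id = stream$stimulus_id, version = stream$version,
         points = pts, points_by_model = points_by_model,
         global_array = sort(unique(pts$time))),
    class = "cue_model_set")
}

#' @export
print.cue_model_set <- function(x, ...) {
  counts <- vapply(x$points_by_model, length, 0L)
  cat(sprintf("<cue_model_set> %s (%s): %d global points\n",
              x$stimulus_id, x$version, length(x$global_array)))
  print(counts)
  invisible(x)
}

#' Global-array diagnostics
#'
#' @param model_set A `cue_model_set` from [assemble_model_set()].
#' @return list with `n_points` and `max_adjacent_gap_ms` (0 for a single
#'   point). The maximum adjacent gap bounds the error made when snapping a
#'   participant press to its nearest global point.
#' @export
global_array_diagnostics <- function(model_set) {
  ga <- model_set$global_array
  if (!length(ga)) stop("empty global array", call. = FALSE)
  list(n_points = length(ga),
       max_adjacent_gap_ms = if (length(ga) > 1) max(diff(ga)) else 0)
}
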