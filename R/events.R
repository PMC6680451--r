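#' Pitch-event stream
#'
#' A `pitch_stream` is the substrate of all cue detection: a time-ordered
#' sequence of stable-pitch, syllable-like events, each with an onset, a
#' duration and a fundamental frequency. Event intervals are half-open
#' `[onset, onset + duration)` in milliseconds; any time not covered by an
#' event is silence. Natural speech and delexicalized (audio-to-MIDI style)
#' versions of a stimulus share this representation; they differ only in how
#' the event pitches were obtained.
#'
#' @param onset Numeric vector of event onsets in ms (0-based, sorted).
#' @param duration Numeric vector of event durations in ms, all `> 0`.
#' @param pitch Numeric vector of event fundamental frequencies in Hz, `> 0`.
#' @param stimulus_id Stimulus label.
#' @param version `"natural"` or `"delexicalized"`.
#' @param total_duration Total stimulus duration in ms. Defaults to the
#'   offset of the last event. Must be at least that offset.
#'
#' @return An object of class `pitch_stream`: a list with `events` (a
#'   data.frame with columns `onset`, `duration`, `pitch`), `stimulus_id`,
#'   `version` and `total_duration`.
#' @examples
#' s <- pitch_stream(c(0, 800), c(500, 400), c(110, 165))
#' n_events(s)
#' @export
pitch_stream <- function(onset, duration, pitch,
                         stimulus_id = "stim",
                         version = c("natural", "delexicalized"),
                         total_duration = NULL) {
  version <- match.arg(version)
  n <- length(onset)
  if (length(duration) != n || length(pitch) != n) {
    stop("onset, duration and pitch must have equal length", call. = FALSE)
  }
  if (n > 0) {
    if (any(!is.finite(onset)) || any(!is.finite(duration)) || any(!is.finite(pitch))) {
      stop("events must be finite", call. = FALSE)
    }
    if (any(duration <= 0)) stop("event durations must be > 0", call. = FALSE)
    if (any(pitch <= 0)) stop("event pitches must be > 0 Hz", call. = FALSE)
    if (any(onset < 0)) stop("event onsets must be >= 0", call. = FALSE)
    o <- order(onset)
    onset <- onset[o]; duration <- duration[o]; pitch <- pitch[o]
    off <- onset + duration
    if (n > 1 && any(onset[-1] < off[-n] - 1e-9)) {
      bad <- which(onset[-1] < off[-n] - 1e-9)[1]
      stop(sprintf("events overlap: event %d ends at %.3f ms but event %d starts at %.3f ms",
                   bad, off[bad], bad + 1, onset[bad + 1]), call. = FALSE)
    }
  }
  last_off <- if (n > 0) onset[n] + duration[n] else 0
  if (is.null(total_duration)) total_duration <- last_off
  if (total_duration < last_off - 1e-9) {
    stop("total_duration is smaller than the offset of the last event", call. = FALSE)
  }
  structure(
    list(events = data.frame(onset = onset, duration = duration, pitch = pitch),
         stimulus_id = stimulus_id, version = version,
         total_duration = as.numeric(total_duration)),
    class = "pitch_stream")
}

#' @export
print.pitch_stream <- function(x, ...) {
  cat(sprintf("<pitch_stream> %s (%s): %d events, %.1f s total\n",
              x$stimulus_id, x$version, nrow(x$events), x$total_duration / 1000))
  invisible(x)
}

#' Number of events in a pitch stream
#' @param stream A `pitch_stream`.
#' @return Integer event count.
#' @export
n_events <- function(stream) nrow(stream$events)

event_offsets <- function(stream) stream$events$onset + stream$events$duration

#' Keypress log for one participant and stimulus
#'
#' Raw space-bar press times for one participant listening to one version of
#' one stimulus, together with the participant's baseline auditory reaction
#' time (used later to correct press times back to perceived boundary times).
#'
#' @param participant_id Participant label.
#' @param instruction `"speech"` or `"music"`.
#' @param stimulus_id Stimulus label.
#' @param version `"natural"` or `"delexicalized"`.
#' @param press_times Numeric vector of raw press times in ms, strictly
#'   increasing.
#' @param baseline_rt Baseline reaction time in ms, `> 0`.
#' @param total_duration Optional stimulus duration in ms; when given,
#'   presses must fall within `[0, total_duration + grace]`.
#' @param grace Grace window after stimulus end in ms (default 1000) within
#'   which late presses are still accepted.
#' @return An object of class `key_press_log`.
#' @export
key_press_log <- function(participant_id, instruction = c("speech", "music"),
                          stimulus_id, version = c("natural", "delexicalized"),
                          press_times, baseline_rt,
                          total_duration = NULL, grace = 1000) {
  instruction <- match.arg(instruction)
  version <- match.arg(version)
  press_times <- as.numeric(press_times)
  if (length(baseline_rt) != 1 || !is.finite(baseline_rt) || baseline_rt <= 0) {
    stop("baseline_rt must be a single positive number (ms)", call. = FALSE)
  }
  if (length(press_times) > 1 && any(diff(press_times) <= 0)) {
    stop("press_times must be strictly increasing", call. = FALSE)
  }
  if (any(press_times < 0)) stop("press_times must be >= 0", call. = FALSE)
  if (!is.null(total_duration) && length(press_times) &&
      any(press_times > total_duration + grace)) {
    stop("press beyond stimulus end + grace window", call. = FALSE)
  }
  structure(
    list(participant_id = participant_id, instruction = instruction,
         stimulus_id = stimulus_id, version = version,
         press_times = press_times, baseline_rt = as.numeric(baseline_rt)),
    class = "key_press_log")
}

#' @export
print.key_press_log <- function(x, ...) {
  cat(sprintf("<key_press_log> %s / %s (%s, %s): %d presses, baseline RT %.0f ms\n",
              x$participant_id, x$stimulus_id, x$version, x$instruction,
              length(x$press_times), x$baseline_rt))
  invisible(x)
}

#' Hertz to Mel conversion
#'
#' Uses the common `2595 * log10(1 + f/700)` variant of the Mel scale, a
#' perceptual pitch scale that compresses high frequencies. Several Mel
#' formulas circulate; this one is fixed here and stated explicitly so that
#' Mel-scale statistics are reproducible.
#'
#' @param f_hz Frequency in Hz, `>= 0` (vectorised).
#' @return Mel value(s).
#' @examples
#' hz_to_mel(700) # 2595 * log10(2)
#' @export
hz_to_mel <- function(f_hz) {
  if (any(f_hz < 0, na.rm = TRUE)) stop("frequencies must be >= 0", call. = FALSE)
  2595 * log10(1 + f_hz / 700)
}

#' Stimulus-level acoustic statistics
#'
#' Summarises a pitch stream the way a stimulus table would: mean and SD of
#' pitch (Hz and Mel), pitch range, pitch-change rate (events per second of
#' total duration), silence proportion and duration. Pitch mean/SD are
#' duration-weighted by default (a long syllable contributes more to the
#' pitch distribution than a short one); set `weighted = FALSE` for plain
#' per-event statistics. Mel statistics are computed on the Mel-transformed
#' event pitches (not by transforming the Hz summary), with the same
#' weighting.
#'
#' SDs use the weighted population-style estimator
#' `sqrt(sum(w*(x-m)^2)/sum(w))` with `w` the event durations; for
#' `weighted = FALSE` the ordinary sample SD is used.
#'
#' @param stream A `pitch_stream` with at least 2 events.
#' @param weighted Duration-weight the pitch mean/SD? Default `TRUE`.
#' @return A `stimulus_stats` object (list) with fields `mean_pitch_hz`,
#'   `sd_pitch_hz`, `mean_pitch_mel`, `sd_pitch_mel`, `pitch_range_hz`,
#'   `pitch_change_rate`, `silence_proportion`, `duration_s`.
#' @export
stimulus_stats <- function(stream, weighted = TRUE) {
  ev <- stream$events
  if (nrow(ev) < 2) stop("need at least 2 events to compute stimulus statistics", call. = FALSE)
  if (weighted) {
    w <- ev$duration
    m_hz <- sum(w * ev$pitch) / sum(w)
    sd_hz <- sqrt(sum(w * (ev$pitch - m_hz)^2) / sum(w))
    mel <- hz_to_mel(ev$pitch)
    m_mel <- sum(w * mel) / sum(w)
    sd_mel <- sqrt(sum(w * (mel - m_mel)^2) / sum(w))
  } else {
    m_hz <- mean(ev$pitch); sd_hz <- stats::sd(ev$pitch)
    mel <- hz_to_mel(ev$pitch)
    m_mel <- mean(mel); sd_mel <- stats::sd(mel)
  }
  dur_s <- stream$total_duration / 1000
  structure(
    list(mean_pitch_hz = m_hz, sd_pitch_hz = sd_hz,
         mean_pitch_mel = m_mel, sd_pitch_mel = sd_mel,
         pitch_range_hz = max(ev$pitch) - min(ev$pitch),
         pitch_change_rate = nrow(ev) / dur_s,
         silence_proportion = 1 - sum(ev$duration) / stream$total_duration,
         duration_s = dur_s,
         weighted = weighted),
    class = "stimulus_stats")
}

#' @export
print.stimulus_stats <- function(x, ...) {
  cat(sprintf(
    "<stimulus_stats> pitch %.1f +/- %.1f Hz (%.0f +/- %.0f Mel)%s\n  range %.1f Hz, %.2f events/s, silence %.1f%%, %.1f s\n",
    x$mean_pitch_hz, x$sd_pitch_hz, x$mean_pitch_mel, x$sd_pitch_mel,
    if (x$weighted) ", duration-weighted" else "",
    x$pitch_range_hz, x$pitch_change_rate, 100 * x$silence_proportion, x$duration_s))
  invisible(x)
}
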