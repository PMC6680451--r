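#' Read a pitch-event stream from file
#'
#' Supported formats:
#' \describe{
#'   \item{`csv`}{Header `onset_ms,duration_ms,pitch_hz`, comma-separated,
#'     UTF-8. One event per row.}
#'   \item{`textgrid`}{Praat long-format TextGrid; the first IntervalTier is
#'     used, non-empty interval labels are parsed as pitch in Hz, empty
#'     labels are silences.}
#'   \item{`pitchtier`}{Praat PitchTier (long text format). Points become
#'     events; each event extends from its point time to the next point
#'     time (the last event gets the median spacing). PitchTier carries no
#'     silence information, so streams read from it have silence only at
#'     the edges.}
#'   \item{`midi`}{Standard MIDI File, type 0 or 1, monophonic. Note numbers
#'     are converted to Hz as `440 * 2^((n - 69)/12)`; the tempo map is
#'     honoured; velocities are ignored. Overlapping notes are rejected.}
#' }
#'
#' @param path Path to the file.
#' @param format One of `"csv"`, `"textgrid"`, `"pitchtier"`, `"midi"`.
#'   Default guesses from the file extension.
#' @param stimulus_id,version,total_duration Passed to [pitch_stream()].
#' @return A [pitch_stream()].
#' @export
read_events <- function(path, format = NULL, stimulus_id = NULL,
                        version = "natural", total_duration = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", textgrid = "textgrid", pitchtier = "pitchtier",
      mid = "midi", midi = "midi",
      stop("cannot guess event format from extension '", ext, "'", call. = FALSE))
  }
  format <- match.arg(format, c("csv", "textgrid", "pitchtier", "midi"))
  if (is.null(stimulus_id)) {
    stimulus_id <- tools::file_path_sans_ext(basename(path))
  }
  ev <- switch(format,
    csv = read_events_csv(path),
    textgrid = read_events_textgrid(path),
    pitchtier = read_events_pitchtier(path),
    midi = read_events_midi(path))
  pitch_stream(ev$onset, ev$duration, ev$pitch,
               stimulus_id = stimulus_id, version = version,
               total_duration = if (is.null(total_duration)) attr(ev, "total_duration") else total_duration)
}

read_events_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, fileEncoding = "UTF-8"),
                 error = function(e) stop("malformed CSV '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  need <- c("onset_ms", "duration_ms", "pitch_hz")
  if (!all(need %in% names(df))) {
    stop("event CSV must have columns onset_ms,duration_ms,pitch_hz", call. = FALSE)
  }
  for (cl in need) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))))[1]
      stop(sprintf("malformed value in column %s, line %d of %s",
                   cl, bad + 1L, path), call. = FALSE)
    }
  }
  data.frame(onset = df$onset_ms, duration = df$duration_ms, pitch = df$pitch_hz)
}

#' Write a pitch stream to an event CSV
#' @param stream A [pitch_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(stream, path) {
  df <- data.frame(onset_ms = stream$events$onset,
                   duration_ms = stream$events$duration,
                   pitch_hz = stream$events$pitch)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Praat long-format parsers.  These files are line-oriented 'key = value'
# listings; we scan for the fields we need rather than building a full
# object model.
praat_num <- function(lines, key, from = 1L) {
  pat <- paste0("^\\s*", key, "\\s*=\\s*([-0-9.eE+]+)")
  hit <- grep(pat, lines[from:length(lines)])
  if (!length(hit)) return(numeric(0))
  as.numeric(sub(pat, "\\1", lines[from - 1L + hit]))
}

read_events_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!any(grepl("ooTextFile", lines[seq_len(min(3, length(lines)))]))) {
    stop("not a Praat text file (missing ooTextFile header): ", path, call. = FALSE)
  }
  tier_at <- grep("class\\s*=\\s*\"IntervalTier\"", lines)
  if (!length(tier_at)) stop("no IntervalTier in TextGrid: ", path, call. = FALSE)
  from <- tier_at[1]
  # tier extent then intervals [n]: xmin, xmax, text
  to <- length(lines)
  tier2 <- grep("class\\s*=\\s*\"", lines)
  tier2 <- tier2[tier2 > from]
  if (length(tier2)) to <- tier2[1] - 1L
  block <- lines[from:to]
  xmin <- praat_num(block, "xmin")
  xmax <- praat_num(block, "xmax")
  texts <- regmatches(block, regexec("text\\s*=\\s*\"([^\"]*)\"", block))
  texts <- vapply(texts, function(m) if (length(m) == 2) m[2] else NA_character_, "")
  keep <- !is.na(texts)
  # first xmin/xmax pair is the tier extent
  total <- xmax[1] * 1000
  xmin <- xmin[-1]; xmax <- xmax[-1]
  texts <- texts[keep]
  if (length(xmin) != length(texts)) {
    stop("malformed TextGrid (interval/text count mismatch): ", path, call. = FALSE)
  }
  lab <- trimws(texts)
  voiced <- nzchar(lab)
  pitch <- suppressWarnings(as.numeric(lab[voiced]))
  if (any(is.na(pitch))) {
    stop("TextGrid interval labels must be pitch values in Hz (or empty for silence): ",
         path, call. = FALSE)
  }
  out <- data.frame(onset = xmin[voiced] * 1000,
                    duration = (xmax[voiced] - xmin[voiced]) * 1000,
                    pitch = pitch)
  attr(out, "total_duration") <- total
  out
}

read_events_pitchtier <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!any(grepl("ooTextFile", lines[seq_len(min(3, length(lines)))]))) {
    stop("not a Praat text file (missing ooTextFile header): ", path, call. = FALSE)
  }
  times <- praat_num(lines, "number")
  values <- praat_num(lines, "value")
  if (!length(times) || length(times) != length(values)) {
    stop("malformed PitchTier (no points or number/value mismatch): ", path, call. = FALSE)
  }
  xmax <- praat_num(lines, "xmax")
  total <- if (length(xmax)) xmax[1] * 1000 else NULL
  t_ms <- times * 1000
  spacing <- if (length(t_ms) > 1) diff(t_ms) else 100
  dur <- c(spacing, stats::median(spacing))
  out <- data.frame(onset = t_ms, duration = dur, pitch = values)
  attr(out, "total_duration") <- total
  out
}

#' MIDI note number to frequency
#' @param note MIDI note number(s); 69 is A4 = 440 Hz.
#' @return Frequency in Hz.
#' @export
midi_to_hz <- function(note) 440 * 2^((note - 69) / 12)

#' Frequency to nearest 12-TET MIDI note number
#' @param f_hz Frequency in Hz, `> 0`.
#' @return Integer MIDI note number (A4 = 440 Hz = note 69).
#' @export
hz_to_midi <- function(f_hz) {
  if (any(f_hz <= 0)) stop("frequencies must be > 0", call. = FALSE)
  as.integer(round(69 + 12 * log2(f_hz / 440)))
}

read_events_midi <- function(path) {
  notes <- smf_read(path)
  if (nrow(notes) > 1) {
    off <- notes$onset + notes$duration
    if (any(notes$onset[-1] < off[-nrow(notes)] - 1e-6)) {
      stop("overlapping MIDI notes: stream must be monophonic", call. = FALSE)
    }
  }
  data.frame(onset = notes$onset, duration = notes$duration,
             pitch = midi_to_hz(notes$note))
}

#' Read participant keypress logs from CSV
#'
#' Expected columns: `participant_id,instruction,stimulus_id,version,
#' press_ms,baseline_rt_ms` with one row per press (participants with zero
#' presses may appear as a single row with an empty `press_ms`).
#'
#' @param path CSV path.
#' @param grace,total_durations Optional press-time validation: a named
#'   vector of stimulus durations (ms) and the grace window (ms).
#' @return A list of [key_press_log()] objects, one per participant x
#'   stimulus x version combination present in the file.
#' @export
read_keypress_logs <- function(path, total_durations = NULL, grace = 1000) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("participant_id", "instruction", "stimulus_id", "version",
            "press_ms", "baseline_rt_ms")
  if (!all(need %in% names(df))) {
    stop("keypress CSV must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  key <- interaction(df$participant_id, df$stimulus_id, df$version, drop = TRUE)
  lapply(split(df, key), function(g) {
    presses <- sort(g$press_ms[!is.na(g$press_ms)])
    key_press_log(
      participant_id = as.character(g$participant_id[1]),
      instruction = as.character(g$instruction[1]),
      stimulus_id = as.character(g$stimulus_id[1]),
      version = as.character(g$version[1]),
      press_times = presses,
      baseline_rt = g$baseline_rt_ms[1],
      total_duration = if (is.null(total_durations)) NULL
                       else total_durations[[as.character(g$stimulus_id[1])]],
      grace = grace)
  })
}

#' Write keypress logs to CSV
#' @param logs A list of [key_press_log()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keypress_logs <- function(logs, path) {
  rows <- lapply(logs, function(l) {
    press <- if (length(l$press_times)) l$press_times else NA_real_
    data.frame(participant_id = l$participant_id, instruction = l$instruction,
               stimulus_id = l$stimulus_id, version = l$version,
               press_ms = press, baseline_rt_ms = l$baseline_rt)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an analysis results table
#'
#' Long-format tables round-trip through CSV or JSON:
#' `read_results(write_results(x, p))` reproduces `x`.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default guesses from extension).
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, format = NULL) {
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  ok <- tryCatch({
    if (format == "csv") {
      utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
    } else {
      jsonlite::write_json(table, path, dataframe = "columns", digits = NA, na = "null")
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    utils::read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
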