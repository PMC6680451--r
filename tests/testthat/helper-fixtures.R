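# Fixture builders shared across test files.  Everything is generated in
# code; no binary fixtures are stored.

# A small hand-built stream: two phrases with a 300 ms gap.
tiny_stream <- function() {
  pitch_stream(onset = c(0, 800), duration = c(500, 400), pitch = c(110, 165),
               stimulus_id = "tiny", total_duration = 1500)
}

# Random valid integer-ms stream (sorted, non-overlapping).
random_stream <- function(n = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dur <- sample(50:400, n, replace = TRUE)
  gap <- sample(0:400, n, replace = TRUE)
  onset <- cumsum(c(0, (dur + gap)[-n]))
  pitch_stream(onset, dur, stats::runif(n, 80, 300),
               total_duration = onset[n] + dur[n] + sample(0:500, 1))
}

# Praat long-format TextGrid with one IntervalTier whose labels are Hz.
write_textgrid_fixture <- function(stream, path) {
  ev <- stream$events
  off <- ev$onset + ev$duration
  # build full interval list incl. silences
  bounds <- sort(unique(c(0, ev$onset, off, stream$total_duration))) / 1000
  lab <- vapply(seq_len(length(bounds) - 1), function(i) {
    hit <- which(abs(ev$onset / 1000 - bounds[i]) < 1e-9)
    if (length(hit)) format(ev$pitch[hit], digits = 12) else ""
  }, "")
  lines <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
             "xmin = 0", sprintf("xmax = %.10f", stream$total_duration / 1000),
             "tiers? <exists>", "size = 1", "item []:", "    item [1]:",
             '        class = "IntervalTier"', '        name = "events"',
             "        xmin = 0",
             sprintf("        xmax = %.10f", stream$total_duration / 1000),
             sprintf("        intervals: size = %d", length(lab)))
  for (i in seq_along(lab)) {
    lines <- c(lines,
               sprintf("        intervals [%d]:", i),
               sprintf("            xmin = %.10f", bounds[i]),
               sprintf("            xmax = %.10f", bounds[i + 1]),
               sprintf('            text = "%s"', lab[i]))
  }
  writeLines(lines, path)
  path
}

write_pitchtier_fixture <- function(times_ms, values_hz, xmax_ms, path) {
  lines <- c('File type = "ooTextFile"', 'Object class = "PitchTier"', "",
             "xmin = 0", sprintf("xmax = %.10f", xmax_ms / 1000),
             sprintf("points: size = %d", length(times_ms)))
  for (i in seq_along(times_ms)) {
    lines <- c(lines, sprintf("points [%d]:", i),
               sprintf("    number = %.10f", times_ms[i] / 1000),
               sprintf("    value = %.10f", values_hz[i]))
  }
  writeLines(lines, path)
  path
}

# Minimal stats stand-in when a test wants to pin sd/mean/range directly.
fake_stats <- function(mean_hz = 150, sd_hz = 30, range_hz = 100) {
  structure(list(mean_pitch_hz = mean_hz, sd_pitch_hz = sd_hz,
                 pitch_range_hz = range_hz),
            class = "stimulus_stats")
}

# One simulated stimulus + model set, reused by matching tests.
fixture_model_set <- function(seed = 7) {
  cfg <- stimulus_config(stimulus_id = "fix", duration_s = 45,
                         mean_pitch_hz = 140, sd_pitch_hz = 25, seed = seed)
  contour <- generate_contour(cfg)
  stream <- naturalize(contour)
  list(stream = stream, contour = contour, ms = assemble_model_set(stream))
}
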