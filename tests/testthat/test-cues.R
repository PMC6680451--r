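test_that("cue_thresholds carries the documented defaults", {
  th <- cue_thresholds()
  expect_equal(th$pause_min_ms, 200)
  expect_equal(th$break_gap_max_ms, 200)
  expect_equal(th$break_delta_sd, 1)
  expect_equal(th$movement_range_fraction, 1 / 3)
  expect_equal(th$rise_min_ms, 500)
  expect_equal(th$drop_min_ms, 1000)
  expect_equal(th$drop_low_end_sd, 0.5)
  expect_equal(th$deflection_max_ms_rise, 250)
  expect_equal(th$deflection_max_ms_drop, 200)
  expect_equal(th$within_movement_pause_max_ms, 200)
  expect_error(cue_thresholds(bogus = 1), "unknown")
  expect_equal(cue_thresholds(pause_min_ms = 300)$pause_min_ms, 300)
})

test_that("detect_pauses finds strict >200 ms silences at their onsets", {
  s <- tiny_stream()   # gap 500..800
  p <- detect_pauses(s)
  expect_equal(nrow(p), 1)
  expect_equal(p$onset, 500)
  expect_equal(p$offset, 800)

  s200 <- pitch_stream(c(0, 700), c(500, 300), c(110, 120))  # gap exactly 200
  expect_equal(nrow(detect_pauses(s200)), 0)
})

test_that("pause detection equals a brute-force gap scan on random streams", {
  for (seed in 1:10) {
    s <- random_stream(25, seed)
    ev <- s$events; off <- ev$onset + ev$duration
    brute <- 0
    for (i in seq_len(nrow(ev) - 1)) {
      if (ev$onset[i + 1] - off[i] > 200) brute <- brute + 1
    }
    expect_equal(nrow(detect_pauses(s)), brute)
  }
})

test_that("pitch breaks follow the contrast and silence rules", {
  th <- cue_thresholds()
  # delta = 60 Hz = 2 SD, gap 100 ms -> break at onset of B
  s <- pitch_stream(c(0, 600), c(500, 400), c(100, 160))
  b <- detect_pitch_breaks(s, fake_stats(sd_hz = 30), th)
  expect_equal(b$model, "pitch_break")
  expect_equal(b$time, 600)

  # same contrast, gap 300 ms -> pause-plus-break at the pause onset
  s2 <- pitch_stream(c(0, 800), c(500, 400), c(100, 160))
  b2 <- detect_pitch_breaks(s2, fake_stats(sd_hz = 30), th)
  expect_equal(b2$model, "pause_pitch_break")
  expect_equal(b2$time, 500)

  # delta exactly 1 SD -> nothing (strict >)
  b3 <- detect_pitch_breaks(s, fake_stats(sd_hz = 60), th)
  expect_equal(nrow(b3), 0)

  # abutting events (gap 0) are a step, not a break across silence
  s4 <- pitch_stream(c(0, 500), c(500, 400), c(100, 160))
  expect_equal(nrow(detect_pitch_breaks(s4, fake_stats(sd_hz = 30), th)), 0)
})

test_that("pitch movements qualify by range or duration, drops need a low end", {
  th <- cue_thresholds()
  # 5-event strict rise spanning 40 Hz = 40% of a 100 Hz range, 400 ms total
  s <- pitch_stream(seq(0, 320, by = 80), rep(80, 5), c(100, 110, 120, 130, 140))
  mv <- detect_pitch_movements(s, fake_stats(range_hz = 100), th, "rise")
  expect_equal(nrow(mv), 1)
  expect_equal(mv$time, 400)           # offset of the run
  expect_equal(mv$span_hz, 40)

  # 1200 ms monotone drop ending only 0.2 SD below the mean -> rejected
  s2 <- pitch_stream(seq(0, 900, by = 300), rep(300, 4), c(160, 155, 150, 144))
  mv2 <- detect_pitch_movements(s2, fake_stats(mean_hz = 150, sd_hz = 30,
                                               range_hz = 1000), th, "drop")
  expect_equal(nrow(mv2), 0)
  # same shape diving to mean - 1 SD -> accepted
  s3 <- pitch_stream(seq(0, 900, by = 300), rep(300, 4), c(160, 150, 140, 120))
  mv3 <- detect_pitch_movements(s3, fake_stats(mean_hz = 150, sd_hz = 30,
                                               range_hz = 1000), th, "drop")
  expect_equal(mv3$time, 1200)

  # 550 ms narrow rise (well under range/3) -> accepted by duration alone
  s4 <- pitch_stream(c(0, 190, 380), rep(180, 3), c(100, 102, 104))
  mv4 <- detect_pitch_movements(s4, fake_stats(range_hz = 1000), th, "rise")
  expect_equal(nrow(mv4), 1)
  expect_equal(mv4$time, 560)
})

test_that("deflections are tolerated up to their duration allowance", {
  th <- cue_thresholds()
  st <- fake_stats(range_hz = 1000)
  # rise with one 200 ms counter-step inside: tolerated (<= 250)
  s <- pitch_stream(c(0, 200, 400, 600, 800), c(200, 200, 200, 200, 200),
                    c(100, 110, 105, 120, 130))
  mv <- detect_pitch_movements(s, st, th, "rise")
  expect_equal(nrow(mv), 1)
  expect_equal(mv$time, 1000)
  expect_equal(mv$n_events, 5L)
  # same shape but a 300 ms deflection: run is split
  s2 <- pitch_stream(c(0, 200, 400, 700, 900), c(200, 200, 300, 200, 200),
                     c(100, 110, 105, 120, 130))
  mv2 <- detect_pitch_movements(s2, st, th, "rise")
  expect_true(all(mv2$n_events < 5))
})

test_that("assemble_model_set resolves coexistence exclusively", {
  # one isolated long gap only
  s <- pitch_stream(c(0, 1000), c(500, 500), c(150, 150))
  ms <- assemble_model_set(s)
  expect_equal(ms$points$model, "pause")
  expect_equal(vapply(ms$points_by_model, length, 0L)[["pause"]], 1L)
  expect_equal(sum(vapply(ms$points_by_model, length, 0L)), 1L)

  # monotone 1200 ms drop to a low pitch followed by a 300 ms gap:
  # one pause_pitch_drop point, no separate pause or drop point there
  s2 <- pitch_stream(c(0, 300, 600, 900, 1500, 1810, 2120),
                     c(300, 300, 300, 300, 300, 300, 380),
                     c(190, 160, 130, 100, 180, 181, 180))
  ms2 <- assemble_model_set(s2)
  expect_equal(ms2$points$model[ms2$points$time == 1200], "pause_pitch_drop")
  expect_false(any(ms2$points$model == "pause" & ms2$points$time == 1200))
  expect_false(any(ms2$points$model == "pitch_drop"))
})

test_that("generator ground truth is recovered exactly (mixed planted cues)", {
  fx <- fixture_model_set(seed = 11)
  truth <- contour_truth(fx$contour)
  det <- fx$ms$points
  expect_equal(nrow(det), nrow(truth))
  o_t <- order(truth$time); o_d <- order(det$time)
  expect_equal(det$time[o_d], truth$time[o_t])
  expect_equal(det$model[o_d], truth$model[o_t])
})

test_that("global_array_diagnostics counts points and gaps", {
  ms <- list(global_array = c(0, 1000, 3500))
  d <- global_array_diagnostics(ms)
  expect_equal(d$n_points, 3)
  expect_equal(d$max_adjacent_gap_ms, 2500)
  expect_equal(global_array_diagnostics(list(global_array = 42))$max_adjacent_gap_ms, 0)
  expect_error(global_array_diagnostics(list(global_array = numeric(0))), "empty")
  for (seed in 1:5) {
    set.seed(seed)
    ga <- sort(sample(1:10000, 30))
    brute <- max(vapply(2:30, function(i) ga[i] - ga[i - 1], 0))
    expect_equal(global_array_diagnostics(list(global_array = ga))$max_adjacent_gap_ms,
                 brute)
  }
})

test_that("detectors are translation- and (pauses) transposition-invariant", {
  fx <- fixture_model_set(seed = 23)
  s <- fx$stream
  shift <- pitch_stream(s$events$onset + 777, s$events$duration, s$events$pitch,
                        stimulus_id = s$stimulus_id,
                        total_duration = s$total_duration + 777)
  ms0 <- assemble_model_set(s); ms1 <- assemble_model_set(shift)
  expect_equal(ms1$global_array, ms0$global_array + 777)
  expect_equal(ms1$points$model, ms0$points$model)
  transposed <- pitch_stream(s$events$onset, s$events$duration,
                             s$events$pitch * 1.3,
                             total_duration = s$total_duration)
  expect_equal(detect_pauses(transposed), detect_pauses(s))
})

test_that("model lists are exclusive and tightening thresholds is monotone", {
  for (seed in c(5, 17)) {
    fx <- fixture_model_set(seed)
    counts <- vapply(fx$ms$points_by_model, length, 0L)
    expect_equal(sum(counts), length(fx$ms$global_array))
    expect_equal(anyDuplicated(fx$ms$points$time), 0L)
    base <- nrow(detect_pauses(fx$stream))
    for (pm in c(250, 300, 400, 600)) {
      expect_lte(nrow(detect_pauses(fx$stream, cue_thresholds(pause_min_ms = pm))),
                 base)
    }
  }
  # monotonicity on random streams too
  for (seed in 1:5) {
    s <- random_stream(30, seed)
    n_prev <- Inf
    for (pm in c(100, 200, 300, 400)) {
      n <- nrow(detect_pauses(s, cue_thresholds(pause_min_ms = pm)))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})
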