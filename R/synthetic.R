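# Synthetic stimuli and responders.
#
# The generator emulates the statistical shape of delexicalized speech:
# ~40-63 s utterances, syllable-like pitch events at 3-4 per second,
# moderate silence, F0 declination across phrases, and one planted
# boundary cue per phrase boundary, cycling through the seven cue models.
# It is parametric, not corpus-trained: phrase bodies are level-pitch
# syllable trains (declination is realised between phrases), which keeps
# the stimuli free of accidental cues so that detector precision/recall
# can be measured against exact ground truth.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Configuration for one synthetic stimulus
#'
#' Defaults mirror the acoustic profile of spontaneous-speech stimuli:
#' about 60 s, mean pitch 112-185 Hz with SD 18-51 Hz, 3-4 pitch events
#' per second. Boundary cue types cycle through the seven models starting
#' at `boundary_phase`, one cue per phrase boundary.
#'
#' @param stimulus_id Label.
#' @param duration_s Target utterance duration in seconds.
#' @param mean_pitch_hz,sd_pitch_hz Nominal pitch mean and SD (Hz). The
#'   realised duration-weighted mean is normalised to `mean_pitch_hz`
#'   exactly; the realised SD is of the same order as `sd_pitch_hz` but is
#'   an emergent property of the phrase plan.
#' @param syllable_rate_hz Syllable (pitch-event) rate, events per second.
#' @param n_phrases Number of phrases; default `round(duration_s / 7)`.
#' @param boundary_phase Offset (0-6) into the cue-model cycle for the
#'   first internal boundary.
#' @param vibrato_pct Within-syllable micro-modulation amplitude as a
#'   percentage of the syllable pitch (one full sine period per syllable,
#'   so event-mean pitch is unaffected). 0 gives piecewise-constant F0.
#' @param sample_step_ms Contour sampling step.
#' @param seed Seed for the stimulus plan.
#' @return A `stimulus_config` list.
#' @export
stimulus_config <- function(stimulus_id = "synthetic",
                            duration_s = 60,
                            mean_pitch_hz = 150, sd_pitch_hz = 30,
                            syllable_rate_hz = 3.3,
                            n_phrases = NULL,
                            boundary_phase = 0,
                            vibrato_pct = 0.5,
                            sample_step_ms = 5,
                            seed = NULL) {
  if (duration_s <= 0 || mean_pitch_hz <= 0 || sd_pitch_hz <= 0 ||
      syllable_rate_hz <= 0) {
    stop("duration, pitch mean/SD and syllable rate must be positive", call. = FALSE)
  }
  if (syllable_rate_hz < 2 || syllable_rate_hz > 4.5) {
    stop("syllable_rate_hz outside the supported 2-4.5 events/s band", call. = FALSE)
  }
  # at least 8 phrases so that every stimulus contains all 7 boundary cue
  # types (in particular the deep pause+drop dive that anchors the global
  # pitch range)
  if (is.null(n_phrases)) n_phrases <- max(8, round(duration_s / 7))
  if (n_phrases < 8) stop("n_phrases must be at least 8", call. = FALSE)
  if (duration_s * 1000 / n_phrases < 2800) {
    stop("infeasible phrase plan: phrases shorter than 2.8 s", call. = FALSE)
  }
  structure(list(stimulus_id = stimulus_id, duration_s = duration_s,
                 mean_pitch_hz = mean_pitch_hz, sd_pitch_hz = sd_pitch_hz,
                 syllable_rate_hz = syllable_rate_hz, n_phrases = n_phrases,
                 boundary_phase = boundary_phase %% 7L,
                 vibrato_pct = vibrato_pct, sample_step_ms = sample_step_ms,
                 seed = seed),
            class = "stimulus_config")
}

#' The five default stimulus configurations
#'
#' Nominal parameters follow the acoustic profile of five spontaneous
#' utterances: mean pitch 185/112/130/172/123 Hz, pitch SD 28/21/35/51/20
#' Hz, durations 63.4/55.5/57.0/59.1/40.2 s, event rates near 3.5/3.2/3.0/
#' 3.1/4.0 per second. Boundary phases are staggered so the seven cue
#' models are evenly represented across the set.
#'
#' @param seed Base seed; stimulus i uses `seed + i`.
#' @return List of five [stimulus_config()] objects.
#' @export
default_stimulus_set <- function(seed = 1) {
  mean_hz <- c(185, 112, 130, 172, 123)
  sd_hz <- c(28, 21, 35, 51, 20)
  dur_s <- c(63.4, 55.5, 57.0, 59.1, 40.2)
  rate <- c(3.47, 3.2, 3.02, 3.09, 4)
  lapply(1:5, function(i) {
    stimulus_config(stimulus_id = paste0("st", i), duration_s = dur_s[i],
                    mean_pitch_hz = mean_hz[i], sd_pitch_hz = sd_hz[i],
                    syllable_rate_hz = rate[i], boundary_phase = (i - 1L) %% 7L,
                    seed = if (is.null(seed)) NULL else seed + i)
  })
}

# --- internal: plan one stimulus as events + ground truth ----------------
# All pitch arithmetic is done on an integer-semitone lattice relative to
# the nominal mean.  Because every planned pitch sits on one lattice, the
# final multiplicative mean-normalisation shifts all events by the same
# fractional semitone, so 12-TET quantization displaces every event by the
# same ratio: in-movement steps can never collapse or invert, and the
# delexicalized version preserves the natural version's SD/mean ratio
# exactly.
# Break jump J and deep-dive step s_d are calibrated on the realized plan:
# J must clear one realized (duration-weighted) pitch SD at the boundary
# where it occurs, so the planted break always fires, yet both the jump
# and the drop-recovery hops must stay under a third of the realized
# global range, so a two-event pair can never span-qualify as a movement.
# The plan is rebuilt with adjusted (J, s_d) until both margins hold.
plan_stimulus <- function(config) {
  sig_st <- 12 * log2(1 + config$sd_pitch_hz / config$mean_pitch_hz)
  J <- max(2, round(0.8 * sig_st))
  s_d <- max(1, round(0.35 * sig_st))
  for (iter in 1:8) {
    plan <- build_plan(config, J, s_d)
    ev <- plan$events
    w <- ev$duration
    m <- sum(w * ev$pitch) / sum(w)
    sd_act <- sqrt(sum(w * (ev$pitch - m)^2) / sum(w))
    range_act <- max(ev$pitch) - min(ev$pitch)
    deltas <- abs(ev$pitch[plan$pairs$b] - ev$pitch[plan$pairs$a])
    clear_deltas <- deltas[plan$pairs$kind %in% c("jump", "jumpp")]
    span_deltas <- deltas[plan$pairs$kind %in% c("jump", "hop")]
    ok_clear <- !length(clear_deltas) || min(clear_deltas) > 1.25 * sd_act
    ok_span <- max(c(span_deltas, 0)) < 0.9 * range_act / 3
    if (ok_clear && ok_span) return(plan)
    if (!ok_clear) J <- J + 1L
    if (!ok_span) s_d <- s_d + 1L
  }
  stop("infeasible stimulus configuration: cannot separate the pitch-SD ",
       "and range constraints for the break jump", call. = FALSE)
}

build_plan <- function(config, J, s_d) {
  sig_st <- 12 * log2(1 + config$sd_pitch_hz / config$mean_pitch_hz)
  s_r <- max(1, round(0.35 * sig_st))     # rise step (3 steps)
  s_sh <- 1L                              # shallow (plain) drop step, 6 steps
  K <- config$n_phrases
  sched <- round(0.45 * sig_st - (seq_len(K) - 1) * 0.9 * sig_st / max(1, K - 1))
  # post-rise landings are kept above the drop low-end region so the
  # return step from a rise peak can never register as a pitch drop
  floor_st <- ceiling(12 * log2(max(1 - 0.1 * config$sd_pitch_hz /
                                      config$mean_pitch_hz, 0.8)))
  pairs <- list(a = integer(0), b = integer(0), kind = character(0))
  note_pair <- function(a, b, kind) {
    pairs$a <<- c(pairs$a, a); pairs$b <<- c(pairs$b, b)
    pairs$kind <<- c(pairs$kind, kind)
  }
  models <- CUE_MODELS[((config$boundary_phase + seq_len(K - 1) - 1L) %% 7L) + 1L]
  syl_period <- 1000 / config$syllable_rate_hz
  body_dur <- function(n) round(syl_period) - 25 + sample(-15:15, n, replace = TRUE)
  body_gap <- function(n) sample(10:40, n, replace = TRUE)

  phrase_len <- config$duration_s * 1000 / K
  onset <- numeric(0); duration <- numeric(0); st <- numeric(0)
  truth <- list()
  t <- 0
  x_prev <- sched[1]
  pending_ladder <- NULL   # recovery ladder pitches after a plain drop
  pending_short <- FALSE   # short first body event (after breaks / ladders)
  for (k in seq_len(K)) {
    bound <- if (k < K) models[k] else "end"
    x <- if (k == 1) sched[1] else x_prev
    # movement tail reserve
    tail_ms <- switch(bound,
      pitch_rise = , pause_pitch_rise = 3 * 170,
      pitch_drop = 6 * 190, pause_pitch_drop = 9 * 190, 0)
    gap_after <- switch(bound,
      pause = , pause_pitch_break = , pause_pitch_rise = , pause_pitch_drop =
        sample(380:650, 1),
      pitch_break = sample(80:150, 1),
      pitch_rise = , pitch_drop = 200,
      end = 0)
    ladder_ms <- if (!is.null(pending_ladder)) (100 + 280) else 0
    body_ms <- phrase_len - tail_ms - gap_after - ladder_ms
    n_body <- max(3, round(body_ms / (syl_period)))

    # recovery ladder from a preceding plain pitch drop
    if (!is.null(pending_ladder)) {
      note_pair(length(onset), length(onset) + 1L, "hop")    # bottom -> mid
      onset <- c(onset, t); duration <- c(duration, 100); st <- c(st, pending_ladder)
      t <- t + 100
      onset <- c(onset, t); duration <- c(duration, 280); st <- c(st, pending_ladder)
      t <- t + 280                     # abuts the next body event: a step,
      pending_ladder <- NULL           # not a break across silence
      note_pair(length(onset), length(onset) + 1L, "hop")    # mid -> body
      pending_short <- TRUE
    }
    durs <- body_dur(n_body)
    gaps <- body_gap(n_body)
    if (pending_short) { durs[1] <- 100; pending_short <- FALSE }
    # keep the event pair flanking a pitch break short enough that the
    # jump can never double as a 500 ms two-event movement run
    if (bound == "pitch_break") durs[n_body] <- 100
    for (i in seq_len(n_body)) {
      onset <- c(onset, t); duration <- c(duration, durs[i]); st <- c(st, x)
      t <- t + durs[i] + (if (i < n_body) gaps[i] else 0)
    }
    # movement tail
    if (bound %in% c("pitch_rise", "pause_pitch_rise")) {
      for (i in 1:3) {
        onset <- c(onset, t); duration <- c(duration, 170); st <- c(st, x + i * s_r)
        t <- t + 170
      }
    } else if (bound == "pitch_drop") {
      for (i in 1:6) {
        onset <- c(onset, t); duration <- c(duration, 190); st <- c(st, x - i * s_sh)
        t <- t + 190
      }
    } else if (bound == "pause_pitch_drop") {
      for (i in 1:9) {
        onset <- c(onset, t); duration <- c(duration, 190); st <- c(st, x - i * s_d)
        t <- t + 190
      }
    }
    if (bound == "end") break
    # ground truth point
    point <- switch(bound,
      pause = , pause_pitch_break = , pause_pitch_rise = , pause_pitch_drop = t,
      pitch_rise = , pitch_drop = t,   # movement offset (== current t)
      pitch_break = t + gap_after)     # onset of next phrase's first event
    truth[[k]] <- data.frame(time = point, model = bound)
    if (bound == "pitch_break") note_pair(length(onset), length(onset) + 1L, "jump")
    if (bound == "pause_pitch_break") note_pair(length(onset), length(onset) + 1L, "jumpp")
    # next phrase level
    x_next <- switch(bound,
      pitch_break = x + J,   # always up; the following break returns down
      pause_pitch_break = if (x >= sched[k + 1]) x - J else x + J,
      pitch_rise = , pause_pitch_rise =
        min(max(min(sched[k + 1], x + 3 * s_r - 1), floor_st), x + 3 * s_r - 1),
      sched[k + 1])
    if (bound == "pitch_break") pending_short <- TRUE
    if (bound == "pitch_drop") pending_ladder <- x - 3 * s_sh  # mid-level
    t <- t + gap_after
    x_prev <- x_next
  }
  pitch <- config$mean_pitch_hz * 2^(st / 12)
  # normalise the duration-weighted mean onto the nominal mean exactly
  pitch <- pitch * config$mean_pitch_hz / (sum(pitch * duration) / sum(duration))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(time = numeric(0), model = character(0))
  list(events = data.frame(onset = onset, duration = duration, pitch = pitch),
       truth = truth, total_duration = t + 200,
       pairs = as.data.frame(pairs))
}

#' Generate a synthetic pitch contour with planted boundary cues
#'
#' Builds the stimulus plan (phrase bodies, declination, one planted cue
#' per phrase boundary) and renders it as a dense F0 track. Each syllable
#' carries one full period of sinusoidal micro-modulation, sampled
#' symmetrically so that the per-syllable mean equals the planned pitch
#' exactly; silences are not sampled.
#'
#' @param config A [stimulus_config()].
#' @return A `pitch_contour`: data.frame with `time_ms`, `f0_hz`, plus
#'   attributes `syllables` (data.frame `onset`, `duration`, `pitch`),
#'   `truth` (data.frame `time`, `model`: the planted cues),
#'   `total_duration` and `config`.
#' @export
generate_contour <- function(config) {
  plan <- with_seed(config$seed, plan_stimulus(config))
  ev <- plan$events
  A <- config$vibrato_pct / 100
  step <- config$sample_step_ms
  samp <- lapply(seq_len(nrow(ev)), function(i) {
    n <- max(1L, round(ev$duration[i] / step))
    u <- (seq_len(n) - 0.5) / n
    data.frame(time_ms = ev$onset[i] + u * ev$duration[i],
               f0_hz = ev$pitch[i] * (1 + A * sin(2 * pi * u)))
  })
  out <- do.call(rbind, samp)
  structure(out,
            syllables = data.frame(onset = ev$onset, duration = ev$duration,
                                   pitch = ev$pitch),
            truth = plan$truth,
            total_duration = plan$total_duration,
            config = config,
            class = c("pitch_contour", "data.frame"))
}

#' Planted ground-truth cues of a contour
#' @param contour A `pitch_contour`.
#' @return data.frame `time`, `model`.
#' @export
contour_truth <- function(contour) attr(contour, "truth")

contour_events <- function(contour, pitch_fun) {
  syl <- attr(contour, "syllables")
  pit <- vapply(seq_len(nrow(syl)), function(i) {
    inside <- contour$time_ms >= syl$onset[i] &
      contour$time_ms < syl$onset[i] + syl$duration[i]
    pitch_fun(contour$f0_hz[inside])
  }, 0)
  list(syl = syl, pitch = pit)
}

#' Render the natural-speech version of a contour
#'
#' Segments the contour at syllable onsets; each event's pitch is the mean
#' F0 over its span, unquantized.
#'
#' @param contour A `pitch_contour`.
#' @return A [pitch_stream()] with `version = "natural"`.
#' @export
naturalize <- function(contour) {
  ce <- contour_events(contour, mean)
  pitch_stream(ce$syl$onset, ce$syl$duration, ce$pitch,
               stimulus_id = attr(contour, "config")$stimulus_id,
               version = "natural",
               total_duration = attr(contour, "total_duration"))
}

#' Render the delexicalized (audio-to-MIDI style) version of a contour
#'
#' Same segmentation as [naturalize()], but each event's pitch is snapped
#' to the nearest 12-TET semitone (A4 = 440 Hz), emulating the discrete
#' pitch of an audio-to-MIDI conversion; intensity is not modelled.
#'
#' @param contour A `pitch_contour`.
#' @return A [pitch_stream()] with `version = "delexicalized"`.
#' @export
delexicalize <- function(contour) {
  ce <- contour_events(contour, mean)
  pitch_stream(ce$syl$onset, ce$syl$duration, midi_to_hz(hz_to_midi(ce$pitch)),
               stimulus_id = attr(contour, "config")$stimulus_id,
               version = "delexicalized",
               total_duration = attr(contour, "total_duration"))
}

#' Configuration of a simulated responder group
#'
#' @param instruction `"speech"` or `"music"`.
#' @param cue_weights Named vector over [CUE_MODELS]: probability that a
#'   cue of each model elicits a press.
#' @param false_alarm_rate Spurious presses per minute (Poisson).
#' @param rt_mean_ms,rt_sd_ms Press latency distribution (Normal), also
#'   used for the measured baseline RT (truncated positive).
#' @param motor_jitter_sd_ms Extra motor noise SD per press.
#' @param refractory_ms Presses closer than this to the previous one are
#'   dropped.
#' @param seed Optional seed.
#' @return A `responder_config` list.
#' @export
responder_config <- function(instruction = "speech",
                             cue_weights = stats::setNames(rep(0.7, 7), CUE_MODELS),
                             false_alarm_rate = 0.5,
                             rt_mean_ms = 287, rt_sd_ms = 50,
                             motor_jitter_sd_ms = 20,
                             refractory_ms = 300,
                             seed = NULL) {
  if (!all(CUE_MODELS %in% names(cue_weights))) {
    stop("cue_weights must be named over all seven models", call. = FALSE)
  }
  cue_weights <- cue_weights[CUE_MODELS]
  if (any(cue_weights < 0 | cue_weights > 1)) {
    stop("cue_weights must be probabilities in [0, 1]", call. = FALSE)
  }
  if (rt_mean_ms <= 0 || rt_sd_ms <= 0) stop("RT parameters must be > 0", call. = FALSE)
  if (false_alarm_rate < 0) stop("false_alarm_rate must be >= 0", call. = FALSE)
  structure(list(instruction = instruction, cue_weights = cue_weights,
                 false_alarm_rate = false_alarm_rate, rt_mean_ms = rt_mean_ms,
                 rt_sd_ms = rt_sd_ms, motor_jitter_sd_ms = motor_jitter_sd_ms,
                 refractory_ms = refractory_ms, seed = seed),
            class = "responder_config")
}

rtrunc_norm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

#' Simulate keypress responders for one stimulus version
#'
#' Each participant presses, for every virtual segmentation point of model
#' M, with probability `cue_weights[M]`, at the cue time plus a Normal
#' press latency plus motor jitter; false alarms arrive as a Poisson
#' process; presses within the refractory window of the previous press are
#' collapsed. Baseline RTs are drawn once per participant.
#'
#' @param model_set A `cue_model_set`.
#' @param config A [responder_config()].
#' @param n_participants Number of simulated participants.
#' @param total_duration Stimulus duration in ms (for false alarms and
#'   press clipping).
#' @param participant_prefix Prefix for participant ids.
#' @return List of [key_press_log()] objects.
#' @export
simulate_responders <- function(model_set, config, n_participants,
                                total_duration, participant_prefix = "p") {
  if (!length(model_set$global_array)) stop("empty global array", call. = FALSE)
  if (all(config$cue_weights == 0) && config$false_alarm_rate == 0) {
    warning("all cue weights zero and no false alarms: empty logs")
  }
  with_seed(config$seed, {
    lapply(seq_len(n_participants), function(j) {
      baseline <- rtrunc_norm_pos(1, config$rt_mean_ms, config$rt_sd_ms)
      presses <- numeric(0)
      for (m in CUE_MODELS) {
        pts <- model_set$points_by_model[[m]]
        if (!length(pts)) next
        hit <- stats::runif(length(pts)) < config$cue_weights[[m]]
        if (any(hit)) {
          lat <- rtrunc_norm_pos(sum(hit), config$rt_mean_ms, config$rt_sd_ms) +
            stats::rnorm(sum(hit), 0, config$motor_jitter_sd_ms)
          presses <- c(presses, pts[hit] + lat)
        }
      }
      n_fa <- stats::rpois(1, config$false_alarm_rate * total_duration / 60000)
      if (n_fa > 0) presses <- c(presses, stats::runif(n_fa, 0, total_duration))
      presses <- sort(presses[presses > 0 & presses <= total_duration + 1000])
      if (length(presses) > 1) {
        keep <- c(TRUE, diff(presses) > config$refractory_ms)
        while (!all(keep)) {        # re-check after collapsing
          presses <- presses[keep]
          keep <- if (length(presses) > 1) c(TRUE, diff(presses) > config$refractory_ms) else TRUE
        }
      }
      key_press_log(participant_id = sprintf("%s%03d", participant_prefix, j),
                    instruction = config$instruction,
                    stimulus_id = model_set$stimulus_id,
                    version = model_set$version,
                    press_times = presses, baseline_rt = baseline)
    })
  })
}

#' Configuration of a full simulated experiment
#'
#' Two instruction groups (n = 35 each by default) hear the same stimuli
#' in natural and delexicalized versions. Cue weights for natural speech
#' are shared by both groups; delexicalized weights are group-specific,
#' which is how a delexicalization x instruction interaction is planted
#' (the default weights scale natural adherence by 0.6 for the speech
#' group and 0.95 for the music group).
#'
#' @param n_per_group Participants per instruction group.
#' @param stimuli List of [stimulus_config()]s; default
#'   [default_stimulus_set()].
#' @param weights_natural Named cue-weight vector for natural versions.
#' @param weights_delex_speech,weights_delex_music Group-specific weights
#'   for delexicalized versions.
#' @param false_alarm_rate,rt_mean_ms,rt_sd_ms,motor_jitter_sd_ms,refractory_ms
#'   Passed to [responder_config()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_per_group = 35,
                              stimuli = NULL,
                              weights_natural = NULL,
                              weights_delex_speech = NULL,
                              weights_delex_music = NULL,
                              false_alarm_rate = 0.5,
                              rt_mean_ms = 287, rt_sd_ms = 50,
                              motor_jitter_sd_ms = 20, refractory_ms = 300,
                              seed = 1) {
  base <- stats::setNames(c(0.8, 0.55, 0.7, 0.45, 0.5, 0.65, 0.75), CUE_MODELS)
  if (is.null(weights_natural)) weights_natural <- base
  if (is.null(weights_delex_speech)) weights_delex_speech <- 0.6 * base
  if (is.null(weights_delex_music)) weights_delex_music <- 0.95 * base
  if (is.null(stimuli)) stimuli <- default_stimulus_set(seed = seed * 101)
  structure(list(n_per_group = n_per_group, stimuli = stimuli,
                 weights_natural = weights_natural,
                 weights_delex_speech = weights_delex_speech,
                 weights_delex_music = weights_delex_music,
                 false_alarm_rate = false_alarm_rate,
                 rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
                 motor_jitter_sd_ms = motor_jitter_sd_ms,
                 refractory_ms = refractory_ms, seed = seed),
            class = "experiment_config")
}

#' Simulate a complete segmentation experiment
#'
#' Generates the stimuli (both versions), assembles the cue model sets,
#' simulates both instruction groups on every stimulus version, and
#' returns the full dataset. Deterministic given the config seed.
#'
#' @param config An [experiment_config()].
#' @param thresholds [cue_thresholds()] used for the model sets.
#' @return List with `streams` (list of `pitch_stream`), `model_sets`,
#'   `truths`, `logs` (flat list of [key_press_log()]), and `design`
#'   (data.frame of participant ids and instructions).
#' @export
simulate_experiment <- function(config, thresholds = cue_thresholds()) {
  streams <- list(); model_sets <- list(); truths <- list(); logs <- list()
  groups <- list(speech = config$weights_delex_speech,
                 music = config$weights_delex_music)
  for (si in seq_along(config$stimuli)) {
    scfg <- config$stimuli[[si]]
    contour <- generate_contour(scfg)
    for (version in c("natural", "delexicalized")) {
      stream <- if (version == "natural") naturalize(contour) else delexicalize(contour)
      key <- paste(stream$stimulus_id, version)
      streams[[key]] <- stream
      truths[[key]] <- contour_truth(contour)
      ms <- assemble_model_set(stream, thresholds)
      model_sets[[key]] <- ms
      for (gi in seq_along(groups)) {
        ins <- names(groups)[gi]
        w <- if (version == "natural") config$weights_natural else groups[[gi]]
        rcfg <- responder_config(
          instruction = ins, cue_weights = w,
          false_alarm_rate = config$false_alarm_rate,
          rt_mean_ms = config$rt_mean_ms, rt_sd_ms = config$rt_sd_ms,
          motor_jitter_sd_ms = config$motor_jitter_sd_ms,
          refractory_ms = config$refractory_ms,
          seed = (config$seed * 7919 + si * 613 + gi * 101 +
                    (version == "natural") * 31) %% 2147483647)
        logs <- c(logs, simulate_responders(
          ms, rcfg, config$n_per_group, stream$total_duration,
          participant_prefix = if (ins == "speech") "s" else "m"))
      }
    }
  }
  ids <- unique(vapply(logs, function(l) l$participant_id, ""))
  design <- data.frame(
    participant_id = ids,
    instruction = ifelse(startsWith(ids, "s"), "speech", "music"))
  list(streams = streams, model_sets = model_sets, truths = truths,
       logs = logs, design = design)
}
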