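#' Correct keypress times for the participant's baseline reaction time
#'
#' Perceived boundary times are estimated by subtracting the participant's
#' baseline auditory reaction time from each raw press time. Corrected times
#' that would fall before stimulus onset are clamped to 0.
#'
#' @param log A [key_press_log()].
#' @return Numeric vector of corrected press times (ms), sorted.
#' @export
correct_keypresses <- function(log) {
  if (is.null(log$baseline_rt) || !is.finite(log$baseline_rt) || log$baseline_rt <= 0) {
    stop("keypress log has no usable baseline reaction time", call. = FALSE)
  }
  pmax(log$press_times - log$baseline_rt, 0)
}

#' Snap corrected press times onto the global array
#'
#' Each press sets the bit of its nearest global-array time; exact midpoints
#' break toward the earlier time, and several presses snapping to the same
#' time set the bit once (the number of such collisions is kept as a QC
#' attribute).
#'
#' @param corrected_times Numeric vector of corrected press times (ms).
#' @param global_array Sorted, non-empty numeric vector of reference times.
#' @return A `logical_array`: list with `reference` (the global array) and
#'   `bits` (0/1 integer vector of the same length), with attribute
#'   `n_collisions`.
#' @export
assign_to_global <- function(corrected_times, global_array) {
  if (!length(global_array)) stop("global array is empty", call. = FALSE)
  if (is.unsorted(global_array)) stop("global array must be sorted", call. = FALSE)
  bits <- integer(length(global_array))
  idx <- integer(0)
  if (length(corrected_times)) {
    lo <- findInterval(corrected_times, global_array)
    lo[lo == 0L] <- 1L
    hi <- pmin(lo + 1L, length(global_array))
    d_lo <- abs(corrected_times - global_array[lo])
    d_hi <- abs(corrected_times - global_array[hi])
    idx <- ifelse(d_hi < d_lo, hi, lo)   # ties (d_hi == d_lo) go to the earlier
    bits[unique(idx)] <- 1L
  }
  structure(list(reference = global_array, bits = bits),
            class = "logical_array",
            n_collisions = length(idx) - length(unique(idx)))
}

#' Model logical array
#'
#' The 0/1 indicator of one model's points over the global array.
#' @param model_set A `cue_model_set`.
#' @param model One of [CUE_MODELS].
#' @return A `logical_array`.
#' @export
model_logical_array <- function(model_set, model) {
  model <- match.arg(model, CUE_MODELS)
  ga <- model_set$global_array
  structure(list(reference = ga,
                 bits = as.integer(ga %in% model_set$points_by_model[[model]])),
            class = "logical_array", n_collisions = 0L)
}

#' Russell-Rao binary similarity coefficient
#'
#' `S = a / n`, where `a` is the number of positions where both arrays are 1
#' and `n` the number of positions. Both arguments must be logical arrays
#' over the same reference times.
#'
#' @param x,y `logical_array` objects (or plain 0/1 vectors of equal length).
#' @return The coefficient, in `[0, 1]`.
#' @export
russell_rao <- function(x, y) {
  bx <- if (inherits(x, "logical_array")) x$bits else x
  by <- if (inherits(y, "logical_array")) y$bits else y
  if (inherits(x, "logical_array") && inherits(y, "logical_array")) {
    if (length(x$reference) != length(y$reference) ||
        any(abs(x$reference - y$reference) > 1e-9)) {
      stop("logical arrays are not aligned to the same reference times", call. = FALSE)
    }
  }
  if (length(bx) != length(by)) stop("logical arrays differ in length", call. = FALSE)
  if (!length(bx)) stop("empty logical arrays", call. = FALSE)
  sum(bx == 1L & by == 1L) / length(bx)
}

#' Match one participant's segmentation against the seven cue models
#'
#' Corrects the participant's press times, snaps them onto the stimulus
#' global array, and scores adherence to each model with the Russell-Rao
#' coefficient.
#'
#' @param log A [key_press_log()] for the same stimulus and version as
#'   `model_set`.
#' @param model_set A `cue_model_set` from [assemble_model_set()].
#' @return data.frame with one row per model: `participant_id`,
#'   `instruction`, `stimulus_id`, `version`, `model`, `score`.
#' @export
match_participant <- function(log, model_set) {
  if (!identical(log$stimulus_id, model_set$stimulus_id) ||
      !identical(log$version, model_set$version)) {
    stop(sprintf("log (%s/%s) and model set (%s/%s) refer to different stimuli",
                 log$stimulus_id, log$version,
                 model_set$stimulus_id, model_set$version), call. = FALSE)
  }
  if (!length(model_set$global_array)) {
    stop("model set has an empty global array", call. = FALSE)
  }
  part <- assign_to_global(correct_keypresses(log), model_set$global_array)
  score <- vapply(CUE_MODELS, function(m) {
    russell_rao(part, model_logical_array(model_set, m))
  }, 0)
  data.frame(participant_id = log$participant_id,
             instruction = log$instruction,
             stimulus_id = log$stimulus_id, version = log$version,
             model = CUE_MODELS, score = unname(score),
             row.names = NULL)
}

#' Match many keypress logs against their model sets
#'
#' @param logs List of [key_press_log()] objects.
#' @param model_sets List of `cue_model_set` objects; matched to logs by
#'   `stimulus_id` and `version`.
#' @return Long data.frame of matching scores (7 rows per log).
#' @export
match_all <- function(logs, model_sets) {
  key <- vapply(model_sets, function(m) paste(m$stimulus_id, m$version), "")
  names(model_sets) <- key
  do.call(rbind, lapply(logs, function(l) {
    k <- paste(l$stimulus_id, l$version)
    ms <- model_sets[[k]]
    if (is.null(ms)) stop("no model set for ", k, call. = FALSE)
    match_participant(l, ms)
  }))
}
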