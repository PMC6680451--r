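#' Run the full inferential layer of a segmentation experiment
#'
#' Mirrors the standard analysis structure for a 2 (version: natural vs
#' delexicalized, within) x 2 (instruction: speech vs music, between) design
#' with a 7-level model factor on the matching scores:
#' \enumerate{
#'   \item Segment length: 2x2 mixed ANOVAs on the per-participant mean and
#'     SD of segment length (averaged over stimuli).
#'   \item Model matching: 2x2x7 mixed ANOVA on Russell-Rao scores; when
#'     the three-way version x model x instruction interaction is
#'     significant at `alpha`, per-model 2x2 ANOVAs are run, each with
#'     follow-up paired t-tests of the delexicalization effect within each
#'     instruction group (uncorrected by default, Holm-adjusted p-values
#'     added when `holm = TRUE`).
#'   \item Confidence ratings (optional): 2x2 mixed ANOVA treating the
#'     rating as continuous.
#' }
#'
#' @param scores Long data.frame of matching scores:
#'   `participant_id, instruction, stimulus_id, version, model, score`.
#' @param seglens Long data.frame of segment statistics:
#'   `participant_id, instruction, stimulus_id, version, n_segments,
#'   mean_len_ms, sd_len_ms`.
#' @param confidence Optional data.frame
#'   `participant_id, instruction, version, rating`.
#' @param alpha Gate level for the three-way interaction (default 0.05).
#' @param holm Add Holm-corrected p-values to follow-up tables?
#' @param gg Greenhouse-Geisser correction in the ANOVAs?
#' @return A `phraseseg_results` list with elements `seglen` (per-metric
#'   ANOVA tables), `seglen_means`, `matching` (the 2x2x7 table),
#'   `per_model` (NULL unless the 3-way gate opened), `followups`,
#'   `confidence`, `alpha`.
#' @export
analyze_experiment <- function(scores, seglens, confidence = NULL,
                               alpha = 0.05, holm = FALSE, gg = FALSE) {
  need_s <- c("participant_id", "instruction", "version", "model", "score")
  if (!all(need_s %in% names(scores))) {
    stop("scores must have columns ", paste(need_s, collapse = ","), call. = FALSE)
  }
  need_l <- c("participant_id", "instruction", "version", "mean_len_ms", "sd_len_ms")
  if (!all(need_l %in% names(seglens))) {
    stop("seglens must have columns ", paste(need_l, collapse = ","), call. = FALSE)
  }
  # collapse the stimulus dimension: participant-level cells.  Undefined
  # per-stimulus values (e.g. segment-length SD for a one-press record)
  # are averaged out over the remaining stimuli; a participant missing a
  # whole cell is dropped, and groups are trimmed (deterministically, by
  # id order) back to equal size, which mixed_anova requires.
  sc <- stats::aggregate(score ~ participant_id + instruction + version + model,
                         data = scores, FUN = mean)
  sl_mean <- stats::aggregate(mean_len_ms ~ participant_id + instruction + version,
                              data = seglens, FUN = mean, na.action = stats::na.omit)
  sl_sd <- stats::aggregate(sd_len_ms ~ participant_id + instruction + version,
                            data = seglens, FUN = mean, na.action = stats::na.omit)
  sl_n <- stats::aggregate(n_segments ~ participant_id + instruction + version,
                           data = seglens, FUN = mean)
  balance_cells <- function(d) {
    n_cell <- length(unique(d$version))
    cnt <- table(d$participant_id)
    keep <- names(cnt)[cnt == n_cell]
    dropped <- setdiff(unique(d$participant_id), keep)
    d <- d[d$participant_id %in% keep, , drop = FALSE]
    grp <- tapply(d$participant_id, d$instruction, function(x) sort(unique(x)))
    n_min <- min(lengths(grp))
    if (n_min < 2) stop("design error: fewer than 2 complete participants in a group",
                        call. = FALSE)
    keep2 <- unlist(lapply(grp, utils::head, n_min))
    trimmed <- setdiff(unlist(grp), keep2)
    if (length(dropped) || length(trimmed)) {
      warning(sprintf("dropped %d incomplete and trimmed %d participant(s) to balance the design",
                      length(dropped), length(trimmed)), call. = FALSE)
    }
    d[d$participant_id %in% keep2, , drop = FALSE]
  }
  sl_mean <- balance_cells(sl_mean)
  sl_sd <- balance_cells(sl_sd)
  sl_n <- balance_cells(sl_n)

  seglen_tables <- list(
    mean_len_ms = mixed_anova(sl_mean, "mean_len_ms", within = "version",
                              between = "instruction", gg = gg),
    sd_len_ms = mixed_anova(sl_sd, "sd_len_ms", within = "version",
                            between = "instruction", gg = gg),
    n_segments = mixed_anova(sl_n, "n_segments", within = "version",
                             between = "instruction", gg = gg))
  seglen_means <- aggregate_segments(
    merge(merge(sl_mean, sl_sd), sl_n),
    grouping = c("version", "instruction"))

  matching <- mixed_anova(sc, "score", within = c("version", "model"),
                          between = "instruction", gg = gg)
  three_way <- matching[matching$effect == "version:model:instruction", ]
  gate_open <- nrow(three_way) == 1 && three_way$p < alpha

  per_model <- NULL
  followups <- NULL
  if (gate_open) {
    per_model <- do.call(rbind, lapply(unique(sc$model), function(m) {
      tab <- as.data.frame(mixed_anova(sc[sc$model == m, ], "score",
                                       within = "version",
                                       between = "instruction", gg = gg))
      cbind(data.frame(model = rep(m, nrow(tab))), tab)
    }))
    followups <- do.call(rbind, lapply(unique(sc$model), function(m) {
      do.call(rbind, lapply(unique(sc$instruction), function(ins) {
        g <- sc[sc$model == m & sc$instruction == ins, ]
        wide <- stats::reshape(g[c("participant_id", "version", "score")],
                               idvar = "participant_id", timevar = "version",
                               direction = "wide")
        tt <- paired_t(wide$score.natural, wide$score.delexicalized)
        data.frame(model = m, instruction = ins, t = tt$statistic,
                   df = tt$df, p = tt$p, cohen_d = tt$effect_size)
      }))
    }))
    if (holm) followups$p_holm <- stats::p.adjust(followups$p, "holm")
  }

  conf_tab <- NULL
  if (!is.null(confidence)) {
    conf_tab <- mixed_anova(confidence, "rating", within = "version",
                            between = "instruction", gg = gg)
  }
  structure(list(seglen = seglen_tables, seglen_means = seglen_means,
                 matching = matching, gate_open = gate_open,
                 per_model = per_model, followups = followups,
                 confidence = conf_tab, alpha = alpha),
            class = "phraseseg_results")
}

#' @export
print.phraseseg_results <- function(x, ...) {
  cat("== Segment length (2x2 mixed ANOVA, mean length) ==\n")
  print(x$seglen$mean_len_ms)
  cat("\n== Segment length variability (SD) ==\n")
  print(x$seglen$sd_len_ms)
  cat("\n== Model matching (2x2x7 mixed ANOVA) ==\n")
  print(x$matching)
  if (isTRUE(x$gate_open)) {
    cat(sprintf("\nThree-way interaction significant at alpha = %.3g;\nper-model version x instruction interactions:\n", x$alpha))
    pm <- x$per_model[x$per_model$effect == "version:instruction", ]
    print(structure(pm, class = c("anova_table", class(pm))))
  } else {
    cat(sprintf("\nThree-way interaction not significant at alpha = %.3g; no per-model breakdown.\n",
                x$alpha))
  }
  if (!is.null(x$confidence)) {
    cat("\n== Confidence ratings ==\n")
    print(x$confidence)
  }
  invisible(x)
}

#' Render a results bundle as a markdown report
#'
#' @param results A `phraseseg_results` from [analyze_experiment()].
#' @param path Optional output path; when NULL the lines are returned.
#' @return Character vector of markdown lines (invisibly when written).
#' @export
report_markdown <- function(results, path = NULL) {
  fmt_tab <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) signif(v, 4))
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
    c(header, sep, body)
  }
  lines <- c("# Segmentation analysis report", "",
             "## Segment length", "",
             "### Mean segment length (ms)", fmt_tab(results$seglen$mean_len_ms), "",
             "### Segment length SD (ms)", fmt_tab(results$seglen$sd_len_ms), "",
             "### Condition means", fmt_tab(results$seglen_means), "",
             "## Model matching scores", fmt_tab(results$matching), "")
  if (isTRUE(results$gate_open)) {
    pm <- results$per_model[results$per_model$effect == "version:instruction", ]
    lines <- c(lines, "### Per-model version x instruction interactions",
               fmt_tab(pm), "",
               "### Follow-up paired t-tests (delexicalization effect per group)",
               fmt_tab(results$followups), "")
  } else {
    lines <- c(lines, sprintf(
      "Three-way interaction not significant at alpha = %.3g; no per-model breakdown.",
      results$alpha), "")
  }
  if (!is.null(results$confidence)) {
    lines <- c(lines, "## Confidence ratings", fmt_tab(results$confidence), "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
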