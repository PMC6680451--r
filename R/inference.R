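#' Mixed within/between ANOVA for balanced designs
#'
#' Classical univariate mixed-model ANOVA for one between-subjects factor
#' (optional) and one or two within-subjects factors, one observation per
#' subject x within-cell (average over stimuli before calling if needed).
#' Each within effect (and its interaction with the between factor) is
#' tested against the corresponding within-factor x subjects-within-groups
#' error; the between effect against subjects within groups. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error_for_that_effect)`.
#'
#' Degrees of freedom are uncorrected by default; `gg = TRUE` applies the
#' Greenhouse-Geisser sphericity correction to within effects with more
#' than 1 numerator df.
#'
#' @param data Long-format data.frame.
#' @param dv Name of the numeric response column.
#' @param within Character vector (length 1 or 2) of within-subject factor
#'   columns.
#' @param between Optional name of the between-subjects factor column.
#' @param subject Name of the subject identifier column.
#' @param gg Apply Greenhouse-Geisser correction to within effects?
#' @return data.frame with one row per effect: `effect`, `df_num`,
#'   `df_den`, `ss`, `ss_error`, `F`, `p`, `partial_eta_sq` (plus `gg_eps`
#'   when `gg = TRUE`). The attribute `ss_total` carries the total sum of
#'   squares, and `ss_components` the full decomposition (effects, error
#'   strata and subject stratum), which sums to `ss_total`.
#' @export
mixed_anova <- function(data, dv, within, between = NULL,
                        subject = "participant_id", gg = FALSE) {
  cols <- c(dv, within, between, subject)
  bad <- setdiff(cols, names(data))
  if (length(bad)) stop("column(s) not in data: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (length(within) < 1 || length(within) > 2) {
    stop("mixed_anova supports 1 or 2 within-subject factors", call. = FALSE)
  }
  y <- data[[dv]]
  if (any(is.na(y))) stop("missing values in the response", call. = FALSE)
  subj <- factor(data[[subject]])
  wf <- lapply(data[within], factor)
  bf <- if (!is.null(between)) factor(data[[between]]) else NULL

  # -- design validation: complete, balanced, one obs per cell ------------
  wcomb <- interaction(wf, drop = FALSE)
  tab <- table(subj, wcomb)
  if (any(tab != 1)) {
    stop("design error: every subject must contribute exactly one observation ",
         "per within-factor cell", call. = FALSE)
  }
  if (!is.null(bf)) {
    sb <- table(subj, bf) > 0
    if (any(rowSums(sb) != 1)) {
      stop("design error: each subject must belong to exactly one between group",
           call. = FALSE)
    }
    gsize <- tapply(as.character(subj), as.character(bf), function(s) length(unique(s)))
    if (length(unique(gsize)) != 1) {
      stop("design error: between groups must have equal size", call. = FALSE)
    }
    if (any(gsize < 2)) stop("design error: need at least 2 subjects per group",
                             call. = FALSE)
  } else if (nlevels(subj) < 2) {
    stop("design error: need at least 2 subjects", call. = FALSE)
  }

  N <- length(y)
  CT <- sum(y)^2 / N
  # R(T): sum over T-cells of (cell total)^2 / (obs per cell); balanced.
  Rfun <- function(fac_list) {
    if (!length(fac_list)) return(CT)
    g <- interaction(fac_list, drop = TRUE)
    tot <- tapply(y, g, sum)
    cnt <- tapply(y, g, length)
    sum(tot^2 / cnt)
  }
  w_named <- stats::setNames(wf, within)
  mobius_ss <- function(Tnames) {  # crossed factors only
    k <- length(Tnames)
    ss <- 0
    for (i in 0:(2^k - 1)) {
      U <- Tnames[bitwAnd(i, 2^(seq_len(k) - 1)) > 0]
      facs <- c(w_named[intersect(U, within)],
                if (!is.null(between) && between %in% U) list(bf))
      ss <- ss + (-1)^(k - length(U)) * Rfun(facs)
    }
    ss
  }
  err_ss <- function(V) {  # V x subjects-within-groups
    k <- length(V)
    ss <- 0
    for (i in 0:(2^k - 1)) {
      U <- V[bitwAnd(i, 2^(seq_len(k) - 1)) > 0]
      facs <- w_named[U]
      ss <- ss + (-1)^(k - length(U)) *
        (Rfun(c(facs, list(subj))) - Rfun(c(facs, if (is.null(bf)) NULL else list(bf))))
    }
    ss
  }
  lev <- vapply(wf, nlevels, 0L)
  names(lev) <- within
  n_subj <- nlevels(subj)
  b <- if (is.null(bf)) 1L else nlevels(bf)
  df_subj <- n_subj - b
  ss_subj <- Rfun(list(subj)) - (if (is.null(bf)) CT else Rfun(list(bf)))

  rows <- list()
  components <- c("subjects" = ss_subj)
  add_row <- function(effect, ss, df_num, ss_err, df_den, eps = 1) {
    Fv <- (ss / df_num) / (ss_err / df_den)
    p <- stats::pf(Fv, eps * df_num, eps * df_den, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, df_num = df_num, df_den = df_den,
      ss = ss, ss_error = ss_err, F = Fv, p = p,
      partial_eta_sq = ss / (ss + ss_err),
      gg_eps = eps)
  }
  if (!is.null(bf)) {
    ss_b <- mobius_ss(between)
    add_row(between, ss_b, b - 1L, ss_subj, df_subj)
    components[between] <- ss_b
  }
  subsets <- if (length(within) == 1) list(within) else
    list(within[1], within[2], within)
  for (V in subsets) {
    dfV <- prod(lev[V] - 1L)
    ssE <- err_ss(V)
    dfE <- dfV * df_subj
    eps <- if (gg && dfV > 1) gg_epsilon(y, subj, wf, within, V) else 1
    ssV <- mobius_ss(V)
    add_row(paste(V, collapse = ":"), ssV, dfV, ssE, dfE, eps)
    components[paste(V, collapse = ":")] <- ssV
    if (!is.null(bf)) {
      ssVB <- mobius_ss(c(V, between))
      add_row(paste(c(V, between), collapse = ":"), ssVB, dfV * (b - 1L), ssE, dfE, eps)
      components[paste(c(V, between), collapse = ":")] <- ssVB
    }
    components[paste(c(V, "error"), collapse = ":")] <- ssE
  }
  out <- do.call(rbind, rows)
  if (!gg) out$gg_eps <- NULL
  rownames(out) <- NULL
  attr(out, "ss_total") <- sum((y - mean(y))^2)
  attr(out, "ss_components") <- components
  class(out) <- c("anova_table", class(out))
  out
}

# Greenhouse-Geisser epsilon for the within-effect V: orthonormal contrasts
# of the effect applied to the subject x cell matrix.
gg_epsilon <- function(y, subj, wf, within, V) {
  cells <- interaction(rev(wf[V]), drop = FALSE)  # rev: first factor fastest
  m <- tapply(y, list(subj, cells), mean)
  contr_for <- function(k) {
    C <- stats::contr.helmert(k)
    sweep(C, 2, sqrt(colSums(C^2)), "/")
  }
  lev <- vapply(wf[V], nlevels, 0L)
  M <- if (length(V) == 2) kronecker(contr_for(lev[2]), contr_for(lev[1]))
       else contr_for(lev[1])
  S <- stats::cov(m %*% M)
  d <- nrow(S)
  min(1, sum(diag(S))^2 / (d * sum(S^2)))
}

#' @export
print.anova_table <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

t_result <- function(statistic, df, p, effect_size, degenerate = FALSE,
                     method = "t") {
  structure(list(statistic = statistic, df = df, p = p,
                 effect_size = effect_size, degenerate = degenerate,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s = %.4g%s, p = %.4g, effect size = %.4g%s\n",
              x$method, x$statistic,
              if (!is.null(x$df) && !is.na(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$p, x$effect_size,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Paired t-test with Cohen's d
#'
#' `d = mean(x - y) / sd(x - y)`. Two-sided p. A zero-variance difference
#' is flagged degenerate (t = 0, d = 0, p = 1 when the mean difference is
#' also zero).
#'
#' @param x,y Paired numeric vectors, `n >= 2`.
#' @return A `test_result` list: `statistic`, `df`, `p`, `effect_size`,
#'   `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("paired_t needs two vectors of equal length >= 2", call. = FALSE)
  }
  d <- x - y
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) return(t_result(0, n - 1, 1, 0, degenerate = TRUE))
    sgn <- sign(mean(d))
    return(t_result(sgn * Inf, n - 1, 0, sgn * Inf, degenerate = TRUE))
  }
  tt <- mean(d) / (sdd / sqrt(n))
  t_result(tt, n - 1, 2 * stats::pt(abs(tt), n - 1, lower.tail = FALSE),
           mean(d) / sdd)
}

#' Independent-samples t-test with Cohen's d
#'
#' Pooled-variance t by default (`d = (mA - mB) / s_pooled`); Welch when
#' `pooled = FALSE` (d still uses the pooled SD).
#'
#' @param a,b Numeric vectors, `n >= 2` each.
#' @param pooled Use the pooled-variance statistic?
#' @return A `test_result`.
#' @export
independent_t <- function(a, b, pooled = TRUE) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("need n >= 2 per sample", call. = FALSE)
  summary_t(mean(a), stats::sd(a), na, mean(b), stats::sd(b), nb,
            pooled = pooled)
}

#' Independent-samples t-test from summary statistics
#'
#' Algebraically identical to [independent_t()] on the raw data; useful for
#' reproducing tests from published group means and SDs.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries; SDs `> 0`
#'   (a zero SD gives a degenerate flag), ns `>= 2`.
#' @param pooled Use the pooled-variance statistic?
#' @return A `test_result`.
#' @export
summary_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b, pooled = TRUE) {
  if (n_a < 2 || n_b < 2) stop("need n >= 2 per sample", call. = FALSE)
  if (sd_a < 0 || sd_b < 0) stop("SDs must be non-negative", call. = FALSE)
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  if (sp2 == 0) {
    eq <- mean_a == mean_b
    return(t_result(if (eq) 0 else sign(mean_a - mean_b) * Inf,
                    n_a + n_b - 2, if (eq) 1 else 0,
                    if (eq) 0 else sign(mean_a - mean_b) * Inf,
                    degenerate = TRUE))
  }
  d <- (mean_a - mean_b) / sqrt(sp2)
  if (pooled) {
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  tt <- (mean_a - mean_b) / se
  t_result(tt, df, 2 * stats::pt(abs(tt), df, lower.tail = FALSE), d)
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped; tied absolute differences get averaged
#' ranks. The reported statistic is the smaller of the two signed-rank
#' sums. The two-sided p is exact (by convolution over all sign patterns)
#' for `n <= exact_max` remaining pairs, and uses the tie-corrected normal
#' approximation above that. The effect size is `r = Z / sqrt(n)`.
#'
#' @param x Numeric vector: paired differences, or first members of pairs
#'   when `y` is given.
#' @param y Optional second members of pairs.
#' @param exact_max Largest n for the exact distribution (default 25).
#' @return A `test_result` with fields `statistic` (smaller rank sum), `z`,
#'   `p`, `effect_size`, `method` (`"wilcoxon-exact"` or
#'   `"wilcoxon-normal"`).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  if (!length(d)) stop("need at least one pair", call. = FALSE)
  d <- d[d != 0]
  n_all <- length(d)
  if (!n_all) {
    res <- t_result(NA_real_, NA, 1, 0, degenerate = TRUE, method = "wilcoxon")
    res$z <- 0
    return(res)
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- n_all * (n_all + 1) / 2 - w_plus
  stat <- min(w_plus, w_minus)
  ties <- table(r)
  mu <- n_all * (n_all + 1) / 4
  sig2 <- n_all * (n_all + 1) * (2 * n_all + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- if (sig2 > 0) (w_plus - mu) / sqrt(sig2) else 0
  if (n_all <= exact_max) {
    r2 <- as.integer(round(2 * r))
    f <- c(1, numeric(sum(r2)))          # counts over doubled rank sums
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(length(f) - ri)])
      f <- f + shifted
    }
    f <- f / 2^n_all
    w2 <- as.integer(round(2 * w_plus))
    p_lo <- sum(f[seq_len(w2 + 1L)])
    p_hi <- sum(f[(w2 + 1L):length(f)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "wilcoxon-exact"
  } else {
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    method <- "wilcoxon-normal"
  }
  res <- t_result(stat, NA, p, z / sqrt(n_all), method = method)
  res$z <- z
  res
}
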