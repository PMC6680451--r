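make_mixed_data <- function(n_per_group, within_levels, seed,
                            interaction = 0) {
  set.seed(seed)
  subj <- sprintf("p%03d", seq_len(2 * n_per_group))
  d <- expand.grid(participant_id = subj, stringsAsFactors = FALSE)
  d <- merge(d, do.call(expand.grid, c(within_levels, stringsAsFactors = FALSE)))
  d$instruction <- ifelse(match(d$participant_id, subj) <= n_per_group, "g1", "g2")
  d$y <- rnorm(nrow(d)) + rnorm(2 * n_per_group)[match(d$participant_id, subj)]
  if (interaction != 0) {
    sgn <- ifelse(d$instruction == "g1", 1, -1) *
      ifelse(d[[names(within_levels)[1]]] == within_levels[[1]][1], 1, -1)
    d$y <- d$y + interaction / 4 * sgn
  }
  d
}

aov_oracle <- function(d, dv, within, between) {
  f <- stats::as.formula(paste(
    dv, "~", paste(c(between, within), collapse = "*"),
    "+ Error(participant_id/(", paste(within, collapse = "*"), "))"))
  fit <- summary(stats::aov(f, data = d))
  out <- list()
  for (stratum in fit) {
    tab <- stratum[[1]]
    for (i in seq_len(nrow(tab))) {
      nm <- trimws(rownames(tab)[i])
      if (nm == "Residuals") next
      out[[nm]] <- c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
                     df1 = tab[i, "Df"], ss = tab[i, "Sum Sq"])
    }
  }
  out
}

norm_effect <- function(e) paste(sort(strsplit(e, ":")[[1]]), collapse = ":")

test_that("mixed_anova agrees with the aov decomposition (2x2)", {
  for (seed in c(1, 2, 3)) {
    d <- make_mixed_data(8, list(version = c("nat", "del")), seed)
    mine <- mixed_anova(d, "y", within = "version", between = "instruction")
    oracle <- aov_oracle(d, "y", "version", "instruction")
    for (i in seq_len(nrow(mine))) {
      key <- names(oracle)[vapply(names(oracle), norm_effect, "") ==
                             norm_effect(mine$effect[i])]
      expect_equal(unname(mine$F[i]), unname(oracle[[key]]["F"]), tolerance = 1e-10)
      expect_equal(unname(mine$p[i]), unname(oracle[[key]]["p"]), tolerance = 1e-10)
      expect_equal(unname(mine$ss[i]), unname(oracle[[key]]["ss"]), tolerance = 1e-10)
    }
  }
})

test_that("mixed_anova agrees with the aov decomposition (2x2x7)", {
  d <- make_mixed_data(6, list(version = c("nat", "del"),
                               model = paste0("m", 1:7)), 42)
  mine <- mixed_anova(d, "y", within = c("version", "model"),
                      between = "instruction")
  oracle <- aov_oracle(d, "y", c("version", "model"), "instruction")
  expect_equal(nrow(mine), 7)
  expect_equal(mine$df_num[mine$effect == "version:model:instruction"], 6)
  expect_equal(mine$df_den[mine$effect == "version:model:instruction"],
               6 * (12 - 2))
  for (i in seq_len(nrow(mine))) {
    key <- names(oracle)[vapply(names(oracle), norm_effect, "") ==
                           norm_effect(mine$effect[i])]
    expect_equal(unname(mine$F[i]), unname(oracle[[key]]["F"]), tolerance = 1e-10)
    expect_equal(unname(mine$p[i]), unname(oracle[[key]]["p"]), tolerance = 1e-10)
  }
})

test_that("a hand-computed small 2x2 fixture reproduces the SS decomposition", {
  # 3 subjects per group, within factor with cell means written out
  d <- data.frame(
    participant_id = rep(c("a", "b", "c", "d", "e", "f"), each = 2),
    version = rep(c("v1", "v2"), 6),
    instruction = rep(c("g1", "g2"), each = 6),
    y = c(10, 12, 11, 15, 9, 12, 14, 13, 15, 15, 16, 14))
  tab <- mixed_anova(d, "y", within = "version", between = "instruction")
  # brute-force: subject means, cell means, grand mean
  sm <- tapply(d$y, d$participant_id, mean)
  gm <- mean(d$y)
  grp_of <- tapply(d$instruction, d$participant_id, function(x) x[1])
  grp_mean <- tapply(d$y, d$instruction, mean)
  ss_b <- 6 * sum((grp_mean - gm)^2)   # 6 observations per group
  ss_subj <- 2 * sum((sm - grp_mean[as.character(grp_of)])^2)
  cell_mean <- tapply(d$y, list(d$instruction, d$version), mean)
  ver_mean <- tapply(d$y, d$version, mean)
  ss_v <- 6 * sum((ver_mean - gm)^2)
  ss_vb <- 3 * sum((cell_mean - outer(grp_mean, ver_mean, "+") + gm)^2)
  ss_tot <- sum((d$y - gm)^2)
  ss_err_w <- ss_tot - ss_b - ss_subj - ss_v - ss_vb
  expect_equal(tab$ss[tab$effect == "instruction"], unname(ss_b))
  expect_equal(tab$ss[tab$effect == "version"], unname(ss_v))
  expect_equal(tab$ss[tab$effect == "version:instruction"], unname(ss_vb))
  expect_equal(tab$ss_error[tab$effect == "version"], unname(ss_err_w))
  expect_equal(tab$F[tab$effect == "instruction"],
               unname((ss_b / 1) / (ss_subj / 4)))
})

test_that("exactly additive cell means carry no interaction sum of squares", {
  d <- expand.grid(participant_id = sprintf("p%d", 1:6),
                   version = c("v1", "v2"), stringsAsFactors = FALSE)
  d$instruction <- ifelse(d$participant_id %in% sprintf("p%d", 1:3), "g1", "g2")
  d$y <- 10 + (d$version == "v2") * 2 + (d$instruction == "g2") * 5 +
    c(0.1, 0.2, -0.3)[as.integer(sub("p", "", d$participant_id)) %% 3 + 1]
  tab <- mixed_anova(d, "y", within = "version", between = "instruction")
  expect_equal(tab$ss[tab$effect == "version:instruction"], 0, tolerance = 1e-12)
})

test_that("ANOVA sums of squares decompose the total; eta reproduces F", {
  d <- make_mixed_data(5, list(version = c("v1", "v2"), model = c("a", "b", "c")), 7)
  tab <- mixed_anova(d, "y", within = c("version", "model"), between = "instruction")
  comp <- attr(tab, "ss_components")
  expect_equal(sum(comp), attr(tab, "ss_total"), tolerance = 1e-10)
  # algebraic identity F = pes/(1-pes) * df_den/df_num
  expect_equal(tab$F,
               tab$partial_eta_sq / (1 - tab$partial_eta_sq) *
                 tab$df_den / tab$df_num,
               tolerance = 1e-10)
})

test_that("mixed_anova rejects broken designs explicitly", {
  d <- make_mixed_data(4, list(version = c("v1", "v2")), 1)
  expect_error(mixed_anova(d[-1, ], "y", "version", "instruction"),
               "design error")
  d2 <- d[d$participant_id != "p001", ]
  expect_error(mixed_anova(d2, "y", "version", "instruction"),
               "equal size")
  d3 <- d[d$participant_id %in% c("p001", "p005"), ]
  expect_error(mixed_anova(d3, "y", "version", "instruction"),
               "at least 2")
})

test_that("Greenhouse-Geisser correction rescales the within df", {
  d <- make_mixed_data(8, list(model = paste0("m", 1:4)), 3)
  tab <- mixed_anova(d, "y", within = "model", between = "instruction", gg = TRUE)
  raw <- mixed_anova(d, "y", within = "model", between = "instruction")
  eps <- tab$gg_eps[tab$effect == "model"]
  expect_gt(eps, 1 / 3 - 1e-9)  # lower bound 1/(k-1)
  expect_lte(eps, 1 + 1e-9)
  i <- which(tab$effect == "model")
  expect_equal(tab$F[i], raw$F[i])  # the statistic itself is unchanged
  expect_equal(tab$p[i],
               pf(tab$F[i], eps * tab$df_num[i], eps * tab$df_den[i],
                  lower.tail = FALSE), tolerance = 1e-12)
  # a 2-level factor (1 df) is never corrected
  tab2 <- mixed_anova(d[d$model %in% c("m1", "m2"), ], "y",
                      within = "model", between = "instruction", gg = TRUE)
  expect_equal(tab2$gg_eps[tab2$effect == "model"], 1)
})

test_that("t-tests match the reference implementation to 1e-10", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    mine <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    a <- rnorm(10); b <- rnorm(14, 0.4)
    mine2 <- independent_t(a, b)
    ref2 <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine2$statistic, unname(ref2$statistic), tolerance = 1e-10)
    expect_equal(mine2$p, ref2$p.value, tolerance = 1e-10)
    mine3 <- independent_t(a, b, pooled = FALSE)
    ref3 <- t.test(a, b)
    expect_equal(mine3$statistic, unname(ref3$statistic), tolerance = 1e-10)
    expect_equal(mine3$df, unname(ref3$parameter), tolerance = 1e-10)
  }
})

test_that("summary_t is exactly the raw-data pooled t and antisymmetric", {
  set.seed(8)
  a <- rnorm(9, 20, 3); b <- rnorm(11, 19, 2)
  raw <- independent_t(a, b)
  summ <- summary_t(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
  expect_equal(summ$statistic, raw$statistic, tolerance = 1e-12)
  expect_equal(summ$effect_size, raw$effect_size, tolerance = 1e-12)
  swapped <- summary_t(mean(b), sd(b), length(b), mean(a), sd(a), length(a))
  expect_equal(swapped$statistic, -summ$statistic, tolerance = 1e-12)
  expect_error(summary_t(1, 1, 1, 1, 1, 5), "n >= 2")
})

test_that("identical samples give the degenerate zero result", {
  x <- c(1, 2, 3, 4)
  r <- paired_t(x, x)
  expect_true(r$degenerate)
  expect_equal(r$statistic, 0)
  expect_equal(r$effect_size, 0)
  expect_equal(r$p, 1)
})

test_that("wilcoxon signed-rank handles the stated examples", {
  all_pos <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(all_pos$statistic, 0)
  expect_equal(all_pos$p, 0.0625)          # 2 / 2^5
  one <- wilcoxon_signed_rank(3)
  expect_equal(one$p, 1)
  zero <- wilcoxon_signed_rank(c(0, 0))
  expect_true(zero$degenerate)
})

test_that("wilcoxon exact p matches full sign-pattern enumeration (n <= 10)", {
  enum_oracle <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    ws <- vapply(0:(2^n - 1), function(mask) {
      sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
    }, 0)
    min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
  }
  set.seed(11)
  for (i in 1:15) {
    n <- sample(3:10, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # ties guaranteed possible
    mine <- wilcoxon_signed_rank(d)
    expect_equal(mine$p, enum_oracle(d), tolerance = 1e-12)
  }
  # and against stats::wilcox.test when there are no ties
  d <- c(1.2, -0.7, 2.5, 3.1, -1.8, 0.4, 2.2)
  expect_equal(wilcoxon_signed_rank(d)$p,
               wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("large-sample wilcoxon uses the tie-corrected normal approximation", {
  set.seed(3)
  d <- sample(c(-5:-1, 1:6), 40, replace = TRUE)
  mine <- wilcoxon_signed_rank(d)
  ref <- wilcox.test(d, exact = FALSE, correct = FALSE)
  expect_equal(mine$method, "wilcoxon-normal")
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})
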