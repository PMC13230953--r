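# Inference chain: mixed ANOVA, t tests, JZS Bayes factors, Raftery bins.

test_that("mixed ANOVA matches a brute-force cell-means decomposition", {
  set.seed(11)
  for (rep in 1:5) {
    s <- data.frame(
      participant_id = sprintf("P%02d", 1:6),
      group = rep(c("low", "high"), each = 3),
      pc_r = round(runif(6), 3),
      pc_t = round(runif(6), 3)
    )
    got <- mixed_anova_2x2(s, measures = c("pc_r", "pc_t"))
    want <- oracle_mixed_anova(s, measures = c("pc_r", "pc_t"))
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df1, rep(1, 3))
    expect_equal(got$df2, rep(4, 3))
  }
})

test_that("null effects produce zero (or undefined) F statistics", {
  # groups identical by construction: between main effect vanishes
  base <- data.frame(
    participant_id = sprintf("P%02d", 1:4),
    group = "low",
    pc_r = c(0.2, 0.4, 0.6, 0.8),
    pc_t = c(0.3, 0.5, 0.8, 0.9)
  )
  dup <- transform(base, participant_id = paste0(participant_id, "b"),
                   group = "high")
  a <- mixed_anova_2x2(rbind(base, dup))
  expect_equal(a$statistic[a$effect == "group"], 0, tolerance = 1e-12)
  expect_equal(a$statistic[a$effect == "group:measure"], 0,
               tolerance = 1e-12)

  # within measures identical for every participant: zero numerator
  same <- rbind(base, dup)
  same$pc_t <- same$pc_r
  b <- mixed_anova_2x2(same)
  f_meas <- b$statistic[b$effect == "measure"]
  expect_true(is.nan(f_meas) || f_meas == 0)
})

test_that("ANOVA rejects malformed designs", {
  s <- make_summaries(c(0.2, 0.4), c(0.3, 0.5))
  expect_error(mixed_anova_2x2(s), "two groups")
  s2 <- make_summaries(c(0.2, 0.4), c(0.3, 0.5), group = c("low", "high"))
  s2$pc_t[1] <- NA
  expect_error(mixed_anova_2x2(s2), "NA|missing")
  expect_error(mixed_anova_2x2(make_summaries(0.1, 0.1), measures = "pc_r"),
               "two columns")
})

test_that("paired t equals the one-sample t on difference scores", {
  set.seed(21)
  a <- runif(30)
  b <- a + rnorm(30, 0.05, 0.1)
  got <- t_test_bf(a, b, paired = TRUE)
  want <- t.test(a - b)
  expect_equal(got$statistic, unname(want$statistic))
  expect_equal(got$df, unname(want$parameter))
  expect_equal(got$p_value, want$p.value)
})

test_that("identical paired samples give t = 0 and p = 1 with null-leaning BF", {
  a <- c(0.2, 0.4, 0.6, 0.9)
  got <- t_test_bf(a, a + c(0.1, -0.1, 0.1, -0.1), paired = TRUE)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
  expect_lt(got$bf10, 1)
})

test_that("zero-variance inputs raise an informative error", {
  expect_error(t_test_bf(c(0, 0, 0, 0), c(1, 1, 1, 1)), "zero-variance")
  expect_error(t_test_bf(c(1, 2, 3), c(1.1, 2.1, 3.1), paired = TRUE),
               "zero-variance")
  expect_error(t_test_bf(0.5, 0.7), "at least 2")
})

test_that("JZS Bayes factors agree with the Cauchy-prior marginal oracle", {
  cases <- list(
    list(t = 0, n1 = 50, n2 = NULL),
    list(t = 2.5, n1 = 30, n2 = NULL),
    list(t = -4.74, n1 = 113, n2 = NULL),
    list(t = 1.42, n1 = 118, n2 = NULL),
    list(t = 3.1, n1 = 40, n2 = 35)
  )
  for (cs in cases) {
    got <- jzs_bf_t(cs$t, cs$n1, cs$n2)
    want <- oracle_jzs(cs$t, cs$n1, cs$n2)
    expect_equal(got, want, tolerance = 1e-5,
                 label = sprintf("jzs(t=%g, n1=%d)", cs$t, cs$n1))
  }
})

test_that("JZS BF10 favours the null at t = 0 and increases in |t|", {
  expect_lt(jzs_bf_t(0, 40), 1)
  ts <- seq(0, 6, by = 0.5)
  bfs <- vapply(ts, jzs_bf_t, numeric(1), n1 = 40)
  expect_true(all(diff(bfs) > 0))
  # two-sided: sign of t is irrelevant
  expect_equal(jzs_bf_t(-2.2, 25), jzs_bf_t(2.2, 25))
  expect_error(jzs_bf_t(Inf, 20), "finite")
})

test_that("Raftery bins are half-open and closed on the left", {
  expect_equal(raftery_label(1), "weak")
  expect_equal(raftery_label(2.99), "weak")
  expect_equal(raftery_label(3), "positive")
  expect_equal(raftery_label(6.86), "positive")
  expect_equal(raftery_label(19.99), "positive")
  expect_equal(raftery_label(20), "strong")
  expect_equal(raftery_label(149.9), "strong")
  expect_equal(raftery_label(150), "very strong")
  expect_equal(raftery_label(204.9), "very strong")
  expect_error(raftery_label(0.5), "max\\(BF10, BF01\\)")
})

test_that("t-test results carry consistent evidence labels", {
  set.seed(31)
  a <- rnorm(40, 0.5, 0.1)
  b <- rnorm(40, 0.8, 0.1)
  got <- t_test_bf(a, b)
  expect_equal(got$bf01, 1 / got$bf10)
  expect_equal(got$evidence, raftery_label(max(got$bf10, got$bf01)))
})
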