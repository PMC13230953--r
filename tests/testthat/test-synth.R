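# Synthetic cohort generator: structure, determinism and statistical
# calibration against the generating model.

test_that("cohort tables have the declared shape", {
  cfg <- cohort_config(n_low = 2, n_high = 2, items_per_condition = 40,
                       seed = 1)
  tr <- generate_cohort(cfg)
  expect_equal(nrow(tr), 2 * 2 * 2 * 40)
  expect_setequal(names(tr),
                  c("participant_id", "group", "condition", "item_id",
                    "correct"))
  counts <- table(tr$participant_id, tr$condition)
  expect_true(all(counts == 40))
  expect_true(all(tr$correct %in% c(0L, 1L)))
  # each participant sits in exactly one group
  ngrp <- tapply(tr$group, tr$participant_id,
                 function(g) length(unique(g)))
  expect_true(all(ngrp == 1L))
})

test_that("identical seeds regenerate the identical table", {
  cfg <- cohort_config(n_low = 5, n_high = 5, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_low = 5, n_high = 5, seed = 100)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("degenerate ability laws hit the floor and ceiling exactly", {
  floor_cfg <- cohort_config(n_low = 3, n_high = 3, items_per_condition = 10,
                             ability_mean_low = 0, ability_mean_high = 0,
                             seed = 1)
  expect_true(all(generate_cohort(floor_cfg)$correct == 0L))
  ceil_cfg <- cohort_config(n_low = 3, n_high = 3, items_per_condition = 10,
                            ability_mean_low = 1, ability_mean_high = 1,
                            seed = 1)
  expect_true(all(generate_cohort(ceil_cfg)$correct == 1L))
})

test_that("under independence the mean test accuracy matches the inclusive-or", {
  # degenerate law at p = 0.5, rho = 0: expected pc_t = 0.75; binomial
  # standard error of the 500-participant x 40-item mean
  cfg <- cohort_config(n_low = 250, n_high = 250, items_per_condition = 40,
                       ability_mean_low = 0.5, ability_mean_high = 0.5,
                       ability_concentration = Inf, rho_low = 0, rho_high = 0,
                       seed = 21)
  s <- summarize_participants(generate_cohort(cfg))
  se <- sqrt(0.75 * 0.25 / (40 * 500))
  expect_lt(abs(mean(s$pc_t) - 0.75), 3 * se)
})

test_that("participant summaries recover proportions and predictions", {
  tr <- data.frame(
    participant_id = rep("P001", 8),
    group = "high",
    condition = rep(c("restudy", "test"), each = 4),
    item_id = c(paste0("r", 1:4), paste0("t", 1:4)),
    correct = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)
  )
  s <- summarize_participants(tr)
  expect_equal(s$pc_r, 1)
  expect_equal(s$pc_t, 1)
  expect_equal(s$pc_t_pred, 1)

  tr$correct <- c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L)
  s <- summarize_participants(tr)
  expect_equal(s$pc_r, 0.5)
  expect_equal(s$pc_t, 0.25)
  expect_equal(s$pc_t_pred, 0.75)

  # 12/40 restudy correct -> pc_r 0.3, predicted 0.51
  tr2 <- data.frame(
    participant_id = "P002",
    group = "low",
    condition = rep(c("restudy", "test"), each = 40),
    item_id = c(sprintf("r%02d", 1:40), sprintf("t%02d", 1:40)),
    correct = c(rep(1L, 12), rep(0L, 28), rep(1L, 20), rep(0L, 20))
  )
  s2 <- summarize_participants(tr2)
  expect_equal(s2$pc_r, 0.3)
  expect_equal(s2$pc_t_pred, 0.51)
})

test_that("a participant missing a condition stratum is reported by name", {
  tr <- data.frame(
    participant_id = c(rep("P001", 4), rep("P002", 2)),
    group = "low",
    condition = c(rep(c("restudy", "test"), each = 2), "restudy", "restudy"),
    item_id = c("r1", "r2", "t1", "t2", "r1", "r2"),
    correct = 1L
  )
  expect_error(summarize_participants(tr), "P002")
})

test_that("observed pc_r sits in the binomial interval around the ability", {
  # degenerate laws give known per-participant abilities; the central 99%
  # binomial interval should cover at least 98% of participants
  cfg <- cohort_config(n_low = 250, n_high = 250, items_per_condition = 40,
                       ability_mean_low = 0.3, ability_mean_high = 0.47,
                       ability_concentration = Inf, seed = 13)
  s <- summarize_participants(generate_cohort(cfg))
  p_true <- ifelse(s$group == "low", 0.3, 0.47)
  lo <- qbinom(0.005, 40, p_true) / 40
  hi <- qbinom(0.995, 40, p_true) / 40
  expect_gte(mean(s$pc_r >= lo & s$pc_r <= hi), 0.98)
})

test_that("group mean restudy accuracy converges to the ability-law mean", {
  cfg <- cohort_config(n_low = 2000, n_high = 2000, seed = 17)
  s <- summarize_participants(generate_cohort(cfg))
  expect_lt(abs(mean(s$pc_r[s$group == "low"]) - 0.30), 0.01)
  expect_lt(abs(mean(s$pc_r[s$group == "high"]) - 0.47), 0.01)
})

test_that("positive strength correlation shrinks the testing effect", {
  cfg <- cohort_config(seed = 31)  # defaults: rho 0 low, 0.334 high
  s <- summarize_participants(generate_cohort(cfg))
  high <- s[s$group == "high", ]
  expect_lt(mean(high$pc_t - high$pc_r), mean(predict_te(high$pc_r)))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_low = 0), "positive")
  expect_error(cohort_config(items_per_condition = 2.5), "positive")
  expect_error(cohort_config(ability_mean_high = 1.2), "0, 1")
  expect_error(cohort_config(ability_concentration = -1), "positive")
  expect_error(cohort_config(rho_high = 2), "rho")
  expect_error(generate_cohort(list(n_low = 3)), "cohort_config")
})
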