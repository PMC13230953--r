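# rho estimation, efficacy reduction, and the dualmem model object.

test_that("fit_rho recovers an exactly self-consistent rho", {
  set.seed(2)
  pc_r <- runif(80, 0.1, 0.9)
  s <- make_summaries(pc_r, pt_correlated(pc_r, 0.3))
  fit <- fit_rho(s)
  expect_s3_class(fit, "dmm_rho_fit")
  expect_equal(fit$rho_hat, 0.3, tolerance = 1e-3)
  expect_equal(fit$boundary, "none")
  expect_true(fit$converged)
})

test_that("fit_rho pins the boundaries when the mean cannot be matched", {
  set.seed(3)
  pc_r <- runif(50, 0.2, 0.8)
  # observed above the independence prediction: no positive rho helps
  hi <- make_summaries(pc_r, pmin(predict_pt(pc_r) + 0.05, 1))
  fit_hi <- fit_rho(hi)
  expect_equal(fit_hi$rho_hat, 0)
  expect_equal(fit_hi$boundary, "lower")
  # observed below the single-route prediction
  lo <- make_summaries(pc_r, pmax(pc_r - 0.05, 0))
  fit_lo <- fit_rho(lo)
  expect_equal(fit_lo$rho_hat, 1)
  expect_equal(fit_lo$boundary, "upper")
})

test_that("the traced objective is minimised at the estimate", {
  set.seed(4)
  pc_r <- runif(60, 0.1, 0.9)
  s <- make_summaries(pc_r, pt_correlated(pc_r, 0.45))
  fit <- fit_rho(s)
  expect_true(all(fit$objective <= fit$search_trace$objective + 1e-12))
  # interior solutions match the mean to within the trial quantisation floor
  expect_lte(fit$objective, 1 / (2 * nrow(s) * 40))
})

test_that("fit_rho is invariant to participant order and cohort duplication", {
  set.seed(7)
  pc_r <- round(runif(40, 0.1, 0.9), 2)
  pc_t <- round(pmin(pt_correlated(pc_r, 0.3) + rnorm(40, 0, 0.05), 1), 2)
  pc_t <- pmax(pc_t, 0)
  s <- make_summaries(pc_r, pc_t)
  fit1 <- fit_rho(s)
  fit2 <- fit_rho(s[rev(seq_len(nrow(s))), ])
  dup <- rbind(s, transform(s, participant_id = paste0(participant_id, "b")))
  fit3 <- fit_rho(dup)
  expect_equal(fit1$rho_hat, fit2$rho_hat)
  expect_equal(fit1$rho_hat, fit3$rho_hat)
})

test_that("degenerate restudy data are rejected", {
  s <- make_summaries(c(0, 1, 0, 1), c(0.2, 0.8, 0.3, 0.9))
  expect_error(fit_rho(s), "not identifiable")
  expect_error(fit_rho(make_summaries(0.5, 0.6)), "at least 2")
})

test_that("parameter recovery is approximately unbiased at study scale", {
  # light version of the full recovery study (which runs at 200 replicates
  # in the acceptance suite)
  rho_hat <- vapply(seq_len(25), function(i) {
    cfg <- cohort_config(n_low = 2, n_high = 113, seed = 500 + i)
    s <- summarize_participants(generate_cohort(cfg))
    fit_rho(s, group = "high")$rho_hat
  }, numeric(1))
  expect_lt(abs(median(rho_hat) - 0.334), 0.08)
})

test_that("efficacy reduction is the relative shortfall of the observed TE", {
  expect_equal(efficacy_reduction(0.185, 0.25), 0.26)
  expect_equal(efficacy_reduction(0.25, 0.25), 0)
  expect_equal(efficacy_reduction(0.30, 0.25), -0.2)
  expect_error(efficacy_reduction(0.1, 0), "positive")
  expect_error(efficacy_reduction(0.1, -0.2), "positive")
})

test_that("dualmem fits both groups and exposes the standard methods", {
  cfg <- cohort_config(n_low = 60, n_high = 60, seed = 12)
  tr <- generate_cohort(cfg)
  fit <- dualmem(tr)
  expect_s3_class(fit, "dualmem")
  expect_setequal(fit$groups, c("low", "high"))
  expect_named(coef(fit), c("low", "high"))
  expect_true(all(coef(fit) >= 0 & coef(fit) <= 1))

  # predictions at the fitted rho pass through the closed form
  expect_equal(predict(fit, newdata = 0.47, group = "high"),
               pt_correlated(0.47, coef(fit)[["high"]]))
  expect_equal(predict(fit, newdata = 0.47, group = "high",
                       model = "independent"), predict_pt(0.47))

  res <- residuals(fit)
  s <- fit$summaries
  expect_equal(unname(res), s$pc_t - unname(fitted(fit)))
  res_ind <- residuals(fit, model = "independent")
  expect_equal(unname(res_ind), s$pc_t - predict_pt(s$pc_r))

  # summary attaches the inference chain
  sm <- summary(fit)
  expect_s3_class(sm$anova_training_task, "dmm_anova")
  expect_named(sm$t_data_type, fit$groups)
  expect_output(print(sm), "Mixed ANOVA")

  # simulate returns trial tables with the fitted structure
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  s1 <- summarize_participants(sims[[1]])
  expect_equal(nrow(s1), nrow(s))
  expect_identical(simulate(fit, nsim = 1, seed = 5),
                   simulate(fit, nsim = 1, seed = 5))
})

test_that("a fixed rho bypasses estimation", {
  cfg <- cohort_config(n_low = 20, n_high = 20, seed = 14)
  fit <- dualmem(generate_cohort(cfg), rho = 0.25)
  expect_equal(unname(coef(fit)), c(0.25, 0.25))
  expect_equal(fit$fits$high$boundary, "fixed")
})
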