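# Independent oracles used to check the package's computational routes.
# Each deliberately uses a different derivation from the implementation it
# validates.

# Bivariate-normal recall probability by direct 2-D quadrature of the
# density over the lower (rejection) quadrant.  Accurate for moderate
# thresholds and correlations; the implementation uses a one-dimensional
# correlation integral instead.
oracle_pt_quad <- function(p, rho) {
  z <- qnorm(1 - p)
  f <- function(x, y) {
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
  }
  1 - pracma::integral2(f, -8.5, z, -8.5, z, reltol = 1e-12)$Q
}

# JZS Bayes factor by marginalising the noncentral-t likelihood over the
# Cauchy effect-size prior directly (the implementation integrates over
# the inverse-gamma mixing variable instead).
oracle_jzs <- function(t, n1, n2 = NULL, r_scale = 0.707) {
  if (is.null(n2)) {
    n_eff <- n1
    nu <- n1 - 1
  } else {
    n_eff <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
  }
  f <- function(d) {
    suppressWarnings(dt(t, nu, ncp = d * sqrt(n_eff))) *
      dcauchy(d, 0, r_scale)
  }
  m1 <- integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
  m1 / dt(t, nu)
}

# Brute-force mixed-design ANOVA from cell means, for balanced two-group
# data with two within-participant measures.
oracle_mixed_anova <- function(summaries, measures) {
  y <- as.matrix(summaries[, measures])
  grp <- summaries$group
  n_tot <- nrow(y)
  stopifnot(length(unique(table(grp))) == 1L)  # balanced only
  G <- mean(y)
  m_subj <- rowMeans(y)
  ss_subj <- 2 * sum((m_subj - G)^2)
  ss_group <- 0
  for (g in unique(grp)) {
    sel <- grp == g
    ss_group <- ss_group + 2 * sum(sel) * (mean(y[sel, ]) - G)^2
  }
  ss_bserr <- ss_subj - ss_group
  ss_meas <- sum(n_tot * (colMeans(y) - G)^2)
  ss_int <- 0
  for (g in unique(grp)) {
    sel <- grp == g
    for (m in seq_along(measures)) {
      ss_int <- ss_int + sum(sel) *
        (mean(y[sel, m]) - mean(y[sel, ]) - mean(y[, m]) + G)^2
    }
  }
  ss_tot <- sum((y - G)^2)
  ss_wserr <- ss_tot - ss_subj - ss_meas - ss_int
  df_err <- n_tot - 2
  data.frame(
    effect = c("group", "measure", "group:measure"),
    statistic = c((ss_group / 1) / (ss_bserr / df_err),
                  (ss_meas / 1) / (ss_wserr / df_err),
                  (ss_int / 1) / (ss_wserr / df_err)),
    stringsAsFactors = FALSE
  )
}

# Convenience: build a summary table directly from proportions.
make_summaries <- function(pc_r, pc_t, group = "high") {
  data.frame(
    participant_id = sprintf("P%03d", seq_along(pc_r)),
    group = rep_len(group, length(pc_r)),
    pc_r = pc_r,
    pc_t = pc_t,
    pc_t_pred = predict_pt(pc_r),
    n_r = 40L,
    n_t = 40L,
    stringsAsFactors = FALSE
  )
}
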