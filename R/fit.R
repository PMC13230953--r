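# Estimation of the strength correlation rho and the main model-fitting
# entry point.  rho acts as a scaling parameter on the mean predicted
# test-condition accuracy, so matching the observed mean identifies it
# uniquely: the mean prediction is continuous and strictly decreasing in
# rho, and bisection on the signed mean difference converges without a
# starting value.

#' Estimate the strength correlation from participant summaries
#'
#' Finds `rho` in \[0, 1\] minimising the absolute difference between the
#' mean of `pt_correlated(pc_r_i, rho)` over participants and the mean
#' observed `pc_t`.  Each participant's own restudy accuracy feeds the
#' prediction; means are taken across participants (subject-level framing),
#' not across pooled trials.
#'
#' If the observed mean already exceeds the independence prediction the
#' estimate is pinned at the lower boundary `rho = 0` (there is no
#' correlation that raises the prediction above independence); an observed
#' mean below the single-route prediction pins it at `rho = 1`.
#'
#' @param summaries participant summaries ([summarize_participants()]).
#' @param group optional group filter (`"low"` / `"high"`).
#' @param tol bisection tolerance on rho.
#' @param nodes quadrature nodes passed to [pt_correlated()].
#' @return an object of class `dmm_rho_fit`: a list with `rho_hat`,
#'   `objective` (absolute mean difference at the estimate), `converged`,
#'   `boundary` (`"none"`, `"lower"` or `"upper"`), `n`, `tol`, and a
#'   `search_trace` data.frame of evaluated `(rho, objective)` pairs.
#' @examples
#' s <- summarize_participants(generate_cohort(cohort_config(seed = 5)))
#' fit_rho(s, group = "high")
#' @export
fit_rho <- function(summaries, group = NULL, tol = 1e-3, nodes = 32L) {
  summaries <- validate_summaries(summaries)
  if (!is.null(group)) summaries <- summaries[summaries$group == group, ]
  n <- nrow(summaries)
  if (n < 2L) stop("need at least 2 participants to fit rho", call. = FALSE)
  pc_r <- summaries$pc_r
  pc_t <- summaries$pc_t
  if (all(pc_r %in% c(0, 1))) {
    stop(paste("rho is not identifiable: every restudy proportion is 0 or 1,",
               "so predictions do not depend on rho"), call. = FALSE)
  }
  obs <- mean(pc_t)
  trace <- list()
  f <- function(rho) {
    val <- mean(pt_correlated(pc_r, rho, nodes)) - obs
    trace[[length(trace) + 1L]] <<- c(rho = rho, objective = abs(val))
    val
  }
  f0 <- f(0)
  boundary <- "none"
  if (f0 <= 0) {
    rho_hat <- 0
    boundary <- "lower"
    objective <- abs(f0)
  } else {
    f1 <- f(1)
    if (f1 >= 0) {
      rho_hat <- 1
      boundary <- "upper"
      objective <- abs(f1)
    } else {
      lo <- 0; hi <- 1
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (f(mid) > 0) lo <- mid else hi <- mid
      }
      f((lo + hi) / 2)
      # take the best evaluated point: monotonicity makes it lie within
      # tol of the final bracket midpoint
      tr <- do.call(rbind, trace)
      best <- which.min(tr[, "objective"])
      rho_hat <- unname(tr[best, "rho"])
      objective <- unname(tr[best, "objective"])
    }
  }
  structure(list(
    rho_hat = rho_hat,
    objective = objective,
    converged = TRUE,
    boundary = boundary,
    n = n,
    tol = tol,
    search_trace = as.data.frame(do.call(rbind, trace))
  ), class = "dmm_rho_fit")
}

#' @export
print.dmm_rho_fit <- function(x, ...) {
  cat(sprintf("Strength-correlation fit: rho = %.3f", x$rho_hat))
  if (x$boundary != "none") cat(sprintf(" (%s boundary)", x$boundary))
  cat(sprintf("\n  |mean predicted - mean observed PC_T| = %.5f, n = %d\n",
              x$objective, x$n))
  invisible(x)
}

#' Relative reduction in testing efficacy
#'
#' Shortfall of the observed mean testing effect relative to the
#' independent-routes prediction, `(predicted - observed) / predicted`.
#' Positive values mean testing delivered less than the parameter-free
#' model promises; negative values mean it delivered more.
#'
#' @param observed_te_mean mean observed testing effect.
#' @param predicted_te_mean mean predicted testing effect; must be positive.
#' @return the fractional reduction.
#' @examples
#' efficacy_reduction(0.185, 0.25)  # 0.26
#' @export
efficacy_reduction <- function(observed_te_mean, predicted_te_mean) {
  if (!is.numeric(predicted_te_mean) || length(predicted_te_mean) != 1L ||
      is.na(predicted_te_mean) || predicted_te_mean <= 0) {
    stop("'predicted_te_mean' must be a single positive number",
         call. = FALSE)
  }
  if (!is.numeric(observed_te_mean) || length(observed_te_mean) != 1L ||
      is.na(observed_te_mean)) {
    stop("'observed_te_mean' must be a single number", call. = FALSE)
  }
  (predicted_te_mean - observed_te_mean) / predicted_te_mean
}

#' Fit the dual-memory model to a cohort
#'
#' The main modelling entry point.  Takes trial-level data (or ready-made
#' participant summaries), computes per-participant restudy and test
#' accuracies, evaluates the parameter-free independent-routes predictions,
#' estimates the strength correlation `rho` separately within each
#' relatedness group by mean matching ([fit_rho()]), builds cumulative
#' distribution curves under both transforms, and quantifies how far
#' observed test performance falls short of the independence prediction.
#'
#' @param data a trial table (from [generate_cohort()] / [read_trials()])
#'   or a participant summary table (recognised by a `pc_r` column).
#' @param rho optional fixed strength correlation; when supplied the
#'   estimation step is skipped and the value is used for every group.
#' @param tol bisection tolerance forwarded to [fit_rho()].
#' @return an object of class `dualmem` with components `summaries`,
#'   `groups`, `means` (per-group condition means and predictions), `fits`
#'   (per-group `dmm_rho_fit`), `curves` (per-group independent and
#'   correlated [cumulative_curve()]s), `deviations` (independent-transform
#'   [deviation_metrics()] per group), `efficacy` (per-group
#'   [efficacy_reduction()] of the mean TE), and the matched `call`.
#' @examples
#' fit <- dualmem(generate_cohort(cohort_config(seed = 3)))
#' fit
#' coef(fit)
#' @export
dualmem <- function(data, rho = NULL, tol = 1e-3) {
  cl <- match.call()
  summaries <- if ("pc_r" %in% names(data)) {
    validate_summaries(data)
  } else {
    summarize_participants(data)
  }
  groups <- intersect(c("low", "high"), unique(summaries$group))
  if (length(groups) == 0L) stop("no recognised groups in data", call. = FALSE)

  fits <- list()
  means <- list()
  curves <- list()
  deviations <- list()
  efficacy <- list()
  for (g in groups) {
    sub <- summaries[summaries$group == g, ]
    fit <- if (is.null(rho)) {
      fit_rho(summaries, group = g, tol = tol)
    } else {
      check_rho(rho)
      structure(list(rho_hat = rho, objective = NA_real_, converged = TRUE,
                     boundary = "fixed", n = nrow(sub), tol = tol,
                     search_trace = data.frame(rho = rho,
                                               objective = NA_real_)),
                class = "dmm_rho_fit")
    }
    fits[[g]] <- fit
    m <- list(
      n = nrow(sub),
      pc_r = mean(sub$pc_r),
      pc_t = mean(sub$pc_t),
      pc_t_pred = mean(sub$pc_t_pred),
      pc_t_pred_fit = mean(pt_correlated(sub$pc_r, fit$rho_hat))
    )
    m$te <- m$pc_t - m$pc_r
    m$te_pred <- m$pc_t_pred - m$pc_r
    means[[g]] <- m
    curves[[g]] <- list(
      independent = cumulative_curve(summaries, group = g,
                                     transform = "independent"),
      correlated = cumulative_curve(summaries, group = g,
                                    transform = "correlated",
                                    rho = fit$rho_hat)
    )
    deviations[[g]] <- deviation_metrics(curves[[g]]$independent)
    efficacy[[g]] <- if (m$te_pred > 0) {
      efficacy_reduction(m$te, m$te_pred)
    } else {
      NA_real_
    }
  }
  structure(list(
    call = cl,
    summaries = summaries,
    groups = groups,
    means = means,
    fits = fits,
    curves = curves,
    deviations = deviations,
    efficacy = efficacy
  ), class = "dualmem")
}

#' @export
print.dualmem <- function(x, digits = 3, ...) {
  cat("Dual-memory model fit\n\n")
  for (g in x$groups) {
    m <- x$means[[g]]
    cat(sprintf("%s relatedness group (n = %d):\n", g, m$n))
    cat(sprintf("  mean PC_R = %.*f, PC_T = %.*f, PC_T predicted = %.*f\n",
                digits, m$pc_r, digits, m$pc_t, digits, m$pc_t_pred))
    cat(sprintf("  mean TE = %.*f (predicted %.*f)\n",
                digits, m$te, digits, m$te_pred))
    cat(sprintf("  fitted rho = %.*f", digits, x$fits[[g]]$rho_hat))
    if (x$fits[[g]]$boundary %in% c("lower", "upper")) {
      cat(sprintf(" (%s boundary)", x$fits[[g]]$boundary))
    }
    cat("\n")
    if (!is.na(x$efficacy[[g]])) {
      cat(sprintf("  testing efficacy vs prediction: %+.1f%%\n",
                  -100 * x$efficacy[[g]]))
    }
  }
  invisible(x)
}

#' @export
coef.dualmem <- function(object, ...) {
  vapply(object$fits, function(f) f$rho_hat, numeric(1))
}

#' Predict test-condition performance from a fitted model
#'
#' @param object a [dualmem()] fit.
#' @param newdata optional vector of restudy accuracies or data.frame with
#'   a `pc_r` column; defaults to the fitted participants.
#' @param group group whose fitted `rho` to use (defaults to the first).
#' @param model `"correlated"` (fitted rho) or `"independent"` (rho = 0).
#' @param ... unused.
#' @return predicted test-condition proportions correct.
#' @export
predict.dualmem <- function(object, newdata = NULL, group = NULL,
                            model = c("correlated", "independent"), ...) {
  model <- match.arg(model)
  if (is.null(group)) group <- object$groups[[1L]]
  if (!group %in% object$groups) {
    stop(sprintf("group '%s' was not in the fitted data", group),
         call. = FALSE)
  }
  pc_r <- if (is.null(newdata)) {
    object$summaries$pc_r[object$summaries$group == group]
  } else if (is.data.frame(newdata)) {
    newdata$pc_r
  } else {
    newdata
  }
  if (model == "independent") {
    predict_pt(pc_r)
  } else {
    pt_correlated(pc_r, object$fits[[group]]$rho_hat)
  }
}

#' @export
fitted.dualmem <- function(object, ...) {
  s <- object$summaries
  out <- numeric(nrow(s))
  for (g in object$groups) {
    idx <- s$group == g
    out[idx] <- pt_correlated(s$pc_r[idx], object$fits[[g]]$rho_hat)
  }
  names(out) <- s$participant_id
  out
}

#' Residual test-condition performance
#'
#' Observed minus predicted `pc_t` per participant, under the fitted
#' correlated model (default) or the parameter-free independent model.
#'
#' @param object a [dualmem()] fit.
#' @param model which transform supplies the prediction.
#' @param ... unused.
#' @return named numeric vector of residuals.
#' @export
residuals.dualmem <- function(object,
                              model = c("correlated", "independent"), ...) {
  model <- match.arg(model)
  s <- object$summaries
  pred <- if (model == "independent") {
    predict_pt(s$pc_r)
  } else {
    fitted(object)
  }
  out <- s$pc_t - pred
  names(out) <- s$participant_id
  out
}

#' Simulate cohorts from a fitted model
#'
#' Semiparametric generator: participant abilities are resampled with
#' replacement from the observed restudy accuracies within each group, and
#' test-condition outcomes are drawn from the correlated-strengths process
#' at the group's fitted `rho`.  Item counts mirror the fitted data.
#'
#' @param object a [dualmem()] fit.
#' @param nsim number of cohorts.
#' @param seed integer seed (the caller's RNG state is preserved).
#' @param ... unused.
#' @return a list of `nsim` trial tables.
#' @export
simulate.dualmem <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  s <- object$summaries
  items <- if ("n_r" %in% names(s)) max(s$n_r) else 40L
  lapply(seq_len(nsim), function(i) {
    pieces <- lapply(object$groups, function(g) {
      sub <- s[s$group == g, ]
      rho <- object$fits[[g]]$rho_hat
      ability <- sample(sub$pc_r, nrow(sub), replace = TRUE)
      simulate_group_trials(g, ability, rho, items)
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  })
}

# Shared by simulate.dualmem: trial table for one group given abilities.
simulate_group_trials <- function(group, ability, rho, items) {
  k <- items
  item_r <- sprintf("r%02d", seq_len(k))
  item_t <- sprintf("t%02d", seq_len(k))
  pieces <- lapply(seq_along(ability), function(i) {
    p <- ability[i]
    z <- if (p <= 0) Inf else if (p >= 1) -Inf else stats::qnorm(1 - p)
    corr_r <- as.integer(stats::runif(k) < p)
    st <- stats::rnorm(k)
    tt <- rho * st + sqrt(1 - rho^2) * stats::rnorm(k)
    corr_t <- as.integer(st > z | tt > z)
    data.frame(
      participant_id = sprintf("%s%03d", toupper(substr(group, 1, 1)), i),
      group = group,
      condition = rep(c("restudy", "test"), each = k),
      item_id = c(item_r, item_t),
      correct = c(corr_r, corr_t),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, pieces)
}

#' Summarise a dual-memory model fit
#'
#' Augments the fit with the inference chain: the mixed-design ANOVA on
#' observed performance (Training Task x Relatedness), the observed-versus-
#' predicted ANOVA (Data Type x Relatedness), and per-group paired t tests
#' of observed against predicted test performance with JZS Bayes factors.
#' Requires both groups; with a single group only the t tests are run.
#'
#' @param object a [dualmem()] fit.
#' @param ... unused.
#' @return an object of class `summary.dualmem`.
#' @export
summary.dualmem <- function(object, ...) {
  s <- object$summaries
  both <- length(object$groups) == 2L
  anova_task <- if (both) mixed_anova_2x2(s, measures = c("pc_r", "pc_t"))
                else NULL
  anova_dtype <- if (both) mixed_anova_2x2(s,
                                           measures = c("pc_t", "pc_t_pred"))
                 else NULL
  t_dtype <- lapply(object$groups, function(g) {
    sub <- s[s$group == g, ]
    t_test_bf(sub$pc_t, sub$pc_t_pred, paired = TRUE)
  })
  names(t_dtype) <- object$groups
  structure(list(
    fit = object,
    anova_training_task = anova_task,
    anova_data_type = anova_dtype,
    t_data_type = t_dtype
  ), class = "summary.dualmem")
}

#' @export
print.summary.dualmem <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$anova_training_task)) {
    cat("\nMixed ANOVA, Training Task x Relatedness (observed):\n")
    print(x$anova_training_task)
    cat("\nMixed ANOVA, Data Type x Relatedness (observed vs predicted PC_T):\n")
    print(x$anova_data_type)
  }
  cat("\nPaired t, observed vs predicted PC_T:\n")
  for (g in names(x$t_data_type)) {
    tt <- x$t_data_type[[g]]
    cat(sprintf("  %s: t(%d) = %.2f, p = %.3g, BF10 = %.3g (%s)\n",
                g, tt$df, tt$statistic, tt$p_value, tt$bf10, tt$evidence))
  }
  invisible(x)
}

#' Plot a dual-memory model fit
#'
#' One cumulative-distribution panel per group: observed restudy and test
#' distributions with the independent-routes prediction and, when the
#' fitted `rho` is positive, the correlated-strengths prediction.
#'
#' @param x a [dualmem()] fit.
#' @param ... passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.dualmem <- function(x, ...) {
  ng <- length(x$groups)
  old <- graphics::par(mfrow = c(1, ng))
  on.exit(graphics::par(old))
  for (g in x$groups) {
    cv <- x$curves[[g]]$independent
    plot(cv, ...)
    rho <- x$fits[[g]]$rho_hat
    if (rho > 0) {
      cc <- x$curves[[g]]$correlated
      graphics::lines(cc$quantile, cc$pc_t_pred, lwd = 2, lty = 2,
                      col = "red3")
      graphics::legend("bottomright", bty = "n", lty = 2, lwd = 2,
                       col = "red3",
                       legend = sprintf("correlated (rho = %.3f)", rho))
    }
  }
  invisible(x)
}
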