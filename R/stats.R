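# Inference chain: mixed-design ANOVA (one within x one between factor),
# pairwise t tests, default JZS Bayes factors for t statistics, and
# Raftery's evidence bins.  ANOVA-level Bayes factors are deliberately not
# provided: the default mixed-model Bayes factor requires integration over
# random-effect priors and is out of scope; reports label it as such.

#' Mixed-design 2 x 2 ANOVA on participant summaries
#'
#' Classical decomposition for one within-participant factor (two
#' measures, e.g. restudy vs test accuracy, or observed vs predicted test
#' accuracy) crossed with the between-participant relatedness group.
#' Sums of squares are partitioned into between-subject and within-subject
#' strata via [stats::aov()] with an error term for participants; unequal
#' group sizes are handled by the standard sequential decomposition.
#'
#' @param summaries participant summaries with both measure columns.
#' @param measures length-2 character vector naming the within-participant
#'   measures, e.g. `c("pc_r", "pc_t")` (Training Task) or
#'   `c("pc_t", "pc_t_pred")` (Data Type).
#' @return a `data.frame` of class `dmm_anova` with one row per effect
#'   (`group`, `measure`, `group:measure`) and columns `statistic` (F),
#'   `df1`, `df2`, `p_value`, `pes` (partial eta squared).
#' @examples
#' s <- summarize_participants(generate_cohort(cohort_config(
#'   n_low = 30, n_high = 30, seed = 4)))
#' mixed_anova_2x2(s, measures = c("pc_r", "pc_t"))
#' @export
mixed_anova_2x2 <- function(summaries, measures = c("pc_r", "pc_t")) {
  summaries <- validate_summaries(summaries)
  if (length(measures) != 2L || !all(measures %in% names(summaries))) {
    stop("'measures' must name two columns of the summaries", call. = FALSE)
  }
  if (anyNA(summaries[, measures])) {
    stop("missing cells: both measures are required for every participant",
         call. = FALSE)
  }
  if (length(unique(summaries$group)) != 2L) {
    stop("exactly two groups are required", call. = FALSE)
  }
  long <- data.frame(
    participant = factor(rep(summaries$participant_id, 2L)),
    group = factor(rep(summaries$group, 2L)),
    measure = factor(rep(measures, each = nrow(summaries)), levels = measures),
    y = c(summaries[[measures[1L]]], summaries[[measures[2L]]])
  )
  fit <- stats::aov(y ~ group * measure + Error(participant / measure),
                    data = long)
  sm <- summary(fit)
  # between-subject stratum: group; within-subject stratum: measure and
  # group:measure, each tested against its stratum residual
  tab_b <- as.data.frame(sm[["Error: participant"]][[1L]])
  tab_w <- as.data.frame(sm[["Error: participant:measure"]][[1L]])
  pull <- function(tab, effect) {
    rn <- trimws(rownames(tab))
    i <- match(effect, rn)
    r <- match("Residuals", rn)
    ss_eff <- tab[i, "Sum Sq"]
    ss_res <- tab[r, "Sum Sq"]
    f <- tab[i, "F value"]
    p <- tab[i, "Pr(>F)"]
    # a numerically zero effect sum of squares is a true null effect even
    # when its stratum residual also vanishes (0/0 in aov's ratio)
    if (ss_eff < 1e-12) {
      f <- 0
      p <- 1
    }
    data.frame(
      effect = effect,
      statistic = f,
      df1 = tab[i, "Df"],
      df2 = tab[r, "Df"],
      p_value = p,
      pes = if (ss_eff + ss_res > 1e-12) ss_eff / (ss_eff + ss_res) else 0,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(pull(tab_b, "group"),
               pull(tab_w, "measure"),
               pull(tab_w, "group:measure"))
  rownames(out) <- NULL
  class(out) <- c("dmm_anova", "data.frame")
  out
}

#' Two-sided t test with a default JZS Bayes factor
#'
#' Wraps [stats::t.test()] (paired or Welch-free pooled two-sample) and
#' attaches the JZS Bayes factor at the default Cauchy prior scale 0.707
#' together with a Raftery evidence label for the directional Bayes factor
#' `max(BF10, BF01)`.
#'
#' Degenerate zero-variance inputs (possible with proportion data pinned at
#' floor or ceiling) raise an error rather than returning an infinite t.
#'
#' @param a,b numeric vectors; equal length when `paired = TRUE`.
#' @param paired paired (difference-score) test?
#' @param r_scale Cauchy prior scale for the Bayes factor.
#' @return a list of class `dmm_test`: `statistic`, `df`, `p_value`,
#'   `bf10`, `bf01`, `evidence`, `method`.
#' @export
t_test_bf <- function(a, b, paired = FALSE, r_scale = 0.707) {
  if (!is.numeric(a) || !is.numeric(b)) {
    stop("'a' and 'b' must be numeric", call. = FALSE)
  }
  if (paired && length(a) != length(b)) {
    stop("paired test requires equal-length vectors", call. = FALSE)
  }
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 observations per sample", call. = FALSE)
  }
  if (paired) {
    if (stats::sd(a - b) == 0) {
      stop("zero-variance difference scores: t is undefined", call. = FALSE)
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    bf10 <- jzs_bf_t(unname(tt$statistic), n1 = length(a), r_scale = r_scale)
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      stop("zero-variance samples: t is undefined", call. = FALSE)
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    bf10 <- jzs_bf_t(unname(tt$statistic), n1 = length(a), n2 = length(b),
                     r_scale = r_scale)
  }
  structure(list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    bf10 = bf10,
    bf01 = 1 / bf10,
    evidence = raftery_label(max(bf10, 1 / bf10)),
    method = if (paired) "paired t" else "two-sample t"
  ), class = "dmm_test")
}

#' @export
print.dmm_test <- function(x, ...) {
  cat(sprintf("%s: t(%g) = %.3f, p = %.4g, BF10 = %.4g, BF01 = %.4g (%s)\n",
              x$method, x$df, x$statistic, x$p_value, x$bf10, x$bf01,
              x$evidence))
  invisible(x)
}

#' Default JZS Bayes factor for a t statistic
#'
#' Bayes factor BF10 for the two-sided default Bayesian t test: a Cauchy
#' prior with scale `r_scale` on the standardised effect size, equivalent
#' to a Zellner-Siow prior on the regression coefficient.  Evaluated by the
#' standard one-dimensional integral over the scaled-inverse-chi-squared
#' mixing variable g,
#' \deqn{BF_{10} = \frac{\int_0^\infty (1+Ngr^2)^{-1/2}
#'   \left(1+\frac{t^2}{(1+Ngr^2)\nu}\right)^{-(\nu+1)/2}
#'   \pi(g)\,dg}{\left(1+\frac{t^2}{\nu}\right)^{-(\nu+1)/2}}}
#' with \eqn{\pi(g)} the inverse-gamma(1/2, 1/2) density, effective sample
#' size \eqn{N = n_1} (one-sample/paired, \eqn{\nu = n_1 - 1}) or
#' \eqn{N = n_1 n_2 / (n_1 + n_2)} (two-sample, \eqn{\nu = n_1 + n_2 - 2}).
#'
#' @param t observed t statistic.
#' @param n1 first (or only) sample size.
#' @param n2 second sample size for a two-sample test, or `NULL`.
#' @param r_scale Cauchy prior scale (default 0.707).
#' @return BF10 (evidence for the alternative; `1/BF10` favours the null).
#' @examples
#' jzs_bf_t(2.5, 30)
#' @export
jzs_bf_t <- function(t, n1, n2 = NULL, r_scale = 0.707) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t)) {
    stop("'t' must be a single finite number", call. = FALSE)
  }
  if (n1 < 2L) stop("'n1' must be at least 2", call. = FALSE)
  if (is.null(n2)) {
    n_eff <- n1
    nu <- n1 - 1
  } else {
    if (n2 < 2L) stop("'n2' must be at least 2", call. = FALSE)
    n_eff <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
  }
  log_h0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    a <- 1 + n_eff * g * r_scale^2
    exp(-0.5 * log(a) +
          (-(nu + 1) / 2) * log1p(t^2 / (a * nu)) - log_h0 +
          stats::dgamma(1 / g, 0.5, rate = 0.5, log = TRUE) - 2 * log(g))
  }
  # split at g = 1 to help the quadrature with the long right tail
  i1 <- stats::integrate(integrand, 0, 1, rel.tol = 1e-9,
                         stop.on.error = FALSE)
  i2 <- stats::integrate(integrand, 1, Inf, rel.tol = 1e-9,
                         stop.on.error = FALSE)
  i1$value + i2$value
}

#' Raftery evidence label for a Bayes factor
#'
#' Bins the directional Bayes factor (whichever of BF10, BF01 is at least
#' 1) into Raftery's verbal categories.  Ranges are half-open, closed on
#' the left: \[1, 3) weak, \[3, 20) positive, \[20, 150) strong, 150 and
#' above very strong.
#'
#' @param bf a Bayes factor, at least 1; callers holding a BF below 1
#'   should pass its reciprocal (i.e. `max(bf10, bf01)`).
#' @return one of `"weak"`, `"positive"`, `"strong"`, `"very strong"`.
#' @examples
#' raftery_label(6.86)   # "positive"
#' raftery_label(204.9)  # "very strong"
#' @export
raftery_label <- function(bf) {
  if (!is.numeric(bf) || length(bf) != 1L || is.na(bf)) {
    stop("'bf' must be a single number", call. = FALSE)
  }
  if (bf < 1) {
    stop(paste("'bf' must be at least 1: pass the directional Bayes factor,",
               "max(BF10, BF01)"), call. = FALSE)
  }
  if (bf < 3) "weak"
  else if (bf < 20) "positive"
  else if (bf < 150) "strong"
  else "very strong"
}
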