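# Cumulative-distribution matching.  Restudy and test-condition proportions
# correct are each sorted across participants onto a shared, equally spaced
# quantile axis; the model prediction is applied to the sorted restudy value
# at each quantile.  A participant's two scores share a quantile only by
# chance, so the comparison matches the distributions, not the individuals,
# and controls for the quadratic relation between restudy accuracy and the
# predicted testing effect.

#' Build a cumulative distribution curve
#'
#' Sorts `pc_r` and `pc_t` independently from smallest to largest over the
#' selected participants, places them on the quantile axis `k/N`
#' (k = 1..N), and attaches the model prediction computed from the sorted
#' `pc_r` at each quantile — either the parameter-free independent-routes
#' transform or the correlated-strengths transform at a given `rho`.
#'
#' @param summaries participant summaries from [summarize_participants()].
#' @param group `"low"`, `"high"`, or `NULL` for all participants combined.
#' @param transform `"independent"` for `predict_pt`, `"correlated"` for
#'   `pt_correlated` at `rho`.
#' @param rho strength correlation used when `transform = "correlated"`.
#' @return an object of class `dmm_curve`: a `data.frame` with columns
#'   `quantile`, `pc_r`, `pc_t`, `pc_t_pred` and attributes `group`,
#'   `transform`, `rho`.
#' @examples
#' s <- summarize_participants(generate_cohort(cohort_config(
#'   n_low = 20, n_high = 20, seed = 2)))
#' curve <- cumulative_curve(s, group = "high")
#' deviation_metrics(curve)
#' @export
cumulative_curve <- function(summaries, group = NULL,
                             transform = c("independent", "correlated"),
                             rho = NULL) {
  transform <- match.arg(transform)
  summaries <- validate_summaries(summaries)
  if (!is.null(group)) {
    if (!group %in% c("low", "high")) {
      stop("'group' must be \"low\", \"high\" or NULL", call. = FALSE)
    }
    summaries <- summaries[summaries$group == group, ]
    label <- group
  } else {
    label <- "combined"
  }
  n <- nrow(summaries)
  if (n < 2L) {
    stop("need at least 2 participants to build a cumulative curve",
         call. = FALSE)
  }
  if (transform == "correlated") {
    if (is.null(rho)) stop("'rho' is required for the correlated transform",
                           call. = FALSE)
    check_rho(rho)
  } else {
    rho <- 0
  }
  # stable sorts with participant_id as tie-break: proportions are
  # multiples of 1/items, so ties are the norm
  pc_r_sorted <- summaries$pc_r[order(summaries$pc_r,
                                      summaries$participant_id)]
  pc_t_sorted <- summaries$pc_t[order(summaries$pc_t,
                                      summaries$participant_id)]
  pred <- if (transform == "independent") {
    predict_pt(pc_r_sorted)
  } else {
    pt_correlated(pc_r_sorted, rho)
  }
  out <- data.frame(
    quantile = seq_len(n) / n,
    pc_r = pc_r_sorted,
    pc_t = pc_t_sorted,
    pc_t_pred = pred
  )
  attr(out, "group") <- label
  attr(out, "transform") <- transform
  attr(out, "rho") <- rho
  class(out) <- c("dmm_curve", "data.frame")
  out
}

#' Deviation of the observed from the predicted test distribution
#'
#' Quantile-wise deviations are observed minus predicted test-condition
#' proportion correct.  A mean signed deviation clearly below zero is the
#' signature of reduced testing efficacy: the independent-routes model
#' systematically overpredicts across the distribution.
#'
#' @param curve a [cumulative_curve()] result.
#' @return a list with `mean_signed_dev`, `mean_abs_dev`, `max_abs_dev`.
#' @export
deviation_metrics <- function(curve) {
  if (!inherits(curve, "dmm_curve")) {
    stop("'curve' must be a dmm_curve object", call. = FALSE)
  }
  d <- curve$pc_t - curve$pc_t_pred
  list(
    mean_signed_dev = mean(d),
    mean_abs_dev = mean(abs(d)),
    max_abs_dev = max(abs(d))
  )
}

#' Fraction of values inside a probability range
#'
#' Used to quantify how much of a group's restudy distribution falls in the
#' band where the quadratic TE prediction is largest (e.g. 0.4-0.6).  The
#' interval is closed by default; `closed = FALSE` uses the open interval,
#' since verbal range statements do not fix the endpoint convention.
#'
#' @param values vector of probabilities.
#' @param lo,hi interval endpoints, `lo <= hi`.
#' @param closed include the endpoints?
#' @return the fraction of `values` inside the interval.
#' @examples
#' range_fraction(c(0.1, 0.45, 0.5, 0.9), 0.4, 0.6)  # 0.5
#' @export
range_fraction <- function(values, lo, hi, closed = TRUE) {
  check_prob(values)
  check_prob(lo)
  check_prob(hi)
  if (lo > hi) stop("'lo' must not exceed 'hi'", call. = FALSE)
  inside <- if (closed) values >= lo & values <= hi else values > lo & values < hi
  mean(inside)
}

#' Interpolate a curve onto a common quantile grid
#'
#' Linear interpolation of the sorted values onto an equally spaced grid,
#' for comparing groups of unequal size at matched quantiles.
#'
#' @param curve a [cumulative_curve()].
#' @param grid_points number of grid points on (0, 1\].
#' @return a `data.frame` with `quantile`, `pc_r`, `pc_t`, `pc_t_pred`.
#' @export
interpolate_curve <- function(curve, grid_points = 101L) {
  if (!inherits(curve, "dmm_curve")) {
    stop("'curve' must be a dmm_curve object", call. = FALSE)
  }
  grid <- seq_len(grid_points) / grid_points
  interp <- function(y) {
    stats::approx(curve$quantile, y, xout = grid, rule = 2)$y
  }
  data.frame(quantile = grid,
             pc_r = interp(curve$pc_r),
             pc_t = interp(curve$pc_t),
             pc_t_pred = interp(curve$pc_t_pred))
}

#' Write a cumulative curve as TSV
#'
#' @param curve a [cumulative_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  if (!inherits(curve, "dmm_curve")) {
    stop("'curve' must be a dmm_curve object", call. = FALSE)
  }
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.dmm_curve <- function(x, ...) {
  cat(sprintf("Cumulative distribution curve (%s group, %s transform",
              attr(x, "group"), attr(x, "transform")))
  if (attr(x, "transform") == "correlated") {
    cat(sprintf(", rho = %.3f", attr(x, "rho")))
  }
  cat(sprintf("), %d participants\n", nrow(x)))
  m <- deviation_metrics(x)
  cat(sprintf("  mean signed dev %.4f, mean abs dev %.4f, max abs dev %.4f\n",
              m$mean_signed_dev, m$mean_abs_dev, m$max_abs_dev))
  invisible(x)
}

#' Plot a cumulative distribution curve
#'
#' Base-graphics rendering in the style of the standard cumulative plots:
#' sorted restudy and test proportions against the quantile axis with the
#' model-predicted test curve overlaid.
#'
#' @param x a `dmm_curve`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dmm_curve <- function(x, ...) {
  graphics::plot(x$quantile, x$pc_t, type = "p", pch = 1, col = "grey40",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Quantile", ylab = "Proportion correct",
                 main = sprintf("%s group", attr(x, "group")), ...)
  graphics::points(x$quantile, x$pc_r, pch = 4, col = "grey70")
  graphics::lines(x$quantile, x$pc_t_pred, lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("test (observed)", "restudy (observed)",
                              "test (predicted)"),
                   pch = c(1, 4, NA), lty = c(NA, NA, 1),
                   col = c("grey40", "grey70", "black"), lwd = c(NA, NA, 2))
  invisible(x)
}

# Validation for participant summaries used across modules.
validate_summaries <- function(summaries) {
  if (!is.data.frame(summaries)) {
    stop("'summaries' must be a data.frame", call. = FALSE)
  }
  needed <- c("participant_id", "group", "pc_r", "pc_t")
  miss <- setdiff(needed, names(summaries))
  if (length(miss)) {
    stop(sprintf("summaries missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(summaries) == 0L) stop("summaries are empty", call. = FALSE)
  check_prob(summaries$pc_r, "pc_r")
  check_prob(summaries$pc_t, "pc_t")
  if (!"pc_t_pred" %in% names(summaries)) {
    summaries$pc_t_pred <- predict_pt(summaries$pc_r)
  }
  summaries
}
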