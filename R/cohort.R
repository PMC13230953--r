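# Synthetic cohort generator.  Emulates the trial-level structure of a
# two-group cued-recall experiment in which semantic relatedness is
# manipulated between participants (low vs high) and the training task
# (restudy vs test with feedback) within participants, with a delayed final
# cued-recall test scored 0/1 per item.  Defaults follow the reference
# design: 118 low- and 113 high-relatedness participants, 40 items per
# training condition, high-group mean restudy accuracy near 0.47 with the
# low group near 0.30, and study/test strength correlation 0.334 in the
# high group (0 in the low group).

#' Configuration of a synthetic cohort
#'
#' Per-participant baseline recall probabilities are drawn from a beta
#' "ability law" parameterised by mean and concentration
#' (`shape1 = mean * concentration`, `shape2 = (1 - mean) * concentration`),
#' so abilities span the full unit interval while matching the target group
#' mean.  `concentration = Inf` (or a mean of exactly 0 or 1) gives a
#' degenerate law with every participant at the mean.  Restudy items are
#' Bernoulli in the participant's ability; test items are scored from a
#' correlated bivariate-normal strength pair thresholded at
#' `qnorm(1 - ability)`, so the expected test-condition accuracy is
#' `pt_correlated(ability, rho)` for the participant's group `rho`.
#'
#' An optional item effect (`item_sd > 0`) adds a per-item normal offset on
#' the latent strength scale, shared between conditions; it is off by
#' default since the subject-level analyses treat items as exchangeable.
#'
#' @param n_low,n_high participants per relatedness group.
#' @param items_per_condition items per training condition per participant.
#' @param ability_mean_low,ability_mean_high group means of the ability law.
#' @param ability_concentration beta concentration (mean-preserving spread
#'   control); `Inf` for a degenerate law.
#' @param rho_low,rho_high study/test strength correlation per group.
#' @param item_sd standard deviation of the optional additive item effect
#'   on the latent scale; 0 disables it.
#' @param seed integer seed that makes [generate_cohort()] deterministic.
#' @return an object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_low = 4, n_high = 4, seed = 7)
#' trials <- generate_cohort(cfg)
#' @export
cohort_config <- function(n_low = 118L, n_high = 113L,
                          items_per_condition = 40L,
                          ability_mean_low = 0.30,
                          ability_mean_high = 0.47,
                          ability_concentration = 3,
                          rho_low = 0, rho_high = 0.334,
                          item_sd = 0, seed = 1L) {
  counts <- c(n_low = n_low, n_high = n_high,
              items_per_condition = items_per_condition)
  if (any(!is.finite(counts)) || any(counts < 1) ||
      any(counts != round(counts))) {
    stop("participant and item counts must be positive integers",
         call. = FALSE)
  }
  check_prob(ability_mean_low)
  check_prob(ability_mean_high)
  if (!is.numeric(ability_concentration) || length(ability_concentration) != 1L ||
      is.na(ability_concentration) || ability_concentration <= 0) {
    stop("'ability_concentration' must be a positive number (Inf allowed)",
         call. = FALSE)
  }
  check_rho(rho_low)
  check_rho(rho_high)
  if (!is.numeric(item_sd) || length(item_sd) != 1L || is.na(item_sd) ||
      item_sd < 0) {
    stop("'item_sd' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  structure(list(
    n_low = as.integer(n_low), n_high = as.integer(n_high),
    items_per_condition = as.integer(items_per_condition),
    ability_mean_low = ability_mean_low,
    ability_mean_high = ability_mean_high,
    ability_concentration = ability_concentration,
    rho_low = rho_low, rho_high = rho_high,
    item_sd = item_sd, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  participants: %d low / %d high relatedness\n",
              x$n_low, x$n_high))
  cat(sprintf("  items per condition: %d\n", x$items_per_condition))
  cat(sprintf("  ability law: beta(mean %.3g / %.3g, concentration %s)\n",
              x$ability_mean_low, x$ability_mean_high,
              format(x$ability_concentration)))
  cat(sprintf("  strength correlation rho: %.3g low, %.3g high\n",
              x$rho_low, x$rho_high))
  if (x$item_sd > 0) cat(sprintf("  item effect sd: %.3g\n", x$item_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Draw n abilities from the group's beta law (degenerate laws permitted).
draw_abilities <- function(n, mean, concentration) {
  if (!is.finite(concentration) || mean == 0 || mean == 1) {
    return(rep(mean, n))
  }
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

#' Generate a synthetic trial table
#'
#' Draws one cohort from a [cohort_config()].  The result is a long-format
#' trial table with one row per (participant, condition, item) and binary
#' `correct` scores, the same shape the analysis functions expect from real
#' (pre-scored) data.  Regenerating with the same configuration reproduces
#' the identical table.
#'
#' Both training conditions share the participant's single baseline ability
#' (study memory is equivalent across conditions); only the test condition
#' receives the second retrieval route.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` with columns `participant_id`, `group`
#'   (`"low"`/`"high"`), `condition` (`"restudy"`/`"test"`), `item_id`,
#'   `correct` (integer 0/1).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("'config' must be a cohort_config object", call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  k <- config$items_per_condition
  item_r <- sprintf("r%02d", seq_len(k))
  item_t <- sprintf("t%02d", seq_len(k))
  groups <- list(
    low = list(n = config$n_low, mean = config$ability_mean_low,
               rho = config$rho_low),
    high = list(n = config$n_high, mean = config$ability_mean_high,
                rho = config$rho_high)
  )
  pieces <- vector("list", 0L)
  offset <- 0L
  for (gname in names(groups)) {
    g <- groups[[gname]]
    ability <- draw_abilities(g$n, g$mean, config$ability_concentration)
    # item effects are drawn per participant list position so that the
    # item_sd = 0 path consumes no extra random numbers
    for (i in seq_len(g$n)) {
      pid <- sprintf("P%03d", offset + i)
      p <- ability[i]
      z <- if (p <= 0) Inf else if (p >= 1) -Inf else stats::qnorm(1 - p)
      eff_r <- if (config$item_sd > 0) stats::rnorm(k, 0, config$item_sd) else 0
      eff_t <- if (config$item_sd > 0) stats::rnorm(k, 0, config$item_sd) else 0
      # restudy: single study-memory route
      if (config$item_sd > 0) {
        corr_r <- as.integer(stats::rnorm(k) + eff_r > z)
      } else {
        corr_r <- as.integer(stats::runif(k) < p)
      }
      # test: bivariate strengths with the group correlation
      s <- stats::rnorm(k)
      t <- g$rho * s + sqrt(1 - g$rho^2) * stats::rnorm(k)
      corr_t <- as.integer(s + eff_t > z | t + eff_t > z)
      pieces[[length(pieces) + 1L]] <- data.frame(
        participant_id = pid,
        group = gname,
        condition = rep(c("restudy", "test"), each = k),
        item_id = c(item_r, item_t),
        correct = c(corr_r, corr_t),
        stringsAsFactors = FALSE
      )
    }
    offset <- offset + g$n
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Per-participant performance summaries
#'
#' Collapses a trial table to one row per participant with restudy and
#' test-condition proportions correct and the parameter-free model
#' prediction `pc_t_pred = predict_pt(pc_r)`.
#'
#' @param trials a trial table as returned by [generate_cohort()] or
#'   [read_trials()].
#' @return a `data.frame` with columns `participant_id`, `group`, `pc_r`,
#'   `pc_t`, `pc_t_pred`, `n_r`, `n_t`, ordered by group then participant.
#' @export
summarize_participants <- function(trials) {
  trials <- validate_trials(trials)
  split_pc <- function(cond) {
    sub <- trials[trials$condition == cond, ]
    n <- tapply(sub$correct, sub$participant_id, length)
    s <- tapply(sub$correct, sub$participant_id, sum)
    data.frame(participant_id = names(n), n = as.integer(n),
               pc = as.numeric(s / n), stringsAsFactors = FALSE)
  }
  r <- split_pc("restudy")
  t <- split_pc("test")
  ids <- sort(unique(trials$participant_id))
  missing_r <- setdiff(ids, r$participant_id)
  missing_t <- setdiff(ids, t$participant_id)
  if (length(missing_r) || length(missing_t)) {
    bad <- sort(unique(c(missing_r, missing_t)))
    stop(sprintf("participant(s) missing a condition stratum: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  grp <- tapply(trials$group, trials$participant_id, function(g) g[[1L]])
  out <- data.frame(
    participant_id = ids,
    group = as.character(grp[ids]),
    pc_r = r$pc[match(ids, r$participant_id)],
    pc_t = t$pc[match(ids, t$participant_id)],
    stringsAsFactors = FALSE
  )
  out$pc_t_pred <- predict_pt(out$pc_r)
  out$n_r <- r$n[match(ids, r$participant_id)]
  out$n_t <- t$n[match(ids, t$participant_id)]
  out <- out[order(out$group, out$participant_id), ]
  rownames(out) <- NULL
  out
}

# Structural validation shared by summarize_participants and the I/O layer.
validate_trials <- function(trials) {
  if (!is.data.frame(trials)) {
    stop("'trials' must be a data.frame", call. = FALSE)
  }
  needed <- c("participant_id", "group", "condition", "item_id", "correct")
  miss <- setdiff(needed, names(trials))
  if (length(miss)) {
    stop(sprintf("trial table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(trials) == 0L) stop("trial table is empty", call. = FALSE)
  bad_grp <- which(!trials$group %in% c("low", "high"))
  if (length(bad_grp)) {
    stop(sprintf("unknown group token at row(s): %s",
                 paste(utils::head(bad_grp, 10L), collapse = ", ")),
         call. = FALSE)
  }
  bad_cond <- which(!trials$condition %in% c("restudy", "test"))
  if (length(bad_cond)) {
    stop(sprintf("unknown condition token at row(s): %s",
                 paste(utils::head(bad_cond, 10L), collapse = ", ")),
         call. = FALSE)
  }
  bad_corr <- which(!trials$correct %in% c(0L, 1L))
  if (length(bad_corr)) {
    stop(sprintf("'correct' must be 0 or 1; offending row(s): %s",
                 paste(utils::head(bad_corr, 10L), collapse = ", ")),
         call. = FALSE)
  }
  key <- paste(trials$participant_id, trials$condition, trials$item_id)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicated (participant, condition, item) at row(s): %s",
                 paste(utils::head(which(duplicated(key)), 10L),
                       collapse = ", ")), call. = FALSE)
  }
  ngrp <- tapply(trials$group, trials$participant_id,
                 function(g) length(unique(g)))
  if (any(ngrp > 1L)) {
    stop(sprintf("participant(s) assigned to more than one group: %s",
                 paste(names(ngrp)[ngrp > 1L], collapse = ", ")),
         call. = FALSE)
  }
  trials$correct <- as.integer(trials$correct)
  trials
}
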