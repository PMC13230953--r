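# File I/O: trial tables and participant summaries as CSV, cohort
# configurations as YAML or JSON.  The trial CSV with header
# participant_id,group,condition,item_id,correct is the canonical input;
# a summary CSV is accepted for users who only have per-participant
# proportions.

#' Read a trial table from CSV
#'
#' Validates the header, group/condition tokens, 0/1 scores and
#' (participant, condition, item) uniqueness; malformed content is
#' reported with offending row numbers.
#'
#' @param path CSV file with header
#'   `participant_id,group,condition,item_id,correct`.
#' @return a validated trial `data.frame`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("trial file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  needed <- c("participant_id", "group", "condition", "item_id", "correct")
  if (!identical(names(raw), needed)) {
    stop(sprintf("expected header %s but found %s",
                 paste(needed, collapse = ","),
                 paste(names(raw), collapse = ",")), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("trial file contains no rows", call. = FALSE)
  bad <- which(!raw$correct %in% c("0", "1"))
  if (length(bad)) {
    stop(sprintf("'correct' must be 0 or 1; offending data row(s): %s",
                 paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  raw$correct <- as.integer(raw$correct)
  validate_trials(raw)
}

#' Write a trial table as CSV
#'
#' @param trials a trial `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read participant summaries from CSV
#'
#' For data already aggregated to per-participant proportions.  Expects at
#' least `participant_id,group,pc_r,pc_t`; `pc_t_pred` is recomputed.
#'
#' @param path CSV path.
#' @return a validated summary `data.frame`.
#' @export
read_summaries <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("summary file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$pc_t_pred <- NULL
  validate_summaries(raw)
}

#' Read a cohort configuration from YAML or JSON
#'
#' Field names mirror the arguments of [cohort_config()]; unknown fields
#' are rejected.
#'
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return a [cohort_config()] object.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  )
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(cohort_config, lst)
}

#' Write a cohort configuration
#'
#' @param config a [cohort_config()].
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  if (!inherits(config, "cohort_config")) {
    stop("'config' must be a cohort_config object", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  lst <- unclass(config)
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(lst, path),
    json = jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  )
  invisible(path)
}
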