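#' Read / write trial-level session data
#'
#' The interchange format is a UTF-8 CSV with header and one row per trial:
#' `participant_id, trial, choice (A/B), outcome (1/-1), correct_stimulus,
#' reversal (0/1), responded (0/1), rt_ms`. Reading validates the schema
#' and reports offending rows by line.
#'
#' @param path File path.
#' @param win_value,loss_value Outcome codes accepted in the file.
#' @return `read_sessions()`: a validated trial tibble.
#' @export
read_sessions <- function(path, win_value = 1, loss_value = -1) {
  trials <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              participant_id = readr::col_character(),
                              trial = readr::col_integer(),
                              choice = readr::col_character(),
                              outcome = readr::col_double(),
                              correct_stimulus = readr::col_character(),
                              reversal = readr::col_integer(),
                              responded = readr::col_integer(),
                              rt_ms = readr::col_double()
                            ))
  check_trials(trials)
  bad_outcome <- which(!trials$outcome %in% c(win_value, loss_value))
  if (length(bad_outcome)) {
    stop("Outcome codes outside {", win_value, ", ", loss_value, "} at row(s): ",
         paste(utils::head(bad_outcome, 5), collapse = ", "), call. = FALSE)
  }
  bad_choice <- which(!trials$choice %in% c("A", "B"))
  if (length(bad_choice)) {
    stop("Choices outside {A, B} at row(s): ",
         paste(utils::head(bad_choice, 5), collapse = ", "), call. = FALSE)
  }
  bad_rt <- which(trials$responded == 1L &
                    !(is.na(trials$rt_ms) | (trials$rt_ms > 0 & trials$rt_ms <= 1500)))
  if (length(bad_rt)) {
    stop("Reaction times outside (0, 1500] at row(s): ",
         paste(utils::head(bad_rt, 5), collapse = ", "), call. = FALSE)
  }
  mono <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(ok = all(diff(.data$trial) > 0) && .data$trial[1] == 1L,
                     .groups = "drop")
  if (any(!mono$ok)) {
    stop("Non-monotone or non-1-based trial indices for participant(s): ",
         paste(mono$participant_id[!mono$ok], collapse = ", "), call. = FALSE)
  }
  trials
}

#' @rdname read_sessions
#' @param trials A trial tibble in the schema above.
#' @export
write_sessions <- function(trials, path) {
  check_trials(trials)
  readr::write_csv(trials, path)
  invisible(path)
}

#' Read / write participant-level cohort tables
#'
#' CSV with one row per participant: hardship items `h1..h4` (1-5),
#' `hardship_composite`, `income` (ordinal), `age`, `gender` (0/1), and
#' optionally true and/or estimated learning parameters. The composite is
#' recomputed on load and must equal the stored item sum.
#'
#' @param path File path.
#' @param n_items Number of hardship items expected.
#' @param likert_range,income_range Valid ranges for items and income.
#' @return `read_cohort()`: a validated cohort tibble.
#' @export
read_cohort <- function(path, n_items = 4L, likert_range = c(1L, 5L),
                        income_range = c(1L, 7L)) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  item_cols <- paste0("h", seq_len(n_items))
  need <- c("participant_id", item_cols, "hardship_composite", "income",
            "age", "gender")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop("Cohort table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  items <- as.matrix(cohort[item_cols])
  bad_item <- which(items < likert_range[1] | items > likert_range[2],
                    arr.ind = TRUE)
  if (nrow(bad_item)) {
    stop("Hardship items outside [", likert_range[1], ", ", likert_range[2],
         "] at row(s): ",
         paste(utils::head(unique(bad_item[, 1]), 5), collapse = ", "),
         call. = FALSE)
  }
  bad_inc <- which(cohort$income < income_range[1] | cohort$income > income_range[2])
  if (length(bad_inc)) {
    stop("Income outside [", income_range[1], ", ", income_range[2],
         "] at row(s): ", paste(utils::head(bad_inc, 5), collapse = ", "),
         call. = FALSE)
  }
  mismatch <- which(abs(rowSums(items) - cohort$hardship_composite) > 1e-8)
  if (length(mismatch)) {
    stop("Stored hardship composite does not equal the item sum at row(s): ",
         paste(utils::head(mismatch, 5), collapse = ", "), call. = FALSE)
  }
  cohort
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML file with optional blocks `task`, `mcmc`, `generative`, `analysis`
#' and a top-level `seed`; keys within each block mirror the arguments of
#' [task_config()], [mcmc_config()] and [generative_config()]. Absent keys
#' fall back to the defaults.
#'
#' @param path Path to the YAML file.
#' @return List with validated `task`, `mcmc`, `generative` configuration
#'   objects, the `analysis` options list and the `seed`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(block, constructor) {
    args <- raw[[block]] %||% list()
    do.call(constructor, args)
  }
  list(task = build("task", task_config),
       mcmc = build("mcmc", mcmc_config),
       generative = build("generative", generative_config),
       analysis = raw$analysis %||% list(censor_nonresponse = FALSE),
       seed = raw$seed %||% 1L)
}
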