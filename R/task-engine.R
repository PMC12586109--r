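#' Configure the probabilistic reversal learning task
#'
#' Builds a validated task configuration for the two-stimulus probabilistic
#' reversal learning (PRL) task. On every trial one of the two stimuli
#' (`"A"`/`"B"`) is designated *correct* and pays a win with probability
#' `p_win_correct` (default 0.75) while the other pays a win with probability
#' `p_win_incorrect` (default 0.25). After a run of consecutive correct
#' choices whose required length is drawn from `reversal_criteria`
#' (default 5 or 6, redrawn after every reversal so reversals cannot be
#' anticipated), the contingencies flip, up to `max_reversals` times.
#'
#' Timing fields are metadata: the simulation never waits in real time, but
#' [expected_trial_duration()] uses them and data importers may check them.
#'
#' @param n_trials Number of trials per session (default 60).
#' @param p_win_correct Win probability when the correct stimulus is chosen.
#' @param p_win_incorrect Win probability when the incorrect stimulus is chosen.
#' @param reversal_criteria Integer vector of run lengths that trigger a
#'   reversal; one element is drawn uniformly after each reversal.
#' @param max_reversals Maximum number of contingency reversals per session.
#' @param win_value,loss_value Numeric outcome codes used by the learning
#'   model (+1 / -1). The on-screen display amounts are separate metadata.
#' @param display_win_amount Currency amount shown for a win (display only).
#' @param timing Named list of timing metadata in milliseconds:
#'   `response_window_ms`, `highlight_ms`, `outcome_delay_range_ms` (length 2),
#'   `outcome_display_ms`, `iti_range_ms` (length 2).
#'
#' @return A list of class `"prl_task_config"`.
#' @export
#' @examples
#' cfg <- task_config()
#' expected_trial_duration(cfg)
task_config <- function(n_trials = 60L,
                        p_win_correct = 0.75,
                        p_win_incorrect = 0.25,
                        reversal_criteria = c(5L, 6L),
                        max_reversals = 10L,
                        win_value = 1,
                        loss_value = -1,
                        display_win_amount = 0.5,
                        timing = list(response_window_ms = 1500,
                                      highlight_ms = 500,
                                      outcome_delay_range_ms = c(500, 1500),
                                      outcome_display_ms = 1000,
                                      iti_range_ms = c(500, 1500))) {
  n_trials <- as.integer(n_trials)
  reversal_criteria <- as.integer(reversal_criteria)
  max_reversals <- as.integer(max_reversals)
  if (n_trials < 1) stop("`n_trials` must be a positive integer.", call. = FALSE)
  if (!(p_win_incorrect > 0 && p_win_incorrect < p_win_correct && p_win_correct < 1)) {
    stop("Need 0 < p_win_incorrect < p_win_correct < 1.", call. = FALSE)
  }
  if (length(reversal_criteria) < 1 || any(reversal_criteria < 1) ||
      anyNA(reversal_criteria)) {
    stop("`reversal_criteria` must be a non-empty set of positive integers.",
         call. = FALSE)
  }
  if (max_reversals < 0) stop("`max_reversals` must be >= 0.", call. = FALSE)
  if (win_value <= loss_value) {
    stop("`win_value` must exceed `loss_value`.", call. = FALSE)
  }
  needed <- c("response_window_ms", "highlight_ms", "outcome_delay_range_ms",
              "outcome_display_ms", "iti_range_ms")
  if (!all(needed %in% names(timing))) {
    stop("`timing` must contain: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_trials = n_trials,
         p_win_correct = p_win_correct,
         p_win_incorrect = p_win_incorrect,
         reversal_criteria = sort(unique(reversal_criteria)),
         max_reversals = max_reversals,
         win_value = win_value,
         loss_value = loss_value,
         display_win_amount = display_win_amount,
         timing = timing),
    class = "prl_task_config"
  )
}

#' @export
print.prl_task_config <- function(x, ...) {
  cat("<prl_task_config>\n")
  cat(sprintf("  %d trials; P(win | correct) = %.2f, P(win | incorrect) = %.2f\n",
              x$n_trials, x$p_win_correct, x$p_win_incorrect))
  cat(sprintf("  reversal after {%s} consecutive correct, max %d reversals\n",
              paste(x$reversal_criteria, collapse = ", "), x$max_reversals))
  invisible(x)
}

#' Draw the run length required for the next reversal
#'
#' Uniform draw from the configured criterion set (default \{5, 6\}), so
#' participants cannot anticipate exactly when a reversal will occur.
#'
#' @param config A [task_config()] object.
#' @return A single integer from `config$reversal_criteria`.
#' @export
draw_reversal_criterion <- function(config = task_config()) {
  crit <- config$reversal_criteria
  if (length(crit) < 1) stop("Empty reversal criterion set.", call. = FALSE)
  crit[sample.int(length(crit), 1L)]
}

#' Initial reversal-tracking state
#'
#' @param config A [task_config()] object.
#' @param correct_stimulus Which stimulus starts as correct (`"A"` or `"B"`);
#'   if `NULL`, chosen at random.
#' @return A list with fields `correct_stimulus`, `consecutive_correct`,
#'   `current_criterion`, `reversals_so_far`.
#' @export
reversal_state <- function(config = task_config(), correct_stimulus = NULL) {
  if (is.null(correct_stimulus)) {
    correct_stimulus <- c("A", "B")[sample.int(2L, 1L)]
  }
  stopifnot(correct_stimulus %in% c("A", "B"))
  list(correct_stimulus = correct_stimulus,
       consecutive_correct = 0L,
       current_criterion = draw_reversal_criterion(config),
       reversals_so_far = 0L)
}

#' Apply one choice to the task environment
#'
#' Samples the probabilistic outcome for `choice`, updates the
#' consecutive-correct counter, and flips the contingencies when the counter
#' reaches the current criterion (provided the reversal cap has not been
#' reached). The counter resets to zero both on an incorrect choice and
#' immediately after a reversal, and a fresh criterion is drawn after each
#' reversal.
#'
#' @param state A reversal state as returned by [reversal_state()].
#' @param choice `"A"` or `"B"`.
#' @param config A [task_config()] object.
#' @return A list with `outcome` (win/loss code), `was_correct` (logical,
#'   relative to the pre-reversal correct stimulus), `reversal` (logical,
#'   whether a reversal fired after this trial) and `state` (updated).
#' @export
apply_choice <- function(state, choice, config = task_config()) {
  if (!choice %in% c("A", "B")) {
    stop("Unknown stimulus id: ", choice, call. = FALSE)
  }
  was_correct <- identical(choice, state$correct_stimulus)
  p_win <- if (was_correct) config$p_win_correct else config$p_win_incorrect
  outcome <- if (stats::runif(1) < p_win) config$win_value else config$loss_value

  reversal <- FALSE
  if (was_correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= state$current_criterion &&
        state$reversals_so_far < config$max_reversals) {
      state$correct_stimulus <- setdiff(c("A", "B"), state$correct_stimulus)
      state$consecutive_correct <- 0L
      state$current_criterion <- draw_reversal_criterion(config)
      state$reversals_so_far <- state$reversals_so_far + 1L
      reversal <- TRUE
    }
  } else {
    state$consecutive_correct <- 0L
  }
  list(outcome = outcome, was_correct = was_correct,
       reversal = reversal, state = state)
}

#' Run one session of the task under an arbitrary choice policy
#'
#' Iterates [apply_choice()] for `n_trials` trials. The policy is a function
#' called once per trial with a context list holding `trial` (1-based index),
#' `correct_stimulus` (the currently correct stimulus — useful for oracle
#' policies in tests; a learning agent should ignore it) and `history`
#' (tibble of completed trials); it must return `"A"` or `"B"`.
#'
#' @param policy `function(ctx) -> "A"/"B"`.
#' @param config A [task_config()] object.
#' @param participant_id Identifier stored in the output.
#' @param seed Optional integer seed for reproducibility.
#' @param start_stimulus Optional `"A"`/`"B"` starting correct stimulus.
#' @return A tibble with one row per trial and columns `participant_id`,
#'   `trial`, `choice`, `outcome`, `correct_stimulus` (the stimulus that was
#'   correct *when the choice was made*), `reversal` (0/1, reversal fired
#'   after this trial), `responded` (0/1) and `rt_ms`.
#' @export
#' @examples
#' coin <- function(ctx) c("A", "B")[sample.int(2, 1)]
#' sess <- run_session(coin, task_config(), "p01", seed = 1)
#' summarize_behavior(sess)
run_session <- function(policy, config = task_config(),
                        participant_id = "p01", seed = NULL,
                        start_stimulus = NULL) {
  stopifnot(is.function(policy))
  if (!is.null(seed)) set.seed(seed)
  state <- reversal_state(config, correct_stimulus = start_stimulus)
  n <- config$n_trials
  choice <- character(n); outcome <- numeric(n)
  correct_stim <- character(n); reversal <- integer(n)
  for (t in seq_len(n)) {
    ctx <- list(trial = t,
                correct_stimulus = state$correct_stimulus,
                history = if (t > 1L) tibble::tibble(
                  trial = seq_len(t - 1L), choice = choice[seq_len(t - 1L)],
                  outcome = outcome[seq_len(t - 1L)]) else NULL)
    ch <- tryCatch(policy(ctx), error = function(e) {
      stop("Policy failed at trial ", t, ": ", conditionMessage(e), call. = FALSE)
    })
    correct_stim[t] <- state$correct_stimulus
    step <- apply_choice(state, ch, config)
    choice[t] <- ch
    outcome[t] <- step$outcome
    reversal[t] <- as.integer(step$reversal)
    state <- step$state
  }
  tibble::tibble(
    participant_id = participant_id,
    trial = seq_len(n),
    choice = choice,
    outcome = outcome,
    correct_stimulus = correct_stim,
    reversal = reversal,
    responded = 1L,
    rt_ms = NA_real_
  )
}

#' Behavioral summary of one or more sessions
#'
#' @param trials Trial-level tibble (possibly several participants) in the
#'   schema produced by [run_session()].
#' @return One row per participant: `accuracy` (fraction of choices of the
#'   then-correct stimulus), `n_reversals` (achieved reversals, the task's
#'   behavioral index of adaptive learning), `mean_rt_ms` (over responded
#'   trials; `NA` if reaction times are absent) and `n_trials`.
#' @export
summarize_behavior <- function(trials) {
  check_trials(trials)
  trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      accuracy = mean(.data$choice == .data$correct_stimulus),
      n_reversals = sum(.data$reversal),
      mean_rt_ms = if (all(is.na(.data$rt_ms))) NA_real_ else
        mean(.data$rt_ms[.data$responded == 1L], na.rm = TRUE),
      .groups = "drop"
    )
}

#' Expected duration of one trial, in milliseconds
#'
#' Sum of the response window, the choice highlight, the midpoint of the
#' outcome-delay range, the outcome display, and the midpoint of the
#' inter-trial interval range. With the default timing this is
#' 1500 + 500 + 1000 + 1000 + 1000 = 5000 ms.
#'
#' @param config A [task_config()] object.
#' @return Expected trial duration in ms.
#' @export
expected_trial_duration <- function(config = task_config()) {
  tm <- config$timing
  tm$response_window_ms + tm$highlight_ms + mean(tm$outcome_delay_range_ms) +
    tm$outcome_display_ms + mean(tm$iti_range_ms)
}

# internal: schema check shared by behavioral summaries / likelihood / IO
check_trials <- function(trials, require_rt = FALSE) {
  need <- c("participant_id", "trial", "choice", "outcome",
            "correct_stimulus", "reversal", "responded", "rt_ms")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("Trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0L) stop("Trial table is empty.", call. = FALSE)
  invisible(trials)
}
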