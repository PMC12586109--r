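#' Reward prediction error
#'
#' The difference between the received outcome and the expectation held
#' before the outcome, `PE = R - EV`. Outcomes are coded +1 (win) and -1
#' (loss) regardless of the currency amounts shown on screen.
#'
#' @param outcome Outcome code(s), +1 or -1.
#' @param ev_prev Expected value(s) before the outcome.
#' @return Numeric prediction error(s).
#' @export
prediction_error <- function(outcome, ev_prev) {
  outcome - ev_prev
}

#' Asymmetric value update
#'
#' Updates the chosen stimulus's expected value by a fraction of the
#' prediction error: the reward learning rate `alpha_pos` when the
#' prediction error is positive, the punishment learning rate `alpha_neg`
#' when it is zero or negative (an outcome no better than expected engages
#' the punishment learning system). The unchosen stimulus's value is never
#' touched by this function — carry it forward unchanged.
#'
#' @param ev_prev Expected value(s) before the update.
#' @param pe Prediction error(s).
#' @param alpha_pos Reward learning rate in \[0, 1\].
#' @param alpha_neg Punishment learning rate in \[0, 1\].
#' @return Updated expected value(s).
#' @export
update_expected_value <- function(ev_prev, pe, alpha_pos, alpha_neg) {
  alpha <- ifelse(pe > 0, alpha_pos, alpha_neg)
  ev_prev + alpha * pe
}

#' Softmax probability of choosing stimulus A
#'
#' `P(A) = 1 / (1 + exp(-beta * (ev_a - ev_b)))`; `P(B) = 1 - P(A)`.
#' `beta = 0` gives pure guessing (0.5) whatever the values; large `beta`
#' gives nearly deterministic value-driven choice.
#'
#' @param ev_a,ev_b Expected values of the two stimuli.
#' @param beta Inverse temperature, `beta >= 0`.
#' @return Probability of choosing A (vectorized).
#' @export
choice_probability <- function(ev_a, ev_b, beta) {
  stopifnot(all(beta >= 0))
  stats::plogis(beta * (ev_a - ev_b))
}

#' Agent parameter triple
#'
#' Convenience constructor/validator for the three-parameter model:
#' reward learning rate, punishment learning rate, inverse temperature.
#'
#' @param alpha_pos,alpha_neg Learning rates in \[0, 1\].
#' @param beta Inverse temperature, non-negative.
#' @return Named numeric vector `c(alpha_pos, alpha_neg, beta)`.
#' @export
agent_parameters <- function(alpha_pos, alpha_neg, beta) {
  if (alpha_pos < 0 || alpha_pos > 1 || alpha_neg < 0 || alpha_neg > 1) {
    stop("Learning rates must lie in [0, 1].", call. = FALSE)
  }
  if (beta < 0) stop("`beta` must be >= 0.", call. = FALSE)
  c(alpha_pos = alpha_pos, alpha_neg = alpha_neg, beta = beta)
}

#' Policy closure for a reinforcement-learning agent
#'
#' Returns a stateful policy usable with [run_session()]: it tracks the two
#' expected values internally (initialized to 0), samples choices through
#' the softmax rule, and updates the chosen stimulus's value from the
#' outcome it observes in the session history.
#'
#' @param params Parameter triple from [agent_parameters()].
#' @return A `function(ctx)` suitable for [run_session()].
#' @export
#' @examples
#' pol <- rl_policy(agent_parameters(0.72, 0.54, 1.36))
#' sess <- run_session(pol, task_config(), seed = 42)
rl_policy <- function(params) {
  ev <- c(A = 0, B = 0)
  last_trial <- 0L
  function(ctx) {
    # learn from the outcome of the previous trial before choosing
    if (!is.null(ctx$history) && ctx$trial > last_trial + 1L) {
      stop("rl_policy must be called on consecutive trials.", call. = FALSE)
    }
    if (!is.null(ctx$history)) {
      prev <- ctx$history[nrow(ctx$history), ]
      pe <- prediction_error(prev$outcome, ev[[prev$choice]])
      ev[[prev$choice]] <<- update_expected_value(
        ev[[prev$choice]], pe, params[["alpha_pos"]], params[["alpha_neg"]])
    }
    last_trial <<- ctx$trial
    p_a <- choice_probability(ev[["A"]], ev[["B"]], params[["beta"]])
    if (stats::runif(1) < p_a) "A" else "B"
  }
}

#' Simulate a PRL session for a reinforcement-learning agent
#'
#' Composition of [rl_policy()] and [run_session()].
#'
#' @param params Parameter triple from [agent_parameters()].
#' @inheritParams run_session
#' @return Trial tibble as from [run_session()].
#' @export
simulate_rl_session <- function(params, config = task_config(),
                                participant_id = "p01", seed = NULL,
                                start_stimulus = NULL) {
  run_session(rl_policy(params), config = config,
              participant_id = participant_id, seed = seed,
              start_stimulus = start_stimulus)
}

#' Log-likelihood of one participant's choices under the model
#'
#' Walks the trial sequence in order. Both expected values start at 0, so
#' the first choice always has probability 0.5. On each trial the log of
#' the probability of the *actually chosen* stimulus is accumulated, then
#' the chosen stimulus's value is updated with the observed outcome via the
#' asymmetric rule. Probabilities are floored at `p_floor` before the log,
#' which guards extreme inverse-temperature proposals during inference
#' without materially changing the likelihood.
#'
#' Computer-selected choices on non-response trials (`responded == 0`)
#' count as the participant's own by default; with
#' `censor_nonresponse = TRUE` their log-probability terms are dropped from
#' the sum while the value updates still use them (the participant saw the
#' outcome either way).
#'
#' @param trials Trial tibble for a *single* participant, ordered by trial.
#' @param alpha_pos,alpha_neg,beta Model parameters (or pass a triple from
#'   [agent_parameters()] as `alpha_pos`).
#' @param censor_nonresponse Drop non-response trials from the sum?
#' @param p_floor Lower bound applied to choice probabilities before `log`.
#' @return A single finite numeric log-likelihood.
#' @export
#' @examples
#' sess <- simulate_rl_session(agent_parameters(0.7, 0.5, 1.4), seed = 1)
#' session_log_likelihood(sess, 0.7, 0.5, 1.4)
session_log_likelihood <- function(trials, alpha_pos, alpha_neg = NULL,
                                   beta = NULL, censor_nonresponse = FALSE,
                                   p_floor = 1e-12) {
  if (is.null(alpha_neg) && length(alpha_pos) == 3L) {
    beta <- alpha_pos[[3L]]; alpha_neg <- alpha_pos[[2L]]
    alpha_pos <- alpha_pos[[1L]]
  }
  check_trials(trials)
  if (length(unique(trials$participant_id)) != 1L) {
    stop("`trials` must contain exactly one participant; see fit helpers ",
         "for cohort-level operations.", call. = FALSE)
  }
  traj <- rl_trajectory(trials, alpha_pos, alpha_neg, beta, p_floor = p_floor)
  keep <- if (censor_nonresponse) trials$responded == 1L else TRUE
  sum(log(pmax(traj$p_chosen[keep], p_floor)))
}

#' Per-trial latent trajectory under fixed parameters
#'
#' Replays a session under the model and returns, for every trial, the
#' expected values *before* the choice, the choice probabilities, the
#' probability of the stimulus actually chosen, and the prediction error of
#' the observed outcome. Summing `log(p_chosen)` reproduces
#' [session_log_likelihood()] (without censoring).
#'
#' @inheritParams session_log_likelihood
#' @return Tibble with columns `trial`, `choice`, `outcome`, `ev_a`, `ev_b`,
#'   `p_a`, `p_chosen`, `pe`.
#' @export
rl_trajectory <- function(trials, alpha_pos, alpha_neg = NULL, beta = NULL,
                          p_floor = 1e-12) {
  if (is.null(alpha_neg) && length(alpha_pos) == 3L) {
    beta <- alpha_pos[[3L]]; alpha_neg <- alpha_pos[[2L]]
    alpha_pos <- alpha_pos[[1L]]
  }
  check_trials(trials)
  stopifnot(alpha_pos >= 0, alpha_pos <= 1, alpha_neg >= 0, alpha_neg <= 1,
            beta >= 0)
  n <- nrow(trials)
  choice <- trials$choice
  outcome <- trials$outcome
  ev <- c(A = 0, B = 0)
  ev_a <- numeric(n); ev_b <- numeric(n)
  p_a <- numeric(n); p_ch <- numeric(n); pe <- numeric(n)
  for (t in seq_len(n)) {
    ev_a[t] <- ev[["A"]]; ev_b[t] <- ev[["B"]]
    p_a[t] <- choice_probability(ev[["A"]], ev[["B"]], beta)
    p_ch[t] <- if (choice[t] == "A") p_a[t] else 1 - p_a[t]
    pe[t] <- prediction_error(outcome[t], ev[[choice[t]]])
    ev[[choice[t]]] <- update_expected_value(ev[[choice[t]]], pe[t],
                                             alpha_pos, alpha_neg)
  }
  tibble::tibble(trial = trials$trial, choice = choice, outcome = outcome,
                 ev_a = ev_a, ev_b = ev_b, p_a = p_a,
                 p_chosen = pmax(p_ch, p_floor), pe = pe)
}
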