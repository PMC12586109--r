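# Shared fixtures and independent oracles, built in code.

# Build a trial tibble directly from vectors (bypasses the simulator so
# likelihood tests control the exact sequence).
make_trials <- function(choices, outcomes, participant_id = "p1",
                        correct = NULL, responded = NULL) {
  n <- length(choices)
  tibble::tibble(
    participant_id = participant_id,
    trial = seq_len(n),
    choice = choices,
    outcome = outcomes,
    correct_stimulus = correct %||% rep("A", n),
    reversal = 0L,
    responded = responded %||% rep(1L, n),
    rt_ms = NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle: classic single-learning-rate Rescorla-Wagner +
# softmax log-likelihood, written as its own loop (not via the package's
# asymmetric implementation).
single_rate_loglik <- function(trials, alpha, beta) {
  ev <- c(A = 0, B = 0)
  ll <- 0
  for (t in seq_len(nrow(trials))) {
    p_a <- 1 / (1 + exp(-beta * (ev[["A"]] - ev[["B"]])))
    p <- if (trials$choice[t] == "A") p_a else 1 - p_a
    ll <- ll + log(p)
    ch <- trials$choice[t]
    ev[[ch]] <- ev[[ch]] + alpha * (trials$outcome[t] - ev[[ch]])
  }
  ll
}

# A random session with random (valid) structure, for property tests.
random_session <- function(n = 30, id = "p1") {
  make_trials(sample(c("A", "B"), n, replace = TRUE),
              sample(c(1, -1), n, replace = TRUE),
              participant_id = id)
}

# Oracle policy for the task engine: always pick the currently correct
# stimulus (uses the context field exposed for exactly this purpose).
oracle_policy <- function(ctx) ctx$correct_stimulus
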