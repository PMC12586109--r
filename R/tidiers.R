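#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hierarchical fit
#'
#' One row per participant per parameter: posterior mean and 95% credible
#' interval on the native scale.
#'
#' @param x A `"prl_hfit"` object.
#' @param ... Unused.
#' @return A tibble with `participant_id`, `parameter`, `estimate`,
#'   `ci_low`, `ci_high`.
#' @export
tidy.prl_hfit <- function(x, ...) {
  pp <- x$participants
  purrr::map_dfr(c("alpha_pos", "alpha_neg", "beta"), function(par) {
    tibble::tibble(participant_id = pp$participant_id,
                   parameter = par,
                   estimate = pp[[paste0(par, "_mean")]],
                   ci_low = pp[[paste0(par, "_ci_low")]],
                   ci_high = pp[[paste0(par, "_ci_high")]])
  })
}

#' Glance at a hierarchical fit
#'
#' @param x A `"prl_hfit"` object.
#' @param ... Unused.
#' @return One-row tibble: cohort size, chain settings, max R-hat,
#'   minimum effective sample size, convergence flag.
#' @export
glance.prl_hfit <- function(x, ...) {
  tibble::tibble(n_participants = x$data$N,
                 n_chains = x$mcmc$n_chains,
                 n_samples = x$mcmc$n_samples,
                 max_rhat = max(x$rhat),
                 min_ess = if (is.null(x$ess)) NA_real_ else min(x$ess),
                 converged = convergence_check(x)$pass)
}

#' Tidy a standardized regression
#'
#' @param x A `"prl_reg"` object.
#' @param ... Unused.
#' @return The per-predictor coefficient tibble (`term`, `estimate`,
#'   `ci_low`, `ci_high`, `p`, `vif`).
#' @export
tidy.prl_reg <- function(x, ...) x$terms

#' Glance at a standardized regression
#'
#' @param x A `"prl_reg"` object.
#' @param ... Unused.
#' @return One-row tibble with `r_squared`, `adj_r_squared`, `n`.
#' @export
glance.prl_reg <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 n = x$n)
}
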