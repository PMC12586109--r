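#' Plot a latent trajectory
#'
#' Expected values of both stimuli and the model's probability of choosing
#' A across trials, with observed reversal-relevant outcomes overlaid.
#'
#' @param traj Trajectory tibble from [rl_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj) {
  long <- tidyr::pivot_longer(traj[c("trial", "ev_a", "ev_b", "p_a")],
                              -"trial", names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "Trial", y = NULL, colour = NULL,
                  title = "Expected values and choice probability") +
    ggplot2::theme_minimal()
}

#' Truth-versus-estimate recovery plot
#'
#' @param cohort Cohort tibble containing `true_*` columns.
#' @param fit A `"prl_hfit"` fitted to the cohort's sessions.
#' @return A ggplot object, one facet per parameter with the identity line.
#' @export
plot_recovery <- function(cohort, fit) {
  est <- dplyr::left_join(cohort, fit$participants, by = "participant_id")
  long <- dplyr::bind_rows(
    tibble::tibble(parameter = "alpha_pos", truth = est$true_alpha_pos,
                   estimate = est$alpha_pos_mean),
    tibble::tibble(parameter = "alpha_neg", truth = est$true_alpha_neg,
                   estimate = est$alpha_neg_mean),
    tibble::tibble(parameter = "beta", truth = est$true_beta,
                   estimate = est$beta_mean))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Generating value", y = "Posterior mean",
                  title = "Parameter recovery") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for the socioeconomic regression table
#'
#' @param tab Output of [analyze_cohort()].
#' @return A ggplot object: standardized coefficients with 95% CIs,
#'   faceted by outcome.
#' @export
plot_regression_table <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "Standardized coefficient (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
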