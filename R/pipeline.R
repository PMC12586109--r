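#' Pipeline drivers
#'
#' End-to-end stages over file artifacts, each reproducible from the
#' manifest (`manifest.json`: configuration, seed, package version) it
#' writes next to its outputs.
#'
#' * `pipeline_simulate()`: synthetic cohort + sessions to CSV.
#' * `pipeline_fit()`: hierarchical fit of a session file; posterior
#'   summary CSV + convergence diagnostics JSON.
#' * `pipeline_recover()`: simulate, fit, and report truth-vs-estimate
#'   correlations.
#' * `pipeline_analyze()`: socioeconomic regressions with FDR adjustment
#'   from a cohort file joined with parameter estimates.
#'
#' @param out_dir Output directory (created if absent).
#' @param generative A [generative_config()].
#' @param task A [task_config()].
#' @param mcmc An [mcmc_config()].
#' @param seed Integer seed for the stochastic stages.
#' @name pipeline
NULL

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

write_manifest <- function(out_dir, stage, config, seed) {
  manifest <- list(stage = stage,
                   config = strip_classes(config),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("prlearn")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' @rdname pipeline
#' @return `pipeline_simulate()`: invisibly, the list from
#'   [generate_cohort()]; writes `cohort.csv`, `sessions.csv`,
#'   `manifest.json`.
#' @export
pipeline_simulate <- function(out_dir, generative = generative_config(),
                              task = task_config(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  syn <- generate_cohort(generative, task, seed = seed)
  write_cohort(syn$cohort, file.path(out_dir, "cohort.csv"))
  write_sessions(syn$trials, file.path(out_dir, "sessions.csv"))
  write_manifest(out_dir, "simulate",
                 list(generative = generative, task = task), seed)
  invisible(syn)
}

#' @rdname pipeline
#' @param sessions_path Trial-level CSV produced by [write_sessions()].
#' @return `pipeline_fit()`: invisibly, the `"prl_hfit"`; writes
#'   `posterior_summary.csv`, `diagnostics.json`, `manifest.json`.
#' @export
pipeline_fit <- function(sessions_path, out_dir, mcmc = mcmc_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- read_sessions(sessions_path)
  fit <- fit_hierarchical(trials, mcmc)
  readr::write_csv(fit$participants, file.path(out_dir, "posterior_summary.csv"))
  readr::write_csv(fit$group, file.path(out_dir, "group_summary.csv"))
  jsonlite::write_json(
    list(rhat = as.list(fit$rhat), ess = as.list(fit$ess),
         max_rhat = max(fit$rhat),
         converged = convergence_check(fit)$pass,
         sampler = unclass(fit$mcmc)),
    file.path(out_dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "fit", list(mcmc = fit$mcmc), fit$mcmc$seed)
  invisible(fit)
}

#' @rdname pipeline
#' @return `pipeline_recover()`: invisibly, a list with the fit, the cohort
#'   and the recovery tibble (`parameter`, `cor_truth_estimate`); writes
#'   `recovery.csv` plus the simulate/fit artifacts.
#' @export
pipeline_recover <- function(out_dir, generative = generative_config(),
                             task = task_config(), mcmc = mcmc_config(),
                             seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  syn <- pipeline_simulate(out_dir, generative, task, seed = seed)
  fit <- fit_hierarchical(syn$trials, mcmc)
  readr::write_csv(fit$participants, file.path(out_dir, "posterior_summary.csv"))
  est <- dplyr::left_join(syn$cohort, fit$participants, by = "participant_id")
  recovery <- tibble::tibble(
    parameter = c("alpha_pos", "alpha_neg", "beta"),
    cor_truth_estimate = c(
      stats::cor(est$true_alpha_pos, est$alpha_pos_mean),
      stats::cor(est$true_alpha_neg, est$alpha_neg_mean),
      stats::cor(est$true_beta, est$beta_mean)))
  readr::write_csv(recovery, file.path(out_dir, "recovery.csv"))
  write_manifest(out_dir, "recover",
                 list(generative = generative, task = task, mcmc = mcmc), seed)
  invisible(list(fit = fit, cohort = syn$cohort, recovery = recovery))
}

#' @rdname pipeline
#' @param cohort_path Cohort CSV with covariates.
#' @param estimates Either a `"prl_hfit"`, a posterior-summary tibble/CSV
#'   path with `alpha_pos_mean` etc., or `NULL` to regress on true
#'   parameters stored in the cohort file.
#' @return `pipeline_analyze()`: invisibly, the regression table; writes
#'   `regression_table.csv`, `analysis_summary.json`, `manifest.json`.
#' @export
pipeline_analyze <- function(cohort_path, out_dir, estimates = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(cohort_path)
  if (is.character(estimates)) {
    estimates <- readr::read_csv(estimates, show_col_types = FALSE)
  } else if (inherits(estimates, "prl_hfit")) {
    estimates <- estimates$participants
  }
  if (!is.null(estimates)) {
    cohort <- dplyr::left_join(cohort, estimates, by = "participant_id")
    out_cols <- c("alpha_pos_mean", "alpha_neg_mean", "beta_mean")
  } else {
    out_cols <- c("true_alpha_pos", "true_alpha_neg", "true_beta")
  }
  cohort <- dplyr::rename(cohort, hardship = "hardship_composite")
  tab <- analyze_cohort(cohort, outcomes = out_cols)
  readr::write_csv(tab, file.path(out_dir, "regression_table.csv"))
  jsonlite::write_json(
    list(n = nrow(cohort),
         hardship_p_fdr = tab$p_fdr[!is.na(tab$p_fdr)],
         r_squared = unique(tab[c("outcome", "r_squared")])),
    file.path(out_dir, "analysis_summary.json"), auto_unbox = TRUE,
    digits = NA)
  write_manifest(out_dir, "analyze", list(outcomes = out_cols), NA_integer_)
  invisible(tab)
}
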