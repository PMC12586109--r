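#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: cohort size, the
#' latent correlation between material hardship and household income, the
#' standardized effect of hardship on the punishment learning rate, and
#' the group-level distribution of the learning parameters.
#'
#' Hardship is measured by four 5-point Likert items (food insecurity,
#' clothing affordability, access to entertainment, housing stability)
#' generated from a shared latent factor with item noise calibrated so the
#' scale's Cronbach's alpha is close to `target_cronbach_alpha`; the
#' composite is the item sum. Income is a 7-level ordinal variable.
#' Both are discretized from a latent bivariate normal with correlation
#' `hardship_income_corr` by fixed Gaussian-quantile thresholds.
#'
#' True parameters live on the unconstrained (probit) scale:
#' `raw ~ Normal(mu_k, scale_k)` with `alpha = Phi(raw)` and
#' `beta = beta_max * Phi(raw)`. The locations `mu_k` are set to
#' `qnorm(target_mean) * sqrt(1 + scale_k^2)` so the expected native-scale
#' group means equal `group_means` exactly. The hardship effect enters the
#' punishment-learning-rate raw score as a standardized linear effect of
#' size `b_hardship_on_alpha_neg`.
#'
#' @param n_participants Cohort size (default 95).
#' @param hardship_income_corr Latent hardship/income correlation
#'   (default -0.417).
#' @param b_hardship_on_alpha_neg Standardized effect of the hardship
#'   composite on the punishment learning rate (default 0.24).
#' @param group_means Native-scale group means of
#'   `(alpha_pos, alpha_neg, beta)` (default 0.72, 0.54, 1.36).
#' @param group_scales_raw Group SDs on the unconstrained scale.
#' @param n_hardship_items,item_likert_range Hardship scale shape.
#' @param target_cronbach_alpha Intended internal consistency (default 0.83).
#' @param income_levels Number of ordinal income categories.
#' @param age_range Inclusive integer age range (default 18-20).
#' @param prop_female Probability a participant is coded female (1).
#' @param effect_allocation `"even"` spreads the hardship effect across the
#'   composite; `"housing"` concentrates it on the housing-instability item
#'   (item 4), emulating subdomain analyses.
#' @param beta_max Upper bound of the inverse-temperature transform.
#' @return A list of class `"prl_generative_config"`.
#' @export
generative_config <- function(n_participants = 95L,
                              hardship_income_corr = -0.417,
                              b_hardship_on_alpha_neg = 0.24,
                              group_means = c(alpha_pos = 0.72,
                                              alpha_neg = 0.54,
                                              beta = 1.36),
                              group_scales_raw = c(alpha_pos = 0.25,
                                                   alpha_neg = 0.22,
                                                   beta = 0.28),
                              n_hardship_items = 4L,
                              item_likert_range = c(1L, 5L),
                              target_cronbach_alpha = 0.83,
                              income_levels = 7L,
                              age_range = c(18L, 20L),
                              prop_female = 0.6,
                              effect_allocation = c("even", "housing"),
                              beta_max = 10) {
  effect_allocation <- match.arg(effect_allocation)
  if (abs(hardship_income_corr) >= 1) {
    stop("|hardship_income_corr| must be < 1.", call. = FALSE)
  }
  if (n_participants < 2) stop("Need at least 2 participants.", call. = FALSE)
  if (target_cronbach_alpha <= 0 || target_cronbach_alpha >= 1) {
    stop("`target_cronbach_alpha` must lie strictly in (0, 1).", call. = FALSE)
  }
  gm <- group_means
  if (gm[["alpha_pos"]] <= 0 || gm[["alpha_pos"]] >= 1 ||
      gm[["alpha_neg"]] <= 0 || gm[["alpha_neg"]] >= 1 ||
      gm[["beta"]] <= 0 || gm[["beta"]] >= beta_max) {
    stop("Group means outside native parameter bounds.", call. = FALSE)
  }
  if (abs(b_hardship_on_alpha_neg) >= 1) {
    stop("|b_hardship_on_alpha_neg| must be < 1.", call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 hardship_income_corr = hardship_income_corr,
                 b_hardship_on_alpha_neg = b_hardship_on_alpha_neg,
                 group_means = gm,
                 group_scales_raw = group_scales_raw,
                 n_hardship_items = as.integer(n_hardship_items),
                 item_likert_range = as.integer(item_likert_range),
                 target_cronbach_alpha = target_cronbach_alpha,
                 income_levels = as.integer(income_levels),
                 age_range = as.integer(age_range),
                 prop_female = prop_female,
                 effect_allocation = effect_allocation,
                 beta_max = beta_max),
            class = "prl_generative_config")
}

# Marginal category probabilities for the discretized scales: right-skewed
# Likert items (mean ~2.1, SD ~1.2, so a 4-item sum near the reference
# mean 8.1 / SD 3.7) and a 7-level income with mean ~3.65, SD ~1.7.
likert_item_probs <- c(0.40, 0.30, 0.15, 0.10, 0.05)
income_level_probs <- c(0.10, 0.18, 0.22, 0.20, 0.14, 0.09, 0.07)

# internal: cut a standard-normal latent at fixed Gaussian quantiles
discretize_gaussian <- function(z, probs) {
  cuts <- stats::qnorm(cumsum(probs)[-length(probs)])
  findInterval(z, cuts) + 1L
}

#' Generate socioeconomic covariate profiles
#'
#' Draws a latent bivariate standard normal per participant with the
#' configured hardship/income correlation, expands the hardship factor
#' into Likert items with noise calibrated to the target Cronbach's alpha
#' (inter-item correlation `r = a / (k - (k-1) a)`), and discretizes both
#' scales with fixed thresholds. Discretization slightly attenuates the
#' observed composite/income correlation relative to the latent value.
#'
#' @param config A [generative_config()].
#' @return Tibble with `participant_id`, items `h1..hk`,
#'   `hardship_composite` (item sum), `income`, `age`, `gender`
#'   (1 = female, 0 = male) and the latent scores `z_hardship`, `z_income`.
#' @export
generate_socioeconomic_profiles <- function(config = generative_config()) {
  n <- config$n_participants
  k <- config$n_hardship_items
  rho <- config$hardship_income_corr
  a <- config$target_cronbach_alpha
  # equal-loading factor model: alpha = k*r/(1+(k-1)*r) -> inter-item r
  r_item <- a / (k - (k - 1) * a)
  if (r_item <= 0 || r_item >= 1) {
    stop("Infeasible Cronbach's alpha target for ", k, " items.", call. = FALSE)
  }
  noise_var <- (1 - r_item) / r_item
  zh <- stats::rnorm(n)
  zi <- rho * zh + sqrt(1 - rho^2) * stats::rnorm(n)
  lik_lo <- config$item_likert_range[1]
  items <- sapply(seq_len(k), function(j) {
    latent <- (zh + stats::rnorm(n, 0, sqrt(noise_var))) / sqrt(1 + noise_var)
    discretize_gaussian(latent, likert_item_probs) + lik_lo - 1L
  })
  colnames(items) <- paste0("h", seq_len(k))
  income <- discretize_gaussian(zi, income_level_probs[seq_len(config$income_levels)] /
                                  sum(income_level_probs[seq_len(config$income_levels)]))
  age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  gender <- stats::rbinom(n, 1L, config$prop_female)
  dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("p%03d", seq_len(n))),
    tibble::as_tibble(items),
    tibble::tibble(hardship_composite = rowSums(items),
                   income = income, age = age, gender = gender,
                   z_hardship = zh, z_income = zi)
  )
}

#' Cronbach's alpha of a multi-item scale
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))`.
#'
#' @param items Data frame or matrix of item scores (columns = items).
#' @return The reliability coefficient.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2 || nrow(items) < 2) {
    stop("Need at least 2 items and 2 rows.", call. = FALSE)
  }
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("Zero total variance; alpha undefined.", call. = FALSE)
  k <- ncol(items)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Generate ground-truth learning parameters for a cohort
#'
#' On the unconstrained scale, the punishment-learning-rate score is a
#' standardized linear function of the (standardized) hardship composite
#' with slope `b_hardship_on_alpha_neg` plus independent residual, scaled
#' to the configured group SD; the reward learning rate and inverse
#' temperature are independent of all covariates. Group locations are
#' chosen so the expected native-scale means equal the configured group
#' means.
#'
#' With `effect_allocation = "housing"` the effect operates through the
#' standardized housing-instability item (item 4) instead of the
#' composite.
#'
#' @param profiles Covariate tibble from [generate_socioeconomic_profiles()].
#' @param config A [generative_config()].
#' @return `profiles` with added columns `true_alpha_pos`,
#'   `true_alpha_neg`, `true_beta`.
#' @export
generate_true_parameters <- function(profiles, config = generative_config()) {
  n <- nrow(profiles)
  s <- config$group_scales_raw
  gm <- config$group_means
  mu <- c(stats::qnorm(gm[["alpha_pos"]]) * sqrt(1 + s[["alpha_pos"]]^2),
          stats::qnorm(gm[["alpha_neg"]]) * sqrt(1 + s[["alpha_neg"]]^2),
          stats::qnorm(gm[["beta"]] / config$beta_max) * sqrt(1 + s[["beta"]]^2))
  b <- config$b_hardship_on_alpha_neg
  driver <- if (config$effect_allocation == "housing") {
    profiles[[paste0("h", config$n_hardship_items)]]
  } else {
    profiles$hardship_composite
  }
  zdrv <- as.numeric(scale(driver))
  raw_an <- mu[2] + s[["alpha_neg"]] *
    (b * zdrv + sqrt(1 - b^2) * stats::rnorm(n))
  raw_ap <- stats::rnorm(n, mu[1], s[["alpha_pos"]])
  raw_bt <- stats::rnorm(n, mu[3], s[["beta"]])
  dplyr::mutate(profiles,
                true_alpha_pos = stats::pnorm(raw_ap),
                true_alpha_neg = stats::pnorm(raw_an),
                true_beta = config$beta_max * stats::pnorm(raw_bt))
}

#' Simulate task sessions for a cohort of agents
#'
#' One PRL session per row of `cohort`, played by an agent with that row's
#' true parameters.
#'
#' @param cohort Tibble with `participant_id`, `true_alpha_pos`,
#'   `true_alpha_neg`, `true_beta`.
#' @param config A [task_config()].
#' @return Trial tibble stacking all sessions.
#' @export
generate_cohort_sessions <- function(cohort, config = task_config()) {
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    simulate_rl_session(
      agent_parameters(cohort$true_alpha_pos[i], cohort$true_alpha_neg[i],
                       cohort$true_beta[i]),
      config = config, participant_id = cohort$participant_id[i])
  })
}

#' Generate a complete synthetic cohort
#'
#' Covariate profiles, ground-truth parameters, and simulated task
#' sessions, in one reproducible call.
#'
#' @param config A [generative_config()].
#' @param task A [task_config()].
#' @param seed Integer seed (one seed drives the whole generation).
#' @return A list with `cohort` (participant-level tibble including true
#'   parameters) and `trials` (stacked trial-level tibble).
#' @export
#' @examples
#' gc <- generative_config(n_participants = 8)
#' syn <- generate_cohort(gc, seed = 1)
#' nrow(syn$cohort); nrow(syn$trials)
generate_cohort <- function(config = generative_config(),
                            task = task_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  profiles <- generate_socioeconomic_profiles(config)
  cohort <- generate_true_parameters(profiles, config)
  trials <- generate_cohort_sessions(cohort, task)
  list(cohort = cohort, trials = trials)
}
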