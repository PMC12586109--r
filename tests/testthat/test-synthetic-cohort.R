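test_that("Cronbach's alpha matches closed forms", {
  # identical items are perfectly reliable
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)

  # two items with exact sample correlation 0.5 and equal variances:
  # Spearman-Brown gives alpha = 2 * 0.5 / 1.5
  z1 <- c(1, 1, -1, -1) / 2
  z2 <- c(1, -1, 1, -1) / 2
  expect_equal(cronbach_alpha(cbind(z1, 0.5 * z1 + sqrt(0.75) * z2)),
               2 * 0.5 / 1.5, tolerance = 1e-10)

  # independent items have near-zero reliability at large n
  set.seed(4)
  ind <- matrix(rnorm(4000 * 4), ncol = 4)
  expect_lt(abs(cronbach_alpha(ind)), 0.1)

  expect_error(cronbach_alpha(cbind(rep(1, 5), rep(2, 5))), "variance")
  expect_error(cronbach_alpha(matrix(1:5, ncol = 1)), "2 items")
})

test_that("socioeconomic profiles match the configured correlation and reliability", {
  set.seed(21)
  cfg <- generative_config(n_participants = 5000)
  prof <- generate_socioeconomic_profiles(cfg)

  expect_identical(nrow(prof), 5000L)
  expect_true(all(prof$h1 %in% 1:5))
  expect_true(all(prof$income %in% 1:7))
  expect_true(all(prof$age %in% 18:20))
  expect_true(all(prof$gender %in% 0:1))
  expect_equal(prof$hardship_composite,
               rowSums(prof[paste0("h", 1:4)]))

  # discretization and item noise attenuate the latent -0.417 to about
  # -0.36 on the observed scales (pilot band over seeds: -0.42 to -0.31)
  r_obs <- cor(prof$hardship_composite, prof$income)
  expect_gt(r_obs, -0.42)
  expect_lt(r_obs, -0.31)

  a <- cronbach_alpha(prof[paste0("h", 1:4)])
  expect_lt(abs(a - 0.83), 0.05)

  # approximate moment calibration of the published scale summaries
  expect_gt(mean(prof$hardship_composite), 7); expect_lt(mean(prof$hardship_composite), 9.5)
  expect_gt(sd(prof$hardship_composite), 2.5); expect_lt(sd(prof$hardship_composite), 4.5)
  expect_gt(mean(prof$income), 3.3); expect_lt(mean(prof$income), 4.0)
  expect_gt(sd(prof$income), 1.3); expect_lt(sd(prof$income), 2.0)
})

test_that("zero latent correlation yields uncorrelated hardship and income", {
  set.seed(22)
  prof <- generate_socioeconomic_profiles(
    generative_config(n_participants = 5000, hardship_income_corr = 0))
  expect_lt(abs(cor(prof$hardship_composite, prof$income)), 0.05)
})

test_that("true parameters encode the configured effect and group structure", {
  set.seed(31)
  cfg <- generative_config(n_participants = 5000)
  cohort <- generate_true_parameters(generate_socioeconomic_profiles(cfg), cfg)

  expect_true(all(cohort$true_alpha_pos > 0 & cohort$true_alpha_pos < 1))
  expect_true(all(cohort$true_alpha_neg > 0 & cohort$true_alpha_neg < 1))
  expect_true(all(cohort$true_beta > 0 & cohort$true_beta < 10))

  # native-scale group means match the configured targets
  expect_lt(abs(mean(cohort$true_alpha_pos) - 0.72), 0.02)
  expect_lt(abs(mean(cohort$true_alpha_neg) - 0.54), 0.02)
  expect_lt(abs(mean(cohort$true_beta) - 1.36), 0.1)

  # only the punishment learning rate tracks hardship
  d <- dplyr::rename(cohort, hardship = hardship_composite)
  tab <- analyze_cohort(d, outcomes = c("true_alpha_pos", "true_alpha_neg",
                                        "true_beta"))
  b_an <- tab$estimate[tab$outcome == "true_alpha_neg" & tab$term == "hardship"]
  b_ap <- tab$estimate[tab$outcome == "true_alpha_pos" & tab$term == "hardship"]
  expect_lt(abs(b_an - 0.24), 0.05)
  expect_lt(abs(b_ap), 0.05)
})

test_that("a null hardship effect produces a null regression coefficient", {
  set.seed(32)
  cfg <- generative_config(n_participants = 5000, b_hardship_on_alpha_neg = 0)
  cohort <- generate_true_parameters(generate_socioeconomic_profiles(cfg), cfg)
  d <- dplyr::rename(cohort, hardship = hardship_composite)
  fit <- standardized_regression(d, "true_alpha_neg",
                                 c("hardship", "income", "age", "gender"))
  expect_lt(abs(tidy(fit)$estimate[1]), 0.05)
})

test_that("degenerate group scales collapse the cohort onto the group means", {
  set.seed(33)
  cfg <- generative_config(n_participants = 50,
                           b_hardship_on_alpha_neg = 0,
                           group_scales_raw = c(alpha_pos = 1e-9,
                                                alpha_neg = 1e-9,
                                                beta = 1e-9))
  cohort <- generate_true_parameters(generate_socioeconomic_profiles(cfg), cfg)
  expect_lt(sd(cohort$true_alpha_pos), 1e-6)
  expect_lt(abs(mean(cohort$true_alpha_pos) - 0.72), 1e-6)
  expect_lt(abs(mean(cohort$true_beta) - 1.36), 1e-5)
})

test_that("cohort generation is reproducible and produces full sessions", {
  cfg <- generative_config(n_participants = 6)
  s1 <- generate_cohort(cfg, seed = 41)
  s2 <- generate_cohort(cfg, seed = 41)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$trials, s2$trials)

  counts <- dplyr::count(s1$trials, participant_id)
  expect_true(all(counts$n == 60))
  expect_identical(nrow(s1$cohort), 6L)
})

test_that("the housing-instability allocation moves the effect onto item 4", {
  set.seed(51)
  cfg <- generative_config(n_participants = 5000,
                           effect_allocation = "housing")
  cohort <- generate_true_parameters(generate_socioeconomic_profiles(cfg), cfg)
  r_h4 <- cor(cohort$h4, cohort$true_alpha_neg)
  r_h1 <- cor(cohort$h1, cohort$true_alpha_neg)
  expect_gt(r_h4, r_h1 + 0.05)
})

test_that("generator configuration validates its inputs", {
  expect_error(generative_config(hardship_income_corr = -1.2), "corr")
  expect_error(generative_config(n_participants = 1), "participants")
  expect_error(generative_config(target_cronbach_alpha = 1.2))
  expect_error(generative_config(b_hardship_on_alpha_neg = 1.5))
  expect_error(generative_config(group_means = c(alpha_pos = 1.2,
                                                 alpha_neg = 0.5, beta = 1)))
})
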