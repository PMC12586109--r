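test_that("parameter transforms are correct and invert each other", {
  expect_equal(unname(to_native(c(0, 0, 0))), c(0.5, 0.5, 5))
  expect_equal(to_native(c(qnorm(0.72), 0, 0))[["alpha_pos"]], 0.72,
               tolerance = 1e-12)

  nat <- c(0.72, 0.54, 1.36)
  expect_equal(unname(to_native(from_native(nat))), nat, tolerance = 1e-10)

  raw <- c(0.3, -1.2, 0.8)
  expect_equal(unname(from_native(to_native(raw))), raw, tolerance = 1e-10)

  # matrix form agrees with the vector form
  m <- rbind(c(0.3, -1.2, 0.8), c(-0.5, 0.2, -2))
  expect_equal(unname(to_native(m)[1, ]), unname(to_native(m[1, ])))

  expect_error(from_native(c(1.5, 0.5, 1)), "outside")
  expect_error(from_native(c(0.5, 0.5, 11)), "outside")
})

test_that("rank-normalized split R-hat separates mixed from unmixed chains", {
  set.seed(61)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(rhat_rank_normalized(good), 1.01)

  shifted <- cbind(matrix(rnorm(2000), ncol = 2),
                   matrix(rnorm(2000, mean = 3), ncol = 2))
  expect_gt(rhat_rank_normalized(shifted), 1.2)

  # scale mismatch is caught through the folded statistic
  scaled <- cbind(matrix(rnorm(2000, sd = 1), ncol = 2),
                  matrix(rnorm(2000, sd = 6), ncol = 2))
  expect_gt(rhat_rank_normalized(scaled), 1.05)

  # a within-chain trend (non-stationarity) is caught by splitting
  trended <- matrix(rnorm(4000) + rep(seq(0, 3, length.out = 1000), 4),
                    ncol = 4)
  expect_gt(rhat_rank_normalized(trended), 1.05)

  expect_true(is.na(rhat_rank_normalized(matrix(1, 100, 4))))
})

test_that("convergence check passes and fails at the threshold, naming offenders", {
  ok <- list(rhat = c("mu[1]" = 1.002, "sg[1]" = 1.005),
             mcmc = list(rhat_threshold = 1.01))
  expect_true(convergence_check(ok)$pass)

  bad <- list(rhat = c("mu[1]" = 1.002, "sg[2]" = 1.05),
              mcmc = list(rhat_threshold = 1.01))
  chk <- convergence_check(bad)
  expect_false(chk$pass)
  expect_identical(chk$offending$parameter, "sg[2]")

  expect_error(convergence_check(list(rhat = NULL)), "R-hat")
})

test_that("the sampler's vectorized likelihood equals the reference implementation", {
  set.seed(71)
  # ragged cohort: sessions of different lengths
  trials <- dplyr::bind_rows(
    random_session(60, "p1"), random_session(45, "p2"),
    random_session(60, "p3"), random_session(30, "p4"))
  dat <- prlearn:::trials_to_matrices(trials)
  for (rep in 1:5) {
    raw <- cbind(rnorm(4), rnorm(4), rnorm(4))
    ll_vec <- prlearn:::cohort_loglik(raw, dat)
    ll_ref <- vapply(seq_len(4), function(i) {
      tr <- trials[trials$participant_id == dat$ids[i], ]
      session_log_likelihood(tr, to_native(raw[i, ]))
    }, numeric(1))
    expect_equal(ll_vec, ll_ref, tolerance = 1e-12)
  }
  # censored route agrees too
  trials$responded[c(3, 70, 120)] <- 0L
  dat <- prlearn:::trials_to_matrices(trials)
  raw <- cbind(rnorm(4), rnorm(4), rnorm(4))
  ll_vec <- prlearn:::cohort_loglik(raw, dat, censor_nonresponse = TRUE)
  ll_ref <- vapply(seq_len(4), function(i) {
    tr <- trials[trials$participant_id == dat$ids[i], ]
    session_log_likelihood(tr, to_native(raw[i, ]), censor_nonresponse = TRUE)
  }, numeric(1))
  expect_equal(ll_vec, ll_ref, tolerance = 1e-12)
})

test_that("hierarchical fit returns bounded, reproducible, well-formed summaries", {
  set.seed(81)
  syn <- generate_cohort(generative_config(n_participants = 8), seed = 81)
  cfg <- mcmc_config(n_chains = 2, n_warmup = 250, n_samples = 250, seed = 5)
  f1 <- suppressWarnings(fit_hierarchical(syn$trials, cfg))
  f2 <- suppressWarnings(fit_hierarchical(syn$trials, cfg))

  expect_s3_class(f1, "prl_hfit")
  expect_identical(nrow(f1$participants), 8L)
  expect_identical(nrow(f1$group), 3L)
  pp <- f1$participants
  expect_true(all(pp$alpha_pos_mean > 0 & pp$alpha_pos_mean < 1))
  expect_true(all(pp$alpha_neg_mean > 0 & pp$alpha_neg_mean < 1))
  expect_true(all(pp$beta_mean > 0 & pp$beta_mean < 10))
  expect_true(all(pp$alpha_neg_ci_low <= pp$alpha_neg_mean &
                    pp$alpha_neg_mean <= pp$alpha_neg_ci_high))
  expect_true(all(is.finite(f1$rhat)))

  # deterministic given the seed
  expect_identical(as.matrix(f1$draws[[1]]), as.matrix(f2$draws[[1]]))

  # tidy/glance interfaces
  td <- tidy(f1)
  expect_identical(nrow(td), 24L)  # 8 participants x 3 parameters
  expect_identical(ncol(glance(f1)), 6L)

  expect_error(fit_hierarchical(syn$trials[syn$trials$participant_id == "p001", ]),
               "at least 2")
})

test_that("identical sessions shrink the group scales relative to a heterogeneous cohort", {
  set.seed(91)
  one <- simulate_rl_session(agent_parameters(0.7, 0.5, 1.5), seed = 13)
  copies <- purrr::map_dfr(1:8, function(i) {
    dplyr::mutate(one, participant_id = sprintf("c%02d", i))
  })
  cfg <- mcmc_config(n_chains = 2, n_warmup = 250, n_samples = 250, seed = 7)
  f_same <- suppressWarnings(fit_hierarchical(copies, cfg))

  het <- generate_cohort(generative_config(
    n_participants = 8,
    group_scales_raw = c(alpha_pos = 0.6, alpha_neg = 0.6, beta = 0.6)),
    seed = 91)
  f_het <- suppressWarnings(fit_hierarchical(het$trials, cfg))
  expect_lt(mean(f_same$group$sigma_raw), mean(f_het$group$sigma_raw))
})

test_that("MAP estimation recovers a long-horizon agent and stays interior", {
  set.seed(3)
  cfg <- task_config(n_trials = 500)
  sess <- simulate_rl_session(agent_parameters(0.6, 0.3, 3.0), cfg, "p1",
                              seed = 5)
  m <- fit_individual_map(sess, n_restarts = 5, seed = 9)
  expect_lt(abs(m$alpha_pos - 0.6), 0.15)
  expect_lt(abs(m$alpha_neg - 0.3), 0.15)
  expect_identical(m$convergence, 0L)

  # an extreme-beta agent still yields an interior estimate
  sharp <- simulate_rl_session(agent_parameters(0.6, 0.4, 8), cfg, "p2",
                               seed = 6)
  m2 <- fit_individual_map(sharp, n_restarts = 5, seed = 10)
  expect_lt(m2$beta, 9.99)
  expect_gt(m2$beta, 1)
})

test_that("partial pooling shrinks individuals from their MAP estimates toward the group", {
  set.seed(101)
  syn <- generate_cohort(generative_config(n_participants = 12), seed = 101)
  fit <- suppressWarnings(fit_hierarchical(
    syn$trials, mcmc_config(n_chains = 2, n_warmup = 400, n_samples = 400,
                            seed = 3)))
  map <- fit_individual_map(syn$trials, n_restarts = 3, seed = 4)
  est <- dplyr::left_join(fit$participants, map, by = "participant_id")

  between <- function(post, map_est, grp) {
    (post >= pmin(map_est, grp) - 1e-9) & (post <= pmax(map_est, grp) + 1e-9)
  }
  grp <- fit$group$native_mean
  frac <- mean(c(
    between(est$alpha_pos_mean, est$alpha_pos, grp[1]),
    between(est$alpha_neg_mean, est$alpha_neg, grp[2]),
    between(est$beta_mean, est$beta, grp[3])))
  expect_gt(frac, 0.5)

  # hierarchical means track the MAP ordering across participants
  expect_gt(cor(est$beta_mean, est$beta), 0)
})

test_that("posterior prediction from a guessing cohort centres on chance accuracy", {
  fake <- list(participants = tibble::tibble(
    participant_id = sprintf("p%d", 1:5),
    alpha_pos_mean = 0.5, alpha_pos_ci_low = 0.4, alpha_pos_ci_high = 0.6,
    alpha_neg_mean = 0.5, alpha_neg_ci_low = 0.4, alpha_neg_ci_high = 0.6,
    beta_mean = 0, beta_ci_low = 0, beta_ci_high = 0))
  pp <- posterior_predictive(fake, task_config(), n_reps = 10, seed = 12)
  expect_identical(nrow(pp), 50L)
  expect_lt(abs(mean(pp$accuracy) - 0.5), 0.05)
  pp2 <- posterior_predictive(fake, task_config(), n_reps = 10, seed = 12)
  expect_identical(pp, pp2)
})
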