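#' MCMC settings for the hierarchical fit
#'
#' @param n_chains Number of chains (default 4).
#' @param n_warmup Warmup (adaptation + burn-in) iterations per chain.
#' @param n_samples Retained iterations per chain (default 1000).
#' @param thin Thinning interval.
#' @param seed Integer seed; per-chain RNG seeds are derived from it
#'   deterministically (`seed * 100 + chain`).
#' @param rhat_threshold Convergence bound on the rank-normalized split
#'   R-hat (default 1.01).
#' @param beta_max Upper bound of the inverse-temperature transform.
#' @return A list of class `"prl_mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 4L, n_warmup = 1000L, n_samples = 1000L,
                        thin = 1L, seed = 1L, rhat_threshold = 1.01,
                        beta_max = 10) {
  stopifnot(n_chains >= 1, n_warmup >= 1, n_samples >= 1, thin >= 1,
            rhat_threshold > 1, beta_max > 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples),
                 thin = as.integer(thin),
                 seed = as.integer(seed),
                 rhat_threshold = rhat_threshold,
                 beta_max = beta_max),
            class = "prl_mcmc_config")
}

#' Map unconstrained parameters to the native scale (and back)
#'
#' Learning rates pass through the standard-normal CDF to (0, 1); the
#' inverse temperature passes through the CDF scaled by `beta_max`
#' (default 10) to (0, `beta_max`). This is the conventional transform for
#' this model class, so group-level distributions live on an unconstrained
#' scale while individual parameters respect their bounds by construction.
#'
#' @param raw Numeric vector `c(alpha_pos, alpha_neg, beta)` on the
#'   unconstrained scale, or a 3-column matrix.
#' @param beta_max Upper bound for the inverse temperature.
#' @return `to_native`: native-scale parameters (same shape, named);
#'   `from_native`: unconstrained parameters.
#' @export
to_native <- function(raw, beta_max = 10) {
  if (is.matrix(raw)) {
    return(cbind(alpha_pos = stats::pnorm(raw[, 1]),
                 alpha_neg = stats::pnorm(raw[, 2]),
                 beta = beta_max * stats::pnorm(raw[, 3])))
  }
  c(alpha_pos = stats::pnorm(raw[[1]]),
    alpha_neg = stats::pnorm(raw[[2]]),
    beta = beta_max * stats::pnorm(raw[[3]]))
}

#' @rdname to_native
#' @param params Native-scale parameters `c(alpha_pos, alpha_neg, beta)`.
#' @export
from_native <- function(params, beta_max = 10) {
  a_p <- params[[1]]; a_n <- params[[2]]; b <- params[[3]]
  if (a_p <= 0 || a_p >= 1 || a_n <= 0 || a_n >= 1 || b <= 0 || b >= beta_max) {
    stop("Native parameters outside (0,1) x (0,1) x (0, beta_max).",
         call. = FALSE)
  }
  c(alpha_pos = stats::qnorm(a_p), alpha_neg = stats::qnorm(a_n),
    beta = stats::qnorm(b / beta_max))
}

# internal: trial tibble -> padded matrices (ch: 1 = A, 2 = B) plus
# precomputed per-trial index sets used by the vectorized likelihood
trials_to_matrices <- function(trials) {
  check_trials(trials)
  ids <- unique(trials$participant_id)
  split_tr <- split(trials, factor(trials$participant_id, levels = ids))
  nt <- vapply(split_tr, nrow, integer(1))
  if (any(nt == 0L)) stop("A session with zero trials was supplied.", call. = FALSE)
  tmax <- max(nt)
  n <- length(ids)
  ch <- matrix(NA_integer_, n, tmax)
  out <- matrix(NA_real_, n, tmax)
  resp <- matrix(TRUE, n, tmax)
  for (i in seq_len(n)) {
    tr <- split_tr[[i]]
    if (any(diff(tr$trial) <= 0)) {
      stop("Non-monotone trial indices for participant ", ids[i], call. = FALSE)
    }
    ch[i, seq_len(nt[i])] <- ifelse(tr$choice == "A", 1L, 2L)
    out[i, seq_len(nt[i])] <- tr$outcome
    resp[i, seq_len(nt[i])] <- tr$responded == 1L
  }
  list(ids = ids, N = n, nt = nt, ch = ch, out = out, resp = resp,
       tmax = tmax)
}

# internal: cohort log-likelihood, vectorized across participants via the
# compiled kernel. raw: N x 3 unconstrained matrix. Returns a length-N
# vector. Tests assert equality with session_log_likelihood() (the pure-R
# reference route) participant by participant.
cohort_loglik <- function(raw, dat, beta_max = 10, censor_nonresponse = FALSE,
                          p_floor = 1e-12) {
  .cohort_loglik_cpp(raw, dat$ch, dat$out, dat$resp, dat$nt, beta_max,
                     censor_nonresponse, p_floor)
}

# half-normal log-density (prior for group scales)
lp_halfnorm <- function(x, sd) {
  ifelse(x > 0, stats::dnorm(x, 0, sd, log = TRUE) + log(2), -Inf)
}

# group-scale prior SDs: half-Normal(0.2) for learning rates,
# half-Normal(1) for the inverse temperature
sg_prior_sd <- c(0.2, 0.2, 1)

# internal: univariate slice sampler (stepping out + shrinkage)
slice_sample1 <- function(x0, log_target, w = 0.5, m = 20L) {
  f0 <- log_target(x0)
  y <- f0 + log(stats::runif(1))
  lo <- x0 - w * stats::runif(1)
  hi <- lo + w
  j <- floor(m * stats::runif(1)); k <- (m - 1) - j
  while (j > 0 && y < log_target(lo)) { lo <- lo - w; j <- j - 1 }
  while (k > 0 && y < log_target(hi)) { hi <- hi + w; k <- k - 1 }
  repeat {
    x1 <- lo + stats::runif(1) * (hi - lo)
    if (y < log_target(x1)) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
    if (hi - lo < 1e-12) return(x0)
  }
}

# internal: one MCMC chain. Adaptive Metropolis-within-Gibbs with
# interweaved centered / non-centered group updates:
#  (a) elementwise random-walk plus group-distribution independence
#      updates of each unconstrained individual-parameter column (all
#      participants in one compiled likelihood pass);
#  (b) conjugate Gibbs update of each group location (centered);
#  (c) random-walk update of each group scale on the log scale (centered);
#  (d) non-centered slice updates of each group location and log scale
#      holding the standardized individual effects fixed, which moves the
#      whole column through the likelihood. The interweaving keeps mixing
#      healthy in the funnel regime where group scales are small.
run_prl_chain <- function(dat, mcmc, chain, censor_nonresponse = FALSE) {
  set.seed(mcmc$seed * 100L + chain)
  n <- dat$N
  n_iter <- mcmc$n_warmup + mcmc$n_samples * mcmc$thin
  mu <- stats::rnorm(3, 0, 0.5)
  sg <- abs(stats::rnorm(3, 0, c(0.2, 0.2, 0.5))) + 0.05
  raw <- sapply(1:3, function(k) stats::rnorm(n, mu[k], sg[k]))
  ll <- cohort_loglik(raw, dat, mcmc$beta_max, censor_nonresponse)
  s_ind <- matrix(0.4, n, 3)       # individual RW proposal SDs
  s_sg <- rep(0.2, 3)              # log-scale RW proposal SDs
  s_grp <- rep(0.15, 3)            # interweaved group proposal SDs
  keep <- matrix(NA_real_, mcmc$n_samples, 6L + 3L * n + 1L)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    adapting <- it <= mcmc$n_warmup
    gam <- if (adapting) min(0.1, 5 / sqrt(it)) else 0
    # (a) individual-level updates, one column at a time: a random-walk
    # pass, then an independence pass proposing from the group
    # distribution (efficient when a participant's data are weak)
    for (k in 1:3) {
      prop <- raw
      prop[, k] <- raw[, k] + s_ind[, k] * stats::rnorm(n)
      llp <- cohort_loglik(prop, dat, mcmc$beta_max, censor_nonresponse)
      logr <- (llp - ll) +
        stats::dnorm(prop[, k], mu[k], sg[k], log = TRUE) -
        stats::dnorm(raw[, k], mu[k], sg[k], log = TRUE)
      acc <- log(stats::runif(n)) < logr
      raw[acc, k] <- prop[acc, k]
      ll[acc] <- llp[acc]
      if (adapting) {
        s_ind[, k] <- s_ind[, k] * exp(gam * (ifelse(acc, 1, 0) - 0.44))
      }
      # independence proposal: prior and proposal terms cancel
      prop <- raw
      prop[, k] <- stats::rnorm(n, mu[k], sg[k])
      llp <- cohort_loglik(prop, dat, mcmc$beta_max, censor_nonresponse)
      acc <- log(stats::runif(n)) < (llp - ll)
      raw[acc, k] <- prop[acc, k]
      ll[acc] <- llp[acc]
    }
    # (b) group locations: conjugate normal Gibbs (prior N(0, 1))
    for (k in 1:3) {
      v <- 1 / (1 + n / sg[k]^2)
      mu[k] <- stats::rnorm(1, v * sum(raw[, k]) / sg[k]^2, sqrt(v))
    }
    # (c) group scales: random walk on log(sg), half-normal prior
    for (k in 1:3) {
      lsg_p <- log(sg[k]) + s_sg[k] * stats::rnorm(1)
      sgp <- exp(lsg_p)
      logr <- sum(stats::dnorm(raw[, k], mu[k], sgp, log = TRUE)) -
        sum(stats::dnorm(raw[, k], mu[k], sg[k], log = TRUE)) +
        lp_halfnorm(sgp, sg_prior_sd[k]) - lp_halfnorm(sg[k], sg_prior_sd[k]) +
        lsg_p - log(sg[k])  # Jacobian of the log transform
      acc <- log(stats::runif(1)) < logr
      if (acc) sg[k] <- sgp
      if (adapting) s_sg[k] <- s_sg[k] * exp(gam * (as.numeric(acc) - 0.44))
    }
    # (d) non-centered slice updates of mu and log(sg), z held fixed
    for (k in 1:3) {
      z <- (raw[, k] - mu[k]) / sg[k]
      col_ll <- function(col) {
        prop <- raw
        prop[, k] <- col
        cohort_loglik(prop, dat, mcmc$beta_max, censor_nonresponse)
      }
      mu[k] <- slice_sample1(mu[k], function(m_) {
        sum(col_ll(m_ + sg[k] * z)) + stats::dnorm(m_, 0, 1, log = TRUE)
      }, w = s_grp[k])
      lsg <- slice_sample1(log(sg[k]), function(ls_) {
        s_ <- exp(ls_)
        sum(col_ll(mu[k] + s_ * z)) + lp_halfnorm(s_, sg_prior_sd[k]) + ls_
      }, w = s_grp[k])
      sg[k] <- exp(lsg)
      raw[, k] <- mu[k] + sg[k] * z
      ll <- cohort_loglik(raw, dat, mcmc$beta_max, censor_nonresponse)
    }
    if (!adapting && (it - mcmc$n_warmup) %% mcmc$thin == 0L) {
      kept <- kept + 1L
      nat <- to_native(raw, mcmc$beta_max)
      keep[kept, ] <- c(mu, sg, nat[, 1], nat[, 2], nat[, 3], -2 * sum(ll))
    }
  }
  colnames(keep) <- c(paste0("mu[", 1:3, "]"), paste0("sg[", 1:3, "]"),
                      paste0("ap[", seq_len(n), "]"),
                      paste0("an[", seq_len(n), "]"),
                      paste0("bt[", seq_len(n), "]"),
                      "deviance")
  coda::mcmc(keep, start = mcmc$n_warmup + 1L, thin = mcmc$thin)
}

#' Hierarchical Bayesian fit of the three-parameter model
#'
#' Fits the asymmetric-learning-rate softmax model to a cohort of sessions
#' by MCMC with partial pooling: on the unconstrained scale each
#' participant's parameter triple is drawn from a group normal
#' distribution, so the group distribution constrains improbable
#' individual estimates. Priors: group locations ~ Normal(0, 1); group
#' scales half-Normal(0.2) for the learning rates and half-Normal(1) for
#' the inverse temperature; individual effects ~ Normal(0, 1) after
#' standardization.
#'
#' The sampler is an adaptive Metropolis-within-Gibbs scheme with
#' vectorized elementwise updates of the individual parameters, conjugate
#' Gibbs updates of the group locations, and interweaved centered /
#' non-centered group-scale moves (the non-centered move rescales a whole
#' parameter column holding the standardized effects fixed, which keeps
#' mixing healthy when group scales are small). Proposal scales adapt
#' during warmup only, leaving the post-warmup chain a valid fixed-kernel
#' Markov chain.
#'
#' Convergence is assessed with the rank-normalized split R-hat for every
#' monitored quantity; a warning (not an error) lists parameters at or
#' above the threshold.
#'
#' @param trials Trial tibble for two or more participants.
#' @param mcmc A [mcmc_config()].
#' @param censor_nonresponse Drop computer-selected (non-response) trials
#'   from the likelihood sum (values still update on them).
#' @return An object of class `"prl_hfit"`: a list with `participants`
#'   (per-participant posterior means and 95% credible intervals on the
#'   native scale), `group` (group-level location/scale summaries, raw and
#'   native), `rhat`, `ess`, `draws` (a [coda::mcmc.list] including the
#'   model deviance), `data`, and the `mcmc` settings.
#' @export
#' @examples
#' \donttest{
#' syn <- generate_cohort(generative_config(n_participants = 8), seed = 1)
#' fit <- fit_hierarchical(syn$trials,
#'                         mcmc_config(n_warmup = 200, n_samples = 200))
#' glance(fit)
#' }
fit_hierarchical <- function(trials, mcmc = mcmc_config(),
                             censor_nonresponse = FALSE) {
  dat <- trials_to_matrices(trials)
  if (dat$N < 2L) {
    stop("Hierarchical fitting needs at least 2 participants.", call. = FALSE)
  }
  draws <- coda::mcmc.list(lapply(seq_len(mcmc$n_chains), function(chain) {
    run_prl_chain(dat, mcmc, chain, censor_nonresponse)
  }))
  fit <- build_hfit(draws, dat, mcmc)
  bad <- names(fit$rhat)[fit$rhat >= mcmc$rhat_threshold]
  if (length(bad)) {
    warning("R-hat at or above ", mcmc$rhat_threshold, " for: ",
            paste(utils::head(bad, 10), collapse = ", "),
            if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10),
            call. = FALSE)
  }
  fit
}

# internal: assemble the prl_hfit object from an mcmc.list
build_hfit <- function(draws, dat, mcmc) {
  mat <- do.call(rbind, lapply(draws, as.matrix))
  vars <- setdiff(colnames(mat), "deviance")
  rhat <- vapply(vars, function(v) {
    rhat_rank_normalized(sapply(draws, function(ch) as.numeric(ch[, v])))
  }, numeric(1))
  ess <- tryCatch(coda::effectiveSize(draws[, vars]), error = function(e) NULL)

  q <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  per_part <- function(prefix) {
    cols <- paste0(prefix, "[", seq_len(dat$N), "]")
    m <- mat[, cols, drop = FALSE]
    list(mean = colMeans(m),
         lo = apply(m, 2, function(x) q(x)[1]),
         hi = apply(m, 2, function(x) q(x)[2]))
  }
  ap <- per_part("ap"); an <- per_part("an"); bt <- per_part("bt")
  participants <- tibble::tibble(
    participant_id = dat$ids,
    alpha_pos_mean = unname(ap$mean), alpha_pos_ci_low = unname(ap$lo),
    alpha_pos_ci_high = unname(ap$hi),
    alpha_neg_mean = unname(an$mean), alpha_neg_ci_low = unname(an$lo),
    alpha_neg_ci_high = unname(an$hi),
    beta_mean = unname(bt$mean), beta_ci_low = unname(bt$lo),
    beta_ci_high = unname(bt$hi)
  )
  par_names <- c("alpha_pos", "alpha_neg", "beta")
  nat_scale <- c(1, 1, mcmc$beta_max)
  group <- purrr::map_dfr(1:3, function(k) {
    mu_d <- mat[, paste0("mu[", k, "]")]
    sg_d <- mat[, paste0("sg[", k, "]")]
    nat <- nat_scale[k] * stats::pnorm(mu_d / sqrt(1 + sg_d^2))
    tibble::tibble(parameter = par_names[k],
                   mu_raw = mean(mu_d), sigma_raw = mean(sg_d),
                   native_mean = mean(nat),
                   native_ci_low = q(nat)[1], native_ci_high = q(nat)[2])
  })
  structure(list(participants = participants, group = group,
                 rhat = rhat, ess = ess, draws = draws,
                 data = dat[c("ids", "N", "nt")], mcmc = mcmc),
            class = "prl_hfit")
}

#' @export
print.prl_hfit <- function(x, ...) {
  cat("<prl_hfit> hierarchical fit,", x$data$N, "participants\n")
  cat(sprintf("  max rank-normalized split R-hat: %.4f (threshold %.3f)\n",
              max(x$rhat), x$mcmc$rhat_threshold))
  print(x$group)
  invisible(x)
}

#' Rank-normalized split R-hat
#'
#' The current-standard convergence diagnostic: draws are rank-transformed
#' across all chains, mapped through the normal quantile function, each
#' chain is split in half, and the classic potential-scale-reduction
#' factor is computed on the split halves. The statistic is also computed
#' on folded draws (absolute deviations from the median, sensitive to
#' scale differences) and the larger of the two is returned.
#'
#' @param x Iterations-by-chains numeric matrix of posterior draws.
#' @return The R-hat value (NA for constant draws).
#' @export
rhat_rank_normalized <- function(x) {
  x <- as.matrix(x)
  base <- function(m) {
    n <- nrow(m)
    h <- floor(n / 2)
    m <- cbind(m[seq_len(h), , drop = FALSE],
               m[(n - h + 1):n, , drop = FALSE])
    n <- h; nc <- ncol(m)
    if (stats::var(as.numeric(m)) == 0) return(NA_real_)
    r <- rank(m, ties.method = "average")
    zm <- matrix(stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4)), n, nc)
    w <- mean(apply(zm, 2, stats::var))
    b <- n * stats::var(colMeans(zm))
    sqrt((n - 1) / n + b / (w * n))
  }
  vals <- c(base(x), base(abs(x - stats::median(x))))
  if (all(is.na(vals))) return(NA_real_)
  max(vals, na.rm = TRUE)
}

#' Check MCMC convergence against an R-hat threshold
#'
#' @param fit A `"prl_hfit"` object (or any list with an `rhat` vector).
#' @param threshold R-hat bound; defaults to the fit's configured threshold.
#' @return A list with `pass` (logical) and `offending` (tibble of
#'   parameter names and R-hat values at or above the threshold).
#' @export
convergence_check <- function(fit, threshold = NULL) {
  if (is.null(fit$rhat) || !length(fit$rhat)) {
    stop("No R-hat diagnostics found on this object.", call. = FALSE)
  }
  if (is.null(threshold)) threshold <- fit$mcmc$rhat_threshold %||% 1.01
  bad <- fit$rhat[fit$rhat >= threshold]
  list(pass = length(bad) == 0L,
       offending = tibble::tibble(parameter = names(bad),
                                  rhat = unname(bad)))
}

#' Maximum a posteriori fit for a single participant
#'
#' Non-hierarchical cross-check for [fit_hierarchical()]: maximizes the
#' session log-likelihood plus independent standard-normal priors on the
#' unconstrained scale, over several random restarts.
#'
#' @param trials Trial tibble; may contain several participants, each fit
#'   independently.
#' @param n_restarts Random restarts per participant.
#' @param beta_max Upper bound of the inverse-temperature transform.
#' @param seed Optional seed for the restart initializations.
#' @return Tibble with one row per participant: native-scale estimates,
#'   the attained log-posterior, and the optimizer convergence code.
#' @export
fit_individual_map <- function(trials, n_restarts = 5L, beta_max = 10,
                               seed = NULL) {
  check_trials(trials)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(trials$participant_id)
  purrr::map_dfr(ids, function(id) {
    tr <- trials[trials$participant_id == id, ]
    neg_post <- function(raw) {
      p <- to_native(raw, beta_max)
      -(session_log_likelihood(tr, p[["alpha_pos"]], p[["alpha_neg"]],
                               p[["beta"]]) +
          sum(stats::dnorm(raw, 0, 1, log = TRUE)))
    }
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- stats::rnorm(3, 0, 1)
      opt <- tryCatch(stats::optim(init, neg_post, method = "Nelder-Mead",
                                   control = list(maxit = 2000)),
                      error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    }
    if (is.null(best)) {
      stop("MAP optimization failed on all restarts for participant ", id,
           call. = FALSE)
    }
    p <- to_native(best$par, beta_max)
    tibble::tibble(participant_id = id,
                   alpha_pos = p[["alpha_pos"]], alpha_neg = p[["alpha_neg"]],
                   beta = p[["beta"]], log_posterior = -best$value,
                   convergence = best$convergence)
  })
}

#' Posterior-predictive behavioral summaries
#'
#' Simulates fresh task sessions at each participant's posterior-mean
#' parameters and summarizes the behavior, for qualitative comparison with
#' observed accuracy and reversal counts.
#'
#' @param fit A `"prl_hfit"` object.
#' @param config A [task_config()] used for the simulated sessions.
#' @param n_reps Simulated sessions per participant.
#' @param seed Optional seed.
#' @return Tibble with `participant_id`, `rep`, `accuracy`, `n_reversals`.
#' @export
posterior_predictive <- function(fit, config = task_config(), n_reps = 10L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pp <- fit$participants
  purrr::map_dfr(seq_len(nrow(pp)), function(i) {
    pars <- agent_parameters(pp$alpha_pos_mean[i], pp$alpha_neg_mean[i],
                             pp$beta_mean[i])
    purrr::map_dfr(seq_len(n_reps), function(r) {
      sess <- simulate_rl_session(pars, config,
                                  participant_id = pp$participant_id[i])
      sm <- summarize_behavior(sess)
      tibble::tibble(participant_id = pp$participant_id[i], rep = r,
                     accuracy = sm$accuracy, n_reversals = sm$n_reversals)
    })
  })
}
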