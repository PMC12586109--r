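---
title: "Models and methods behind prlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prlearn)
```

prlearn studies how people learn from probabilistic reward and punishment,
and how socioeconomic adversity relates to that learning. This vignette is
the package's account of its models, its estimation machinery, and the
design decisions behind both.

## The probabilistic reversal learning task

Participants repeatedly choose between two stimuli, A and B. One is
*correct*: it wins with probability 0.75 and loses with probability 0.25;
the other has the reversed contingencies. After a run of consecutive
correct choices whose required length is drawn uniformly from {5, 6} — and
redrawn after every reversal, so the moment of reversal cannot be
anticipated — the designation flips. At most 10 reversals can occur in a
60-trial session; after the cap the contingencies stay fixed. The number
of achieved reversals is the task's behavioral index of adaptive learning.

Design decisions where the task description leaves room:

* "Consecutive correct" counts choices of the currently correct stimulus,
  not rewarded trials — probabilistic feedback would otherwise make a
  "correct" run depend on outcome luck.
* The run counter resets to zero after a reversal (standard convention for
  this task family) and after any incorrect choice.
* An always-correct agent could in principle reach 12 reversals at
  criterion 5 in 60 trials; the cap of 10 is enforced as a hard rule.
* Timing fields (response window 1500 ms, highlight 500 ms, outcome delay
  500–1500 ms, outcome display 1000 ms, inter-trial interval 500–1500 ms)
  are metadata. `expected_trial_duration()` sums the fixed components and
  the range midpoints, giving 5000 ms for the defaults; the simulator
  never waits in real time.
* Simulated agents always respond; the `responded` flag exists for
  imported data, where a non-response means the computer chose randomly
  and the reaction time is recorded as the full window.

## The three-parameter learning model

On trial $t$ the agent holds expected values $EV$ for both stimuli
(initialized to 0, so the first choice is a coin flip). After receiving
outcome $R_t \in \{+1, -1\}$ (win/loss; display currency is irrelevant to
the model) for the chosen stimulus:

$$PE_t = R_t - EV_{t-1}, \qquad
  EV_t = EV_{t-1} + \alpha \times PE_t$$

with $\alpha = \alpha^{+}$ (reward learning rate) when $PE_t > 0$ and
$\alpha = \alpha^{-}$ (punishment learning rate) when $PE_t \le 0$ — an
outcome no better than expected engages the punishment system. Only the
chosen stimulus's value is updated; the other is carried forward unchanged
(no decay or fictive update). Choice follows a softmax with inverse
temperature $\beta \ge 0$:

$$P(A_t) = \frac{1}{1 + e^{-\beta\,(EV_A - EV_B)}}.$$

With $\alpha^{+} = \alpha^{-}$ the model collapses exactly to the classic
single-rate Rescorla–Wagner + softmax model, which the tests exploit as an
independent oracle. Expected values stay inside $[-1, 1]$ by convexity.

One behavioral regularity worth knowing: mean accuracy on the default
task rises with $\beta$ only in the exploratory regime (roughly
$\beta \lesssim 3$ at these learning rates). At large $\beta$ the
combination of near-deterministic choice and sizable learning rates turns
the agent into a lose-shifter that abandons the correct stimulus after
every probabilistic loss, and accuracy falls back toward chance. The
property tests therefore assert the accuracy trend over
$\beta \in \{0, 0.8, 2\}$ rather than globally.

Numerical choices: choice probabilities are floored at $10^{-12}$ before
logs, which guards extreme-$\beta$ proposals during sampling without
materially changing any likelihood; computer-selected choices on
non-response trials enter the likelihood by default (keeping it defined on
all 60 trials), with `censor_nonresponse = TRUE` dropping their likelihood
terms while still updating values — the participant saw the outcome either
way.

## Hierarchical Bayesian estimation

Each participant's triple $(\alpha^{+}, \alpha^{-}, \beta)$ lives on an
unconstrained scale through the standard probit-style transform:
$\alpha = \Phi(raw)$ and $\beta = 10\,\Phi(raw)$. The group model is
normal on that scale with priors

* group locations $\mu_k \sim \mathcal{N}(0, 1)$,
* group scales $\sigma_k \sim$ half-$\mathcal{N}(0.2)$ for the learning
  rates and half-$\mathcal{N}(1)$ for the inverse temperature,
* standardized individual effects $z_{ik} \sim \mathcal{N}(0, 1)$.

These match the conventions of the hierarchical toolkits commonly used
for this model class; the $\beta$ upper bound of 10 is far above the
group means encountered here (~1.4). Partial pooling shrinks poorly
informed individual estimates toward the group distribution, which the
test suite checks directly against non-hierarchical MAP fits.

### The sampler

`fit_hierarchical()` uses a purpose-built adaptive
Metropolis-within-Gibbs scheme with the cohort likelihood compiled in
C++:

1. elementwise random-walk updates of each individual-parameter column
   (all participants in one vectorized likelihood pass), followed by an
   independence pass proposing from the current group distribution —
   efficient precisely when a participant's 60 trials say little;
2. conjugate Gibbs updates of the group locations (centered form);
3. random-walk updates of the log group scales (centered form);
4. slice-sampled non-centered updates of each group location and log
   scale holding the standardized effects fixed, which moves a whole
   parameter column through the likelihood at once.

The interweaving of centered and non-centered moves (step 2–3 vs step 4)
is what keeps mixing healthy in the funnel regime where a group scale is
small; either family alone stalls there. Proposal scales adapt during
warmup only (Robbins–Monro, targets 0.44 for scalar moves), so the
post-warmup chain is a valid fixed-kernel Markov chain. One top-level
seed fans out deterministically to per-chain seeds (`seed * 100 +
chain`).

Convergence is judged by the rank-normalized split R-hat (computed on
rank-normalized and on folded draws, taking the larger), with the
conventional threshold of 1.01 for every monitored quantity; failures
warn and name the offending parameters rather than erroring. Effective
sample sizes come from `coda`. Defaults are 4 chains with 1000 warmup and
1000 retained iterations; the recovery analyses below use 2000 warmup
with 3000 post-warmup iterations thinned to 1500, which brings all R-hat
below 1.01 at the reference cohort size in four to five minutes (at
shorter runs a single group-scale parameter occasionally sits at
1.01–1.015, diagnostic noise at moderate effective sample size rather
than genuine non-convergence).

The MAP cross-check (`fit_individual_map()`) maximizes each session's
log-likelihood plus independent standard-normal priors on the
unconstrained scale over random restarts. It recovers long-horizon agents
(500 trials) to within ±0.15 on the learning rates and serves as the
no-pooling reference point for shrinkage tests.

## The synthetic cohort generator

The generator defines the study conditions used throughout the tests:
95 participants, 60 trials, and a socioeconomic layer with known ground
truth.

* **Hardship and income.** A latent bivariate standard normal per
  participant with correlation −0.417. The hardship factor is expanded
  into four Likert items (food insecurity, clothing, entertainment,
  housing stability) by adding item noise calibrated from the
  equal-loading identity $\alpha = k r / (1 + (k-1) r)$ so the scale's
  Cronbach's α is ≈ 0.83, then discretized at fixed Gaussian quantiles
  with marginal probabilities (0.40, 0.30, 0.15, 0.10, 0.05) — a
  right-skewed item distribution whose 4-item *sum* has mean ≈ 8.4 and SD
  ≈ 3.6, close to the reference scale summaries (the composite is the
  sum; reported scale moments are only consistent with a sum, and
  standardization makes the choice immaterial to standardized
  coefficients). Income is the second latent coordinate discretized into
  7 levels with probabilities (0.10, 0.18, 0.22, 0.20, 0.14, 0.09, 0.07),
  mean ≈ 3.65 and SD ≈ 1.7. The latent correlation is the configured
  −0.417 exactly; item noise and discretization attenuate the *observed*
  composite–income correlation to ≈ −0.36 at large n. The configuration
  deliberately pins the latent (structural) correlation rather than
  inflating it to chase the observed value, and the calibration tests
  band the observed correlation accordingly.
* **Ages** are uniform over 18–20 and **gender** is Bernoulli(0.6)
  female, matching the reference cohort's composition.
* **True parameters.** On the unconstrained scale,
  $raw^{-}_i = \mu_2 + \sigma_2 (b\, z_i + \sqrt{1-b^2}\,\varepsilon_i)$
  where $z_i$ is the standardized hardship composite and $b = 0.24$ is
  the standardized hardship → punishment-learning-rate effect; reward
  learning rate and inverse temperature are independent of all
  covariates. Locations are set to $\Phi^{-1}(m_k)\sqrt{1+\sigma_k^2}$ so
  the *native-scale* group means equal (0.72, 0.54, 1.36) exactly in
  expectation. An optional allocation concentrates the effect on the
  housing-instability item instead of the composite, emulating subdomain
  analyses.
* **Group scales** on the unconstrained scale default to
  (0.25, 0.22, 0.28). The punishment-rate and inverse-temperature values
  are calibrated so the implied native SDs (≈ 0.09 and ≈ 0.62) match the
  reference cohort's dispersion. The reported reward-learning-rate SD in
  that cohort (≈ 0.01) reflects post-shrinkage spread of posterior means,
  not generative heterogeneity — taken literally it would make recovery
  correlations undefined in practice — so the reward-rate scale is set
  comparable to the punishment-rate scale instead.

What the generator does *not* emulate: reaction times, missing data,
demographic covariance beyond the stated correlations, and any
non-Gaussian structure in the hardship items — the Gaussian-latent item
model is a stand-in, not a reproduction. Passing tests therefore speak to
the pipeline's internal consistency and calibration under these
conditions, not to distributional quirks of real cohorts.

## The statistical layer

Three standardized regressions relate the fitted parameters to material
hardship and household income with age and gender as covariates, entered
simultaneously. Every variable (binary indicators included) is z-scored
before ordinary least squares, so all coefficients read as standardized
effects; confidence intervals and p-values come from the usual OLS
sampling distribution, and variance inflation factors are computed from
first principles as $1/(1-R^2_j)$. The Benjamini–Hochberg FDR family is
the hardship coefficient's three p-values across the three models — the
three primary dependent variables. Correlation intervals use the Fisher-z
method (the method behind `cor.test`); tests are two-sided at α = 0.05.

## Calibration results and problem sizes

The test suite and the acceptance script work at these scales, chosen to
make each check informative while keeping a full run comfortable on one
CPU:

* Generator calibration (correlation, reliability, regression-effect
  recovery on true parameters) at n = 5000 — Monte-Carlo error on a
  standardized coefficient is then ≈ 0.014.
* Parameter recovery at the reference conditions, 95 participants × 60
  trials. A 20-replicate pilot at exactly these settings fixed the
  acceptance thresholds for the truth-vs-estimate correlations. Across
  the pilot the correlations were ≈ 0.82 (range 0.70–0.88) for β,
  ≈ 0.29 (range 0.12–0.43) for the punishment learning rate, and ≈ 0.19
  (range 0.01–0.40) for the reward learning rate: with only 60 noisy
  trials at β ≈ 1.4, individual reward-rate estimates are shrinkage-
  dominated, and a single cohort cannot guarantee materially positive
  recovery for that parameter. The per-cohort thresholds (−0.05, 0.08,
  0.65) are the pilot's lower envelope with margin.
* Type-I calibration of the end-to-end pipeline (generate → fit →
  regress under a null hardship effect) over 12 scaled-down replicate
  cohorts (40 participants, 2 short chains): under the null, estimation
  noise in the fitted punishment rate is independent of hardship, so the
  nominal 5% level holds regardless of fit precision, and the test counts
  rejections against the binomial band.

## Known limitations

* The model omits reward/punishment sensitivity scaling, decay or
  forgetting, and choice-perseveration kernels; with 60 trials per
  participant, richer models are not identifiable anyway.
* Individual learning-rate estimates at 60 trials are dominated by the
  group posterior; between-participant correlations with covariates are
  attenuated relative to the generating effect. The package's
  true-parameter regression quantifies the undiluted effect; the
  estimated-parameter regression shows what a study of this size can
  resolve.
* The sampler is specialized to this model family; it is not a generic
  probabilistic-programming backend.
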