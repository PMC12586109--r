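# prlearn

Reinforcement learning under probabilistic reward and punishment, and its
relation to socioeconomic adversity.

Studies in computational psychiatry increasingly ask whether conditions
like material hardship (concrete deprivation: food insecurity, unstable
housing) change *how* people learn from feedback, over and above income.
The standard paradigm is a probabilistic reversal learning (PRL) task —
two stimuli, one "correct" (75% win / 25% loss), contingencies silently
reversing after 5–6 consecutive correct choices — with behavior modeled
by a reinforcement-learning model whose parameters are then regressed on
socioeconomic indicators. `prlearn` implements that whole pipeline as a
tested, reusable R package, with a synthetic-cohort generator providing
ground truth so every stage can be validated end to end.

## The model

On each trial the agent updates the expected value of the chosen
stimulus from the prediction error, with separate learning rates for
good and bad surprises:

$$PE_t = R_t - EV_{t-1}, \qquad EV_t = EV_{t-1} + \alpha \, PE_t,$$

where $R_t \in \{+1,-1\}$, $\alpha = \alpha^{+}$ (reward learning rate)
if $PE_t > 0$ and $\alpha = \alpha^{-}$ (punishment learning rate) if
$PE_t \le 0$. Choices follow a softmax with inverse temperature $\beta$:

$$P(A_t) = \bigl(1 + e^{-\beta (EV_A - EV_B)}\bigr)^{-1}.$$

Per-participant triples $(\alpha^{+}, \alpha^{-}, \beta)$ are estimated
by hierarchical Bayesian MCMC with partial pooling (probit-transformed
parameters, normal group distributions, adaptive Metropolis-within-Gibbs
with interweaved centered/non-centered group moves and a compiled
likelihood; convergence judged by rank-normalized split R-hat < 1.01).
A non-hierarchical MAP fit serves as a cross-check. The statistical
layer provides one-sample *t* tests with Cohen's *d*, Pearson
correlations, standardized multiple regression with variance inflation
factors, and Benjamini–Hochberg FDR adjustment.

See `vignettes/prl-methods.Rmd` for the full account of the models,
priors, sampler, and generator calibration.

## Worked example

Simulate a small cohort with a known hardship → punishment-learning
effect, fit the hierarchical model, and run the socioeconomic
regressions:

```r
library(prlearn)

syn <- generate_cohort(generative_config(n_participants = 20), seed = 1)
summarize_behavior(syn$trials)
#> # A tibble: 20 × 5
#>   participant_id n_trials accuracy n_reversals mean_rt_ms
#>   <chr>             <int>    <dbl>       <int>      <dbl>
#> 1 p001                 60    0.683           5         NA
#> 2 p002                 60    0.7             3         NA
#> 3 p003                 60    0.467           3         NA
#> 4 p004                 60    0.6             3         NA
#> # i 16 more rows

fit <- fit_hierarchical(syn$trials,
        mcmc_config(n_chains = 2, n_warmup = 500, n_samples = 500, seed = 2))
fit$group
#> # A tibble: 3 × 6
#>   parameter  mu_raw sigma_raw native_mean native_ci_low native_ci_high
#>   <chr>       <dbl>     <dbl>       <dbl>         <dbl>          <dbl>
#> 1 alpha_pos  1.07       0.173       0.827         0.623          0.989
#> 2 alpha_neg  0.0229     0.214       0.509         0.361          0.650
#> 3 beta      -1.15       0.287       1.37          1.04           1.77
```

The behavioral summaries show accuracies around 0.6–0.7 and a few
achieved reversals per 60-trial session; the group-level posterior means
land near the generating values (0.72, 0.54, 1.36) even at this demo
size (at 2 short chains the `glance(fit)` diagnostics flag incomplete
convergence — production settings are 4 chains × 1500/1500). Joining the
estimates back onto the covariates and regressing:

```r
cohort <- dplyr::left_join(syn$cohort, fit$participants, by = "participant_id") |>
  dplyr::rename(hardship = hardship_composite)
analyze_cohort(cohort,
               outcomes = c("alpha_pos_mean", "alpha_neg_mean", "beta_mean")) |>
  dplyr::filter(term == "hardship")
#> # A tibble: 3 × 9
#>   outcome        r_squared term     estimate ci_low ci_high      p   vif p_fdr
#>   <chr>              <dbl> <chr>       <dbl>  <dbl>   <dbl>  <dbl> <dbl> <dbl>
#> 1 alpha_pos_mean     0.237 hardship  -0.291  -0.948  0.367  0.361   1.87 0.542
#> 2 alpha_neg_mean     0.144 hardship  -0.0285 -0.725  0.668  0.932   1.87 0.932
#> 3 beta_mean          0.364 hardship  -0.555  -1.16   0.0453 0.0675  1.87 0.203
```

One row per predictor per learning parameter, with standardized
coefficients, 95% CIs, VIFs, and the BH-adjusted p-values for the focal
hardship coefficients (at n = 20 the estimates are dominated by noise —
the package's calibration tests work at n = 95–5000).

`pipeline_simulate()`, `pipeline_fit()`, `pipeline_recover()` and
`pipeline_analyze()` run the same stages over CSV artifacts with a
reproducibility manifest, and `plot_recovery()` /
`plot_regression_table()` / `plot_trajectory()` visualize the results.

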