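test_that("one-sample t test reproduces hand arithmetic and reported values", {
  # hand check: se = 0.1/sqrt(25) = 0.02; t = 0.1/0.02 = 5
  r <- one_sample_t(0.6, 0.1, 25, mu0 = 0.5)
  expect_equal(r$t, 5)
  expect_equal(r$df, 24)
  expect_equal(r$d, 1)

  # published accuracy-vs-chance test
  r <- one_sample_t(0.694, 0.067, 95, mu0 = 0.5)
  expect_equal(round(r$t, 2), 28.22)
  expect_lt(abs(r$d - 2.895), 0.001)
  expect_lt(r$p, 0.001)

  z <- one_sample_t(0.5, 0.067, 95, mu0 = 0.5)
  expect_equal(z$t, 0)
  expect_equal(z$d, 0)

  expect_error(one_sample_t(0.6, 0, 25, 0.5), "sd")
  expect_error(one_sample_t(0.6, 0.1, 1, 0.5), "n")
})

test_that("one-sample t test is invariant to the measurement unit", {
  prop <- one_sample_t(0.694, 0.067, 95, mu0 = 0.5)
  pct <- one_sample_t(69.4, 6.7, 95, mu0 = 50)
  expect_equal(prop$t, pct$t, tolerance = 1e-12)
  expect_equal(prop$d, pct$d, tolerance = 1e-12)
  expect_equal(prop$p, pct$p, tolerance = 1e-12)
})

test_that("correlation machinery matches the t-transform and Fisher interval", {
  # hand check: t = 0.5 * sqrt(10) / sqrt(0.75)
  r <- pearson_p_from_r(0.5, 12)
  expect_equal(r$t, 0.5 * sqrt(10) / sqrt(0.75), tolerance = 1e-12)
  expect_equal(r$t, 1.8257419, tolerance = 1e-6)

  # reported hardship / punishment-learning-rate correlation
  r <- pearson_p_from_r(0.261, 95)
  expect_equal(round(r$p, 3), 0.011)

  set.seed(2)
  x <- rnorm(40); y <- x + rnorm(40)
  pc <- pearson_cor(x, y)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  expect_true(pc$ci_low <= pc$r && pc$r <= pc$ci_high)
  # affine invariance
  pc2 <- pearson_cor(3 * x - 7, 0.1 * y + 2)
  expect_equal(pc$r, pc2$r, tolerance = 1e-12)
  expect_equal(pc$p, pc2$p, tolerance = 1e-12)

  expect_error(pearson_cor(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_cor(rnorm(5), rnorm(6)), "length")
})

test_that("Benjamini-Hochberg adjustment matches the step-up rule", {
  # published family: the hardship p-values across the three models
  adj <- bh_fdr(c(0.773, 0.036, 0.560))
  expect_equal(min(adj), 0.108, tolerance = 1e-12)
  expect_equal(adj, c(0.773, 0.108, 0.773), tolerance = 1e-12)

  # hand application of the step-up rule
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)

  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.5, -0.1)), "0, 1")
})

test_that("BH adjustment is order-preserving and bounded", {
  # (step-up adjustment is deliberately not idempotent: re-adjusting an
  # already-adjusted vector inflates it again, e.g. (0.1, 0.9) ->
  # (0.2, 0.9) -> (0.4, 0.9))
  set.seed(6)
  for (rep in 1:10) {
    p <- runif(sample(3:12, 1))
    adj <- bh_fdr(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # monotone: sorting by raw p sorts the adjusted values too
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("VIF matches closed forms and flags collinearity", {
  # exactly orthogonal predictors
  X <- data.frame(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(X)), c(1, 1), tolerance = 1e-12)

  # exact sample correlation 0.6 -> VIF = 1/(1 - 0.36) = 1.5625
  z1 <- c(1, 1, -1, -1) / 2
  z2 <- c(1, -1, 1, -1) / 2
  X <- data.frame(a = z1, b = 0.6 * z1 + 0.8 * z2)
  expect_equal(unname(vif(X)), c(1.5625, 1.5625), tolerance = 1e-10)

  expect_error(vif(data.frame(a = 1:5, b = 2 * (1:5))), "rank")
  expect_error(vif(data.frame(a = 1:5)), "2 predictors")
})

test_that("VIF agrees with the car implementation", {
  set.seed(11)
  d <- data.frame(y = rnorm(60), x1 = rnorm(60))
  d$x2 <- 0.5 * d$x1 + rnorm(60)
  d$x3 <- rnorm(60)
  ours <- vif(d[c("x1", "x2", "x3")])
  theirs <- car::vif(lm(y ~ x1 + x2 + x3, data = d))
  expect_equal(unname(ours), unname(theirs[names(ours)]), tolerance = 1e-10)
})

test_that("standardized regression recovers unit and null coefficients", {
  set.seed(3)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- d$x1
  fit <- standardized_regression(d, "y", c("x1", "x2", "x3"))
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "x1"], 1, tolerance = 1e-10)
  expect_lt(max(abs(est$estimate[est$term != "x1"])), 1e-10)
  expect_equal(glance(fit)$r_squared, 1, tolerance = 1e-10)
  expect_true(all(est$vif >= 1))

  # a single standardized predictor reproduces the Pearson correlation
  d$y2 <- 0.3 * d$x1 + rnorm(n)
  f1 <- standardized_regression(d, "y2", "x1")
  expect_equal(tidy(f1)$estimate, cor(d$y2, d$x1), tolerance = 1e-10)

  d$dup <- d$x1
  expect_error(standardized_regression(d, "y", c("x1", "dup")), "dup")
  expect_error(standardized_regression(d, "y", "x1") -> ok, NA)
})

test_that("cohort analysis lays out predictors by outcome with FDR on the focal term", {
  set.seed(9)
  n <- 120
  cohort <- data.frame(hardship = rnorm(n), income = rnorm(n),
                       age = sample(18:20, n, TRUE), gender = rbinom(n, 1, 0.6))
  cohort$alpha_pos <- rnorm(n)
  cohort$alpha_neg <- 0.3 * scale(cohort$hardship) + rnorm(n)
  cohort$beta <- rnorm(n)
  tab <- analyze_cohort(cohort)
  expect_identical(nrow(tab), 12L)   # 4 predictors x 3 outcomes
  expect_identical(sum(!is.na(tab$p_fdr)), 3L)
  hard <- tab[tab$term == "hardship", ]
  expect_equal(hard$p_fdr, bh_fdr(hard$p), tolerance = 1e-12)
  expect_true(all(tab$vif >= 1))
})
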