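#' One-sample t test from summary statistics, with Cohen's d
#'
#' Computes the test directly from a reported mean, standard deviation and
#' sample size, so published summaries can be checked without raw data:
#' `t = (mean - mu0) / (sd / sqrt(n))`, `d = (mean - mu0) / sd`, two-sided
#' p from the t distribution with `n - 1` degrees of freedom.
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation (> 0).
#' @param n Sample size (>= 2).
#' @param mu0 Null value (e.g. chance-level accuracy 0.5).
#' @return Tibble with `t`, `df`, `p`, `d`.
#' @export
#' @examples
#' one_sample_t(0.694, 0.067, 95, mu0 = 0.5)
one_sample_t <- function(mean, sd, n, mu0 = 0) {
  if (sd <= 0) stop("`sd` must be positive.", call. = FALSE)
  if (n < 2) stop("`n` must be >= 2.", call. = FALSE)
  t <- (mean - mu0) / (sd / sqrt(n))
  df <- n - 1
  tibble::tibble(t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df),
                 d = (mean - mu0) / sd)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return Tibble with `r`, `n`, `t`, `p` (two-sided), `ci_low`, `ci_high`.
#' @export
pearson_cor <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length.", call. = FALSE)
  if (length(x) < 3) stop("Need at least 3 observations.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Correlation undefined for a constant vector.", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, conf.level = conf_level)
  tibble::tibble(r = unname(ct$estimate), n = length(x),
                 t = unname(ct$statistic), p = ct$p.value,
                 ci_low = ct$conf.int[1], ci_high = ct$conf.int[2])
}

#' p-value for a reported correlation coefficient
#'
#' Recovers the two-sided p-value from a published `r` and `n` via the
#' t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)`.
#'
#' @param r Pearson correlation.
#' @param n Sample size (>= 3).
#' @return Tibble with `r`, `n`, `t`, `p`.
#' @export
#' @examples
#' pearson_p_from_r(0.261, 95)
pearson_p_from_r <- function(r, n) {
  stopifnot(abs(r) < 1, n >= 3)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  tibble::tibble(r = r, n = n, t = t, p = 2 * stats::pt(-abs(t), n - 2))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (with the running-minimum enforcement), as
#' implemented in [stats::p.adjust()]. Input order is preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.773, 0.036, 0.560))
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` on all the others.
#'
#' @param X Data frame or matrix of numeric predictors (>= 2 columns).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("VIF needs at least 2 predictors.", call. = FALSE)
  qrX <- qr(scale(as.matrix(X), center = TRUE, scale = FALSE))
  if (qrX$rank < ncol(X)) {
    stop("Predictors are rank deficient (perfect collinearity).", call. = FALSE)
  }
  vapply(names(X), function(j) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(names(X), j), j),
                            data = X))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

#' Standardized multiple regression
#'
#' z-scores the response and every predictor (binary indicators included,
#' so all coefficients share the standardized-b reading), fits ordinary
#' least squares, and reports coefficients with normal-theory 95%
#' confidence intervals and p-values plus per-predictor variance inflation
#' factors and the model R-squared.
#'
#' @param data Data frame holding the response and predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @param conf_level Confidence level for the intervals.
#' @return An object of class `"prl_reg"`; see [tidy.prl_reg()] /
#'   [glance.prl_reg()]. Its `terms` element is a tibble with one row per
#'   predictor: `term`, `estimate`, `ci_low`, `ci_high`, `p`, `vif`.
#' @export
standardized_regression <- function(data, response, predictors,
                                    conf_level = 0.95) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)))
  if (nrow(data) <= length(predictors) + 1) {
    stop("Too few rows for the number of predictors.", call. = FALSE)
  }
  zsc <- function(v) {
    v <- as.numeric(v)
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      stop("Constant column cannot be standardized.", call. = FALSE)
    }
    (v - mean(v)) / s
  }
  zd <- data[c(response, predictors)]
  zd[] <- lapply(zd, zsc)
  Xm <- as.matrix(zd[predictors])
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    stop("Collinear predictor column(s): ",
         paste(predictors[-keep], collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = zd)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  co <- sm$coefficients
  rows <- predictors
  terms <- tibble::tibble(
    term = rows,
    estimate = unname(co[rows, "Estimate"]),
    ci_low = unname(ci[rows, 1]),
    ci_high = unname(ci[rows, 2]),
    p = unname(co[rows, "Pr(>|t|)"]),
    vif = if (length(predictors) >= 2) unname(vif(zd[predictors])[rows])
          else rep(1, length(rows))
  )
  structure(list(terms = terms, r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 n = nrow(data), response = response, lm_fit = fit),
            class = "prl_reg")
}

#' @export
print.prl_reg <- function(x, ...) {
  cat("<prl_reg> standardized regression of", x$response,
      sprintf("(n = %d, R^2 = %.3f)\n", x$n, x$r_squared))
  print(x$terms)
  invisible(x)
}

#' Socioeconomic regression layer over a cohort of fitted parameters
#'
#' Runs one standardized regression per learning parameter (reward learning
#' rate, punishment learning rate, inverse temperature) on material
#' hardship, household income, age and gender entered simultaneously, and
#' applies Benjamini-Hochberg FDR adjustment to the hardship coefficient's
#' p-values across the three models (the three primary dependent
#' variables form the FDR family).
#'
#' @param cohort Data frame with the outcome columns and predictor columns.
#' @param outcomes Names of the three outcome columns.
#' @param predictors Names of the predictor columns (first one is the
#'   FDR-adjusted focal predictor unless `fdr_term` says otherwise).
#' @param fdr_term Which predictor's p-values to FDR-adjust across models.
#' @return Tibble with one row per predictor per outcome: `outcome`,
#'   `term`, `estimate`, `ci_low`, `ci_high`, `p`, `vif`, `p_fdr` (filled
#'   only for `fdr_term` rows), plus model `r_squared`.
#' @export
analyze_cohort <- function(cohort,
                           outcomes = c("alpha_pos", "alpha_neg", "beta"),
                           predictors = c("hardship", "income", "age", "gender"),
                           fdr_term = predictors[1]) {
  fits <- purrr::map(outcomes, function(y) {
    standardized_regression(cohort, y, predictors)
  })
  tab <- purrr::map2_dfr(fits, outcomes, function(f, y) {
    dplyr::mutate(f$terms, outcome = y, r_squared = f$r_squared,
                  .before = 1)
  })
  focal <- tab$term == fdr_term
  tab$p_fdr <- NA_real_
  tab$p_fdr[focal] <- bh_fdr(tab$p[focal])
  tab
}
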