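#' Genomic-control inflation factor
#'
#' Estimates the genomic inflation factor lambda from genome-wide
#' chi-squared statistics, by the median (observed median over the
#' theoretical chi-squared median) and by the mean (observed mean over the
#' degrees of freedom).
#'
#' @param t Vector of chi-squared score statistics.
#' @param df Reference degrees of freedom (`p` of the test that produced
#'   `t`; 2 for the usual joint GxE test).
#' @return A one-row tibble with `lambda_median`, `lambda_mean`, `df` and
#'   `n_loci`.
#' @export
genomic_lambda <- function(t, df) {
  t <- t[is.finite(t)]
  if (length(t) < 1) abort("No finite statistics supplied.")
  tibble(lambda_median = median(t) / qchisq(0.5, df),
         lambda_mean = mean(t) / df,
         df = df, n_loci = length(t))
}

#' Genomic-control adjustment of statistics
#'
#' Divides the statistics by the estimated inflation factor; with the
#' median method the adjusted sample median equals the theoretical
#' chi-squared median by construction.
#'
#' @inheritParams genomic_lambda
#' @param method `"median"` or `"mean"` lambda estimator.
#' @return Adjusted statistics, same length as `t` (non-finite entries
#'   propagate).
#' @export
gc_adjust <- function(t, df, method = c("median", "mean")) {
  method <- match.arg(method)
  lam <- genomic_lambda(t, df)
  t / if (method == "median") lam$lambda_median else lam$lambda_mean
}

#' Cook's-distance outlier flags for the null model
#'
#' Computes Cook's distance for each sample from the least-squares fit of
#' the phenotype on the given predictors, and flags samples whose distance
#' exceeds `mean(D) + k * sd(D)` (default `k = 4`) -- the influential
#' observations most likely to drive systematic inflation of joint GxE
#' statistics.
#'
#' @param data Data frame of samples.
#' @param pheno Phenotype column name.
#' @param predictors Character vector of predictor column names (covariates
#'   and environment variables of the null model).
#' @param k Flag threshold multiplier on the standard deviation.
#' @return A tibble with `index`, `cooks_d` and logical `flag`.
#' @export
cooks_flags <- function(data, pheno, predictors, k = 4) {
  data <- as.data.frame(data)
  keep <- complete.cases(data[c(pheno, predictors)])
  if (!all(keep)) {
    inform_dropped(sum(!keep))
    data <- data[keep, , drop = FALSE]
  }
  n <- nrow(data)
  if (n <= length(predictors) + 1) abort("Too few samples for a residual degree of freedom.")
  fml <- stats::reformulate(predictors, response = pheno)
  d <- unname(cooks.distance(lm(fml, data = data)))
  if (!all(is.finite(d))) abort("Cook's distance undefined (saturated or degenerate fit).")
  tibble(index = seq_len(n), cooks_d = d,
         flag = d > mean(d) + k * sd(d))
}

#' Quantile-quantile plot coordinates for scan statistics
#'
#' Pairs the observed order statistics with theoretical chi-squared
#' quantiles at plotting positions `(i - 0.5) / L`, on both the statistic
#' scale and the `-log10` p-value scale.
#'
#' @param t Vector of finite chi-squared statistics.
#' @param df Reference degrees of freedom.
#' @return A tibble with `expected`, `observed`, `expected_log10p`,
#'   `observed_log10p`, ordered by increasing expected quantile.
#' @export
qq_points <- function(t, df) {
  t <- sort(t[is.finite(t)])
  L <- length(t)
  if (L < 1) abort("No finite statistics supplied.")
  pp <- (seq_len(L) - 0.5) / L
  tibble(expected = qchisq(pp, df),
         observed = t,
         expected_log10p = -log10(1 - pp),
         observed_log10p = -pchisq(t, df, lower.tail = FALSE, log.p = TRUE) / log(10))
}
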