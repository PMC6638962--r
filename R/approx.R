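#' Closed-form approximation to the genome-wide mean score statistic
#'
#' Computes `t_approx`, the genotype-free approximation to the expected
#' per-locus joint GxE score statistic under independent, identically
#' distributed genotypes: the trace `tr(A^{-1} B)` with
#' `A = sum_i x~_i x~_i' (Q_Ztilde)_ii` and `B = sum_i x~_i x~_i' (Q u)_i^2`,
#' where `x~_i = omega_i^{1/2} x_i`. No genotype data is consumed, which is
#' the point: the quantity predicts the scaled mean of a whole genome scan
#' from the null model alone.
#'
#' @param fit A [fit_null()] object.
#' @param marginal If `TRUE`, use the all-ones multiplier design (marginal
#'   1df test) instead of the fit's `[1, E...]` design.
#' @return The scalar `t_approx`.
#' @export
t_approx_stat <- function(fit, marginal = FALSE) {
  stopifnot(inherits(fit, "gweis_null"))
  X <- if (marginal) matrix(1, fit$n, 1) else fit$X
  Xt <- sqrt(fit$omega) * X
  A <- crossprod(Xt, Xt * fit$q_diag)
  if (rcond(A) < 1e-12) {
    abort("Leverage-weighted moment matrix is singular (degenerate design or weights).")
  }
  B <- crossprod(Xt, Xt * fit$q_u^2)
  sum(diag(solve(A, B)))
}

#' Scan-free inflation assessment l_approx
#'
#' The headline diagnostic: `l_approx = t_approx / p` (for the Gaussian
#' family the rescaled `T_approx / p` with
#' `T_approx = t_approx / ((rss_null - t_approx)/n)`), computed from the
#' phenotype, environment and covariates alone. Values near one indicate
#' that a genome-wide joint GxE scan under this null model would not be
#' systematically inflated or deflated; large departures flag null-model
#' misspecification before any scan is run.
#'
#' The returned flag uses configurable screening bands: `"ok"` when
#' `|l_approx - 1| <= review`, `"review"` up to `problem`, else
#' `"problematic"`.
#'
#' @param fit A [fit_null()] object.
#' @param marginal Use the 1df marginal design instead of the joint one.
#' @param review,problem Flag thresholds on `|l_approx - 1|`.
#' @return A one-row tibble with `t_approx`, `T_approx` (Gaussian only),
#'   `l_approx`, `p_df`, `family` and `flag`.
#' @examples
#' d <- data.frame(y = rnorm(500), e = rnorm(500))
#' l_approx(fit_null(d, "y", env = "e"))
#' @export
l_approx <- function(fit, marginal = FALSE, review = 0.1, problem = 0.5) {
  t_app <- t_approx_stat(fit, marginal = marginal)
  p <- if (marginal) 1L else fit$p
  if (fit$family == "gaussian") {
    T_app <- rescale_approx(t_app, fit$rss_null, fit$n)
    l_app <- T_app / p
  } else {
    T_app <- NA_real_
    l_app <- t_app / p
  }
  dev <- abs(l_app - 1)
  tibble(t_approx = t_app, T_approx = T_app, l_approx = l_app,
         p_df = p, family = fit$family,
         flag = ifelse(dev > problem, "problematic",
                       ifelse(dev > review, "review", "ok")))
}

#' Gaussian rescaling of t_approx
#'
#' `T_approx = t_approx / ((rss_null - t_approx) / n)`, the same rescaling
#' applied to per-locus statistics by [gaussian_rescale()].
#'
#' @param t_approx The trace approximation from [t_approx_stat()].
#' @inheritParams gaussian_rescale
#' @return Scalar `T_approx`.
#' @export
rescale_approx <- function(t_approx, rss_null, n) {
  gaussian_rescale(t_approx, rss_null, n)
}

#' Sweep l_approx over phenotype-environment pairs
#'
#' Screens every combination of the given phenotype and environment columns
#' with the scan-free diagnostic, the intended workflow when many candidate
#' environment variables (e.g. hundreds of metabolites) must be triaged
#' before committing to genome-wide scans.
#'
#' @param data Data frame of samples.
#' @param pheno Character vector of phenotype column names.
#' @param covar Character vector of covariate column names shared by all fits.
#' @param env Character vector of candidate environment column names; each is
#'   assessed on its own (p = 2 joint test).
#' @param family `"gaussian"` or `"binomial"`.
#' @param ... Passed to [l_approx()] (flag thresholds).
#' @return A tibble with one row per (phenotype, environment) pair.
#' @export
l_approx_sweep <- function(data, pheno, covar = character(), env,
                           family = "gaussian", ...) {
  grid <- tidyr::expand_grid(pheno = pheno, env = env)
  purrr::pmap_dfr(grid, function(pheno, env) {
    res <- l_approx(fit_null(data, pheno, covar = covar, env = env,
                             family = family), ...)
    dplyr::bind_cols(tibble(pheno = pheno, env = env), res)
  })
}

#' Monte-Carlo estimate of the expected per-locus score statistic
#'
#' Testing oracle for the quantity [t_approx_stat()] approximates: draws
#' genotypes i.i.d. Binomial(2, maf) per sample (Hardy-Weinberg), computes
#' the per-locus statistic for each draw, and returns the mean with its
#' standard error.
#'
#' @param fit A [fit_null()] object.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param n_draws Number of genotype draws (>= 100).
#' @param seed Optional RNG seed.
#' @param mode `"joint"` or `"marginal"`.
#' @return A one-row tibble with `mean`, `se` and `n_used`.
#' @export
mc_oracle_mean_t <- function(fit, maf, n_draws = 2000, seed = NULL,
                             mode = c("joint", "marginal")) {
  mode <- match.arg(mode)
  stopifnot(maf > 0, maf <= 0.5, n_draws >= 100)
  if (!is.null(seed)) set.seed(seed)
  stat_fun <- if (mode == "joint") joint_gxe_stat else marginal_stat
  t_draws <- vapply(seq_len(n_draws), function(i) {
    stat_fun(fit, rbinom(fit$n, 2, maf))
  }, numeric(1))
  t_draws <- t_draws[is.finite(t_draws)]
  tibble(mean = mean(t_draws),
         se = sd(t_draws) / sqrt(length(t_draws)),
         n_used = length(t_draws))
}
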