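#' Per-locus joint GxE interaction score statistic
#'
#' Computes the p-df score statistic for the joint test of the genotype main
#' effect and all genotype-by-environment interaction terms at one locus,
#' using the working quantities of a fitted null model. The tested block at
#' locus `l` is `W_l = G_l X` with `G_l = diag(g)` and `X` the multiplier
#' design `[1, E1, ..., Ek]`, so the statistic is the quadratic form
#' `u' (Q W~) (W~' Q W~)^{-1} (Q W~)' u` on the weighted scale, asymptotically
#' chi-squared with p df under a correctly specified null.
#'
#' Missing dosages are imputed to the locus mean so the shared null fit
#' remains valid. Degenerate loci (monomorphic, or with a numerically
#' singular projected information) return `NA` rather than erroring, so
#' genome scans can proceed.
#'
#' @param fit A [fit_null()] object.
#' @param g Genotype dosage vector for one locus (0/1/2 or real dosages).
#' @return The score statistic (scalar), or `NA` for a skipped locus.
#' @export
joint_gxe_stat <- function(fit, g) {
  stopifnot(inherits(fit, "gweis_null"))
  g <- impute_locus(as.numeric(g), fit$n)
  if (is.null(g)) return(NA_real_)
  locus_stat(fit, g, fit$X)
}

#' Per-locus marginal association score statistic
#'
#' The 1df score statistic `{(Q g~)' u}^2 / (g~' Q g~)` for the marginal
#' genotype association test; identical to [joint_gxe_stat()] with the
#' multiplier design reduced to the all-ones column.
#'
#' @inheritParams joint_gxe_stat
#' @return The 1df score statistic, or `NA` for a skipped locus.
#' @export
marginal_stat <- function(fit, g) {
  stopifnot(inherits(fit, "gweis_null"))
  g <- impute_locus(as.numeric(g), fit$n)
  if (is.null(g)) return(NA_real_)
  locus_stat(fit, g, matrix(1, fit$n, 1))
}

# Shared quadratic-form evaluation on the weighted scale.
locus_stat <- function(fit, g, X, rcond_tol = 1e-12) {
  Xt <- sqrt(fit$omega) * X
  W <- g * Xt
  V <- W - fit$Qthin %*% crossprod(fit$Qthin, W)
  M <- crossprod(V)
  if (!all(is.finite(M)) || rcond(M) < rcond_tol) return(NA_real_)
  a <- drop(crossprod(V, fit$u_tilde))
  drop(crossprod(a, solve(M, a)))
}

impute_locus <- function(g, n) {
  if (length(g) != n) abort("Genotype vector length does not match the null fit.")
  if (anyNA(g)) {
    m <- mean(g, na.rm = TRUE)
    if (is.nan(m)) return(NULL)  # all-missing locus
    g[is.na(g)] <- m
  }
  if (max(g) == min(g)) return(NULL)  # monomorphic
  g
}

#' Gaussian rescaling of a score statistic
#'
#' Converts a Gaussian-family score statistic `t` into the F-like rescaled
#' version `T = t / ((rss_null - t) / n)`, the form under which the linear
#' model's genome-wide means are summarised.
#'
#' @param t Score statistic(s), nonnegative.
#' @param rss_null Residual sum of squares of the null fit, `||Q_Z y||^2`.
#' @param n Sample size.
#' @return Rescaled statistic(s), same length as `t`.
#' @export
gaussian_rescale <- function(t, rss_null, n) {
  if (any(rss_null <= t, na.rm = TRUE)) {
    abort("`rss_null` must exceed the statistic (degenerate or saturated fit).")
  }
  t / ((rss_null - t) / n)
}

#' Genome-wide scan of score statistics
#'
#' Computes the joint GxE (or marginal) score statistic at every locus of a
#' genotype matrix, sharing a single null fit, and summarises the scan by
#' `t_mean`, the scaled mean `l_mean = t_mean / p` (for the Gaussian family
#' the rescaled `T_mean / p`), and genomic-control lambda estimates.
#'
#' @param fit A [fit_null()] object.
#' @param G Genotype dosage matrix, samples in rows, loci in columns.
#'   `NA` entries are mean-imputed within locus.
#' @param mode `"joint"` for the p-df joint GxE test, `"marginal"` for the
#'   1df association test.
#' @param ids Optional locus identifiers (defaults to column names or
#'   `snp1..snpL`).
#' @return A `gweis_scan` object. `tidy()` returns the per-locus table,
#'   `glance()` the one-row summary, `autoplot()` a QQ plot.
#' @examples
#' d <- data.frame(y = rnorm(200), e = rnorm(200))
#' fit <- fit_null(d, "y", env = "e")
#' G <- simulate_genotypes(200, 50, seed = 1)
#' glance(genome_scan(fit, G))
#' @export
genome_scan <- function(fit, G, mode = c("joint", "marginal"), ids = NULL) {
  stopifnot(inherits(fit, "gweis_null"))
  mode <- match.arg(mode)
  G <- as.matrix(G)
  if (nrow(G) != fit$n) abort("`G` must have one row per sample of the null fit.")
  L <- ncol(G)
  if (L < 1) abort("`G` has no loci.")
  if (is.null(ids)) ids <- colnames(G) %||% paste0("snp", seq_len(L))

  X <- if (mode == "joint") fit$X else matrix(1, fit$n, 1)
  p <- ncol(X)
  t_all <- scan_statistics(fit, G, X)

  skipped <- !is.finite(t_all)
  if (all(skipped)) abort("All loci were skipped (degenerate genotypes).")
  t_valid <- t_all[!skipped]

  gaussian <- fit$family == "gaussian"
  T_all <- if (gaussian) gaussian_rescale(t_all, fit$rss_null, fit$n) else rep(NA_real_, L)
  t_mean <- mean(t_valid)
  T_mean <- if (gaussian) mean(T_all[!skipped]) else NA_real_
  l_mean <- if (gaussian) T_mean / p else t_mean / p
  # genomic control needs statistics on the chi-squared scale: the raw
  # gaussian t is phenotype-scale-dependent, its rescaled T is not
  lam <- genomic_lambda(if (gaussian) T_all[!skipped] else t_valid, df = p)

  loci <- tibble(id = ids, t = t_all, T = T_all, df = p, skipped = skipped)
  structure(
    list(loci = loci, mode = mode, family = fit$family, p_df = p,
         t_mean = t_mean, T_mean = T_mean, l_mean = l_mean,
         lambda_median = lam$lambda_median, lambda_mean = lam$lambda_mean,
         n_loci = L, n_skipped = sum(skipped)),
    class = "gweis_scan")
}

# Vectorised evaluation of the per-locus quadratic forms: all locus-level
# cross products are matrix products against the genotype matrix, leaving
# only L tiny p x p solves.
scan_statistics <- function(fit, G, X, rcond_tol = 1e-12) {
  n <- fit$n
  L <- ncol(G)
  p <- ncol(X)
  if (anyNA(G)) {
    mns <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mns[idx[, 2]]
    G[, is.nan(mns)] <- 0  # all-missing loci become constant -> skipped
  }
  poly <- nonconstant_cols(G)

  Xt <- sqrt(fit$omega) * X
  # numerator pieces a_l = W~' Q u = W~' q_u (Q symmetric idempotent)
  Avec <- crossprod(G, Xt * fit$q_u)                       # L x p
  # Gram pieces: W~' W~ and C_j = Qthin' (g * x~_j)
  G2 <- G * G
  pair_idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  Sm <- matrix(0, L, nrow(pair_idx))
  Cs <- vector("list", p)
  for (j in seq_len(p)) Cs[[j]] <- crossprod(fit$Qthin, G * Xt[, j])  # q x L
  for (r in seq_len(nrow(pair_idx))) {
    j <- pair_idx[r, 1]; k <- pair_idx[r, 2]
    Sm[, r] <- drop(crossprod(G2, Xt[, j] * Xt[, k])) -
      colSums(Cs[[j]] * Cs[[k]])
  }
  t_all <- rep(NA_real_, L)
  M <- matrix(0, p, p)
  for (l in seq_len(L)) {
    if (!poly[l]) next
    M[cbind(pair_idx[, 1], pair_idx[, 2])] <- Sm[l, ]
    M[cbind(pair_idx[, 2], pair_idx[, 1])] <- Sm[l, ]
    if (!all(is.finite(M)) || rcond(M) < rcond_tol) next
    a <- Avec[l, ]
    t_all[l] <- drop(crossprod(a, solve(M, a)))
  }
  t_all
}

# TRUE for columns that are non-constant.
nonconstant_cols <- function(G) {
  mx <- apply(G, 2, max)
  mn <- apply(G, 2, min)
  mx > mn
}

#' @export
print.gweis_scan <- function(x, ...) {
  cat("<gweis_scan> ", x$mode, " ", x$family, " scan over ", x$n_loci,
      " loci (", x$n_skipped, " skipped), p = ", x$p_df, "\n", sep = "")
  cat(sprintf("  l_mean = %.4f, lambda_median = %.4f, lambda_mean = %.4f\n",
              x$l_mean, x$lambda_median, x$lambda_mean))
  invisible(x)
}

#' @rdname genome_scan
#' @param x A `gweis_scan` object.
#' @param ... Unused.
#' @method tidy gweis_scan
#' @export
tidy.gweis_scan <- function(x, ...) x$loci

#' @rdname genome_scan
#' @method glance gweis_scan
#' @export
glance.gweis_scan <- function(x, ...) {
  tibble(mode = x$mode, family = x$family, p_df = x$p_df,
         t_mean = x$t_mean, T_mean = x$T_mean, l_mean = x$l_mean,
         lambda_median = x$lambda_median, lambda_mean = x$lambda_mean,
         n_loci = x$n_loci, n_skipped = x$n_skipped)
}

#' @rdname genome_scan
#' @param object A `gweis_scan` object.
#' @method autoplot gweis_scan
#' @export
autoplot.gweis_scan <- function(object, ...) {
  keep <- !object$loci$skipped
  t_valid <- if (object$family == "gaussian") object$loci$T[keep] else
    object$loci$t[keep]
  qq <- qq_points(t_valid, df = object$p_df)
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = sprintf("Expected chi-squared(%d) quantile", object$p_df),
      y = "Observed statistic",
      title = sprintf("%s scan QQ plot (l_mean = %.2f)",
                      object$mode, object$l_mean)) +
    ggplot2::theme_minimal()
}
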