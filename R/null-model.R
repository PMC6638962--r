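#' Fit the genotype-free null model of a GWEIS
#'
#' Fits the regression of the phenotype on covariates and environment main
#' effects -- the model under which every locus-wise joint GxE score
#' statistic is computed -- and stores the working quantities that all
#' downstream statistics share: the IRLS weights `omega`, the working
#' residuals `u`, the complement-of-leverage diagonal and the residuals of
#' `u` projected off the weighted null design.
#'
#' The null design `Z` is `[intercept, covariates, environment]`; the tested
#' multiplier design `X` is `[intercept, environment]`, so the joint GxE
#' test at a locus `g` tests the block `(g, g * E1, ..., g * Ek)` with
#' `p = 1 + k` degrees of freedom. With no environment variables the test
#' reduces to the 1df marginal association test.
#'
#' @param data A data frame with one row per sample.
#' @param pheno Name of the phenotype column. Quantitative for
#'   `family = "gaussian"`; 0/1 for `family = "binomial"`.
#' @param covar Character vector of covariate column names (may be empty).
#' @param env Character vector of environment-variable column names; these
#'   enter both the null design and the tested multiplier design.
#' @param family `"gaussian"` (identity link) or `"binomial"` (logit link).
#' @return An object of class `gweis_null`.
#' @examples
#' d <- data.frame(y = rnorm(100), age = rnorm(100), e = rnorm(100))
#' fit <- fit_null(d, pheno = "y", covar = "age", env = "e")
#' glance(fit)
#' @export
fit_null <- function(data, pheno, covar = character(), env = character(),
                     family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  all_cols <- c(pheno, covar, env)
  missing_cols <- setdiff(all_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Columns not found in `data`: ",
                 paste(missing_cols, collapse = ", ")))
  }
  keep <- complete.cases(data[all_cols])
  if (!all(keep)) {
    inform_dropped(sum(!keep))
    data <- data[keep, , drop = FALSE]
  }
  y <- data[[pheno]]
  n <- length(y)
  zcols <- c(covar, env)
  Z <- cbind(rep(1, n), if (length(zcols)) as.matrix(data[zcols]))
  colnames(Z) <- c("(Intercept)", zcols)
  X <- cbind(rep(1, n), if (length(env)) as.matrix(data[env]))
  colnames(X) <- c("(Intercept)", env)
  fit <- fit_null_matrix(y, Z, X, family = family)
  fit$pheno <- pheno
  fit
}

inform_dropped <- function(k) {
  rlang::inform(paste0("Dropped ", k, " incomplete case",
                       if (k == 1) "" else "s", " before fitting."))
}

#' Fit the null model from design matrices
#'
#' Matrix-level workhorse behind [fit_null()]. `Z` is the full null design
#' (first column must be the intercept unless a constant column is already
#' present, in which case it is used as-is) and `X` is the tested multiplier
#' design whose first column is all ones. Every column of `X` must also be a
#' column of `Z` (up to an invertible reparameterisation the score test does
#' not see); callers using [fit_null()] get this by construction.
#'
#' @param y Numeric phenotype vector (0/1 for binomial).
#' @param Z Null design matrix, `n x q`.
#' @param X Tested multiplier matrix, `n x p`, first column all ones.
#' @param family `"gaussian"` or `"binomial"`.
#' @return A `gweis_null` object with elements `gamma`, `omega`, `u`,
#'   `q_diag` (the `(Q_Ztilde)_ii = 1 - leverage` diagonal), `q_u` (the
#'   projected residuals `(Q_Ztilde u)_i`), `rss_null` (gaussian),
#'   `converged`, and the designs needed by the score tests.
#' @export
fit_null_matrix <- function(y, Z, X = NULL,
                            family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  y <- as.numeric(y)
  Z <- as.matrix(Z)
  n <- length(y)
  if (nrow(Z) != n) abort("`y` and `Z` must have the same number of rows.")
  if (anyNA(y) || anyNA(Z)) abort("Missing values in `y` or `Z`; use fit_null() for complete-case handling.")
  has_const <- apply(Z, 2, function(col) max(col) == min(col) && col[1] != 0)
  if (!any(has_const)) {
    Z <- cbind(`(Intercept)` = rep(1, n), Z)
  }
  if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  q <- ncol(Z)
  if (n < q + 2) abort("Need at least q + 2 samples.")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) abort("`X` must have the same number of rows as `y`.")
  if (max(abs(X[, 1] - X[1, 1])) > 0 || X[1, 1] == 0) {
    abort("The first column of `X` must be a nonzero constant (all ones).")
  }

  check_full_rank(Z)

  if (family == "gaussian") {
    dec <- qr(Z)
    gamma <- qr.coef(dec, y)
    omega <- rep(1, n)
    u <- y
    res <- qr.resid(dec, y)
    rss_null <- sum(res^2)
    Qthin <- qr.Q(dec)
    converged <- TRUE
  } else {
    if (!all(y %in% c(0, 1))) abort("Binomial phenotype must be coded 0/1.")
    if (length(unique(y)) < 2) abort("Binomial phenotype has a single class.")
    irls <- irls_logistic(y, Z)
    gamma <- irls$gamma
    mu <- irls$mu
    omega <- mu * (1 - mu)
    u <- (y - mu) / omega
    dec <- qr(sqrt(omega) * Z)
    Qthin <- qr.Q(dec)
    rss_null <- NA_real_
    converged <- irls$converged
  }
  q_diag <- 1 - rowSums(Qthin^2)
  # statistics live on the weighted scale: the projected residual is
  # Q_Ztilde applied to u~ = Omega^{1/2} u = Omega^{-1/2}(y - mu), whose
  # variance is O(1) per sample; with u~ the quadratic form reproduces the
  # Rao score statistic exactly (for gaussian, u~ = u = y)
  u_tilde <- sqrt(omega) * u
  q_u <- drop(u_tilde - Qthin %*% crossprod(Qthin, u_tilde))

  structure(
    list(family = family, gamma = stats::setNames(drop(gamma), colnames(Z)),
         omega = omega, u = u, u_tilde = u_tilde,
         q_diag = q_diag, q_u = q_u,
         rss_null = rss_null, converged = converged,
         n = n, q = q, p = ncol(X), y = y, Z = Z, X = X,
         Qthin = Qthin),
    class = "gweis_null")
}

check_full_rank <- function(Z) {
  dec <- qr(Z)
  if (dec$rank < ncol(Z)) {
    bad <- colnames(Z)[dec$pivot[(dec$rank + 1):ncol(Z)]]
    abort(paste0("Null design is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

# Newton/IRLS for the logistic null, initialised at gamma = 0, declared
# converged when the score (gradient) norm max|Z'(y - mu)| < tol.
irls_logistic <- function(y, Z, tol = 1e-10, max_iter = 100) {
  gamma <- rep(0, ncol(Z))
  for (iter in seq_len(max_iter)) {
    eta <- drop(Z %*% gamma)
    mu <- plogis(eta)
    if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
      abort(paste0("Fitted probabilities numerically 0 or 1 ",
                   "(quasi-separation); review covariates/environment."))
    }
    score <- drop(crossprod(Z, y - mu))
    if (max(abs(score)) < tol) {
      return(list(gamma = gamma, mu = mu, converged = TRUE))
    }
    w <- mu * (1 - mu)
    dec <- qr(sqrt(w) * Z)
    gamma <- gamma + qr.coef(dec, (y - mu) / sqrt(w))
  }
  abort("Logistic null fit did not converge in 100 iterations; review covariates.")
}

#' Dichotomize a quantitative phenotype at its mean
#'
#' Returns the 0/1 indicator of the phenotype exceeding its mean, the
#' binary-phenotype construction used to exercise the logistic score test.
#'
#' @param y Numeric, non-constant vector.
#' @return Integer 0/1 vector of the same length.
#' @examples
#' dichotomize_at_mean(c(1, 2, 3))
#' @export
dichotomize_at_mean <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y)) abort("`y` must not contain missing values.")
  if (max(y) == min(y)) abort("`y` is constant; dichotomization would give a single class.")
  as.integer(y > mean(y))
}

#' @export
print.gweis_null <- function(x, ...) {
  cat("<gweis_null> ", x$family, " null model: n = ", x$n,
      ", q = ", x$q, " null columns, p = ", x$p, " tested df\n", sep = "")
  cat("coefficients:\n")
  print(round(x$gamma, 4))
  invisible(x)
}

#' @rdname fit_null
#' @param x A `gweis_null` object.
#' @param ... Unused.
#' @method tidy gweis_null
#' @export
tidy.gweis_null <- function(x, ...) {
  tibble(term = names(x$gamma), estimate = unname(x$gamma))
}

#' @rdname fit_null
#' @method glance gweis_null
#' @export
glance.gweis_null <- function(x, ...) {
  tibble(family = x$family, n = x$n, q = x$q, p = x$p,
         rss_null = x$rss_null, converged = x$converged)
}
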