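SCENARIO_IDS <- c("Base", "1a", "1b", "1c", "1d",
                  "2a", "2b", "2c", "2d", "2e",
                  "3a", "3b", "3c", "3d", "4a", "4b", "4c")

#' Define a simulation scenario
#'
#' Bundles the configuration for one cell of the simulation study that
#' validates the scan-free approximation: a scenario identifier, the effect
#' triplet `(b_G, b_Z, b_GE)` for genotype, covariate and GxE interaction
#' effects, the genotype coding used when genetic effects are present, the
#' phenotype family, and the problem size.
#'
#' Scenario identifiers: `Base` (one standard-normal covariate and
#' environment variable, correctly specified null, unlinked uniform-MAF
#' genotypes); `1a`/`1b`/`1c` associate genotypes with the covariate, the
#' environment, or both; `1d` associates environment with covariate;
#' `2a`/`2b` omit a genotype-associated covariate from the null model;
#' `2c` generates a quadratic environment effect but fits a linear null;
#' `2d`/`2e` inject 1 or 10 gross outliers; `3a`-`3d` vary the
#' covariate/environment distributions (five normals, uniform, binary,
#' ordinal); `4a`-`4c` vary the genotype distribution (AR(1) linkage
#' disequilibrium and/or a beta MAF spectrum).
#'
#' @param scenario One of the identifiers above.
#' @param effects Numeric triplet `(b_G, b_Z, b_GE)`.
#' @param coding Genotype coding for the generated genetic effects.
#' @param family `"gaussian"` or `"binomial"`.
#' @param n Samples per replicate.
#' @param L Loci per replicate.
#' @param reps Number of replicates.
#' @param seed Master seed; replicate seeds are derived from it by a
#'   counter scheme so each replicate is individually reproducible.
#' @param params Named list overriding scenario parameters:
#'   `assoc_delta` (genotype association strength on the logit-MAF scale,
#'   0.1), `env_covar_coef` (0.5), `quad_coef` (1), `outlier_y_sd` (10),
#'   `outlier_e_sd` (5), `n_causal` (10), `ld_rho` (0.8), `beta_shape`
#'   (`c(1, 3)`), `maf_range` (`c(0.05, 0.5)`).
#' @return A `gweis_scenario` specification list.
#' @export
scenario_spec <- function(scenario = "Base", effects = c(0, 0, 0),
                          coding = c("additive", "dominant", "recessive"),
                          family = c("gaussian", "binomial"),
                          n = 1000, L = 2000, reps = 50, seed = 1,
                          params = list()) {
  if (!scenario %in% SCENARIO_IDS) {
    abort(paste0("Unknown scenario `", scenario, "`; expected one of: ",
                 paste(SCENARIO_IDS, collapse = ", ")))
  }
  stopifnot(length(effects) == 3, reps >= 1, n >= 10, L >= 2)
  defaults <- list(assoc_delta = 0.1, env_covar_coef = 0.5, quad_coef = 1,
                   outlier_y_sd = 10, outlier_e_sd = 5, n_causal = 10,
                   ld_rho = 0.8, beta_shape = c(1, 3),
                   maf_range = c(0.05, 0.5))
  params <- utils::modifyList(defaults, params)
  structure(
    list(scenario = scenario, effects = as.numeric(effects),
         coding = match.arg(coding), family = match.arg(family),
         n = as.integer(n), L = as.integer(L), reps = as.integer(reps),
         seed = as.integer(seed), params = params),
    class = "gweis_scenario")
}

#' Generate one replicate of a simulation scenario
#'
#' Draws covariates, environment, genotypes and phenotype according to the
#' scenario, and returns both the data-generating design and the
#' (possibly deliberately misspecified) null design that the analysis
#' fits.
#'
#' @param spec A [scenario_spec()].
#' @param seed Optional seed for this replicate.
#' @return A list with `y`, `Z_null`, `Z_true`, `X`, `G` and `family`.
#' @export
generate_scenario_data <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "gweis_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n; L <- spec$L; sc <- spec$scenario; pr <- spec$params
  b <- spec$effects  # (b_G, b_Z, b_GE)

  # covariates and environment
  draw_var <- function() switch(sc,
    "3b" = runif(n), "3c" = rbinom(n, 1, 0.5),
    "3d" = sample(0:4, n, replace = TRUE), rnorm(n))
  n_covar <- if (sc == "3a") 5L else 1L
  Zc <- matrix(replicate(n_covar, draw_var()), n, n_covar)
  colnames(Zc) <- paste0("covar", seq_len(n_covar))
  E <- if (sc %in% c("1d", "2b")) {
    pr$env_covar_coef * Zc[, 1] + rnorm(n)
  } else draw_var()

  # genotypes
  maf_dist <- if (sc %in% c("4b", "4c")) "beta" else "uniform"
  ld <- if (sc %in% c("4a", "4c")) "ar1" else "none"
  assoc_f <- switch(sc,
    "1a" = Zc[, 1], "2a" = Zc[, 1], "2b" = Zc[, 1],
    "1b" = E, "1c" = (Zc[, 1] + E) / sqrt(2), NULL)
  if (is.null(assoc_f)) {
    G <- simulate_genotypes(n, L, maf_dist = maf_dist,
                            maf_range = pr$maf_range,
                            beta_shape = pr$beta_shape,
                            ld = ld, rho = pr$ld_rho)
    maf <- attr(G, "maf")
  } else {
    # per-sample allele frequency tilted by the shared latent factor
    maf <- runif(L, pr$maf_range[1], pr$maf_range[2])
    probs <- plogis(outer(pr$assoc_delta * assoc_f, qlogis(maf), "+"))
    G <- matrix(rbinom(n * L, 2L, probs), n, L)
    colnames(G) <- paste0("snp", seq_len(L))
  }

  # phenotype
  lp <- b[2] * Zc[, 1]
  if (b[1] != 0 || b[3] != 0) {
    causal <- sample.int(L, min(pr$n_causal, L))
    Gc <- code_genotype(G[, causal, drop = FALSE], spec$coding)
    if (b[1] != 0) lp <- lp + b[1] * rowSums(Gc)
    if (b[3] != 0) lp <- lp + b[3] * rowSums(Gc * E)
  }
  if (sc == "2c") {
    lp <- lp + pr$quad_coef * E^2
  }
  y <- if (spec$family == "gaussian") lp + rnorm(n)
       else rbinom(n, 1, plogis(lp))

  # gross outliers, injected after generation so the fitted null sees them
  if (sc %in% c("2d", "2e")) {
    k <- if (sc == "2d") 1L else 10L
    out <- sample.int(n, k)
    E[out] <- E[out] + pr$outlier_e_sd * sd(E)
    if (spec$family == "gaussian") {
      y[out] <- y[out] + pr$outlier_y_sd * sd(y)
    }
  }

  drop_covar <- sc %in% c("2a", "2b")
  Z_null <- cbind(`(Intercept)` = 1,
                  if (!drop_covar) Zc, env = E)
  Z_true <- cbind(`(Intercept)` = 1, Zc, env = E,
                  if (sc == "2c") cbind(env_sq = E^2))
  X <- cbind(`(Intercept)` = 1, env = E)
  list(y = y, Z_null = Z_null, Z_true = Z_true, X = X, G = G,
       family = spec$family)
}

#' Run the replicate study for one scenario
#'
#' For each replicate: generate the data, fit the null model on the
#' scenario's null design, compute the scan-free `l_approx` and the scanned
#' `l_mean` for both the joint GxE and marginal tests, and record their
#' ratio. Replicates that fail (e.g. a degenerate fit) are recorded and
#' excluded with a warning.
#'
#' @param spec A [scenario_spec()].
#' @return A `gweis_sim` object; `tidy()` gives the per-replicate values,
#'   `glance()` the replicate means and SDs in the layout of the
#'   summary tables (one row per test mode).
#' @examples
#' sim <- run_replicates(scenario_spec("Base", n = 200, L = 100, reps = 3))
#' glance(sim)
#' @export
run_replicates <- function(spec) {
  stopifnot(inherits(spec, "gweis_scenario"))
  rows <- purrr::map(seq_len(spec$reps), function(r) {
    seed_r <- replicate_seed(spec$seed, r)
    tryCatch({
      dat <- generate_scenario_data(spec, seed = seed_r)
      fit <- fit_null_matrix(dat$y, dat$Z_null, dat$X, family = dat$family)
      la_j <- l_approx(fit)$l_approx
      la_m <- l_approx(fit, marginal = TRUE)$l_approx
      lm_j <- genome_scan(fit, dat$G, mode = "joint")$l_mean
      lm_m <- genome_scan(fit, dat$G, mode = "marginal")$l_mean
      tibble(rep = r, seed = seed_r, ok = TRUE,
             l_approx_joint = la_j, l_mean_joint = lm_j,
             ratio_joint = la_j / lm_j,
             l_approx_marginal = la_m, l_mean_marginal = lm_m,
             ratio_marginal = la_m / lm_m)
    }, error = function(e) {
      warn(paste0("Replicate ", r, " failed and was excluded: ",
                  conditionMessage(e)))
      tibble(rep = r, seed = seed_r, ok = FALSE,
             l_approx_joint = NA_real_, l_mean_joint = NA_real_,
             ratio_joint = NA_real_,
             l_approx_marginal = NA_real_, l_mean_marginal = NA_real_,
             ratio_marginal = NA_real_)
    })
  })
  reps <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(reps, .data$ok)
  if (nrow(ok) == 0) abort("All replicates failed.")
  summarise_mode <- function(mode) {
    la <- ok[[paste0("l_approx_", mode)]]
    lm <- ok[[paste0("l_mean_", mode)]]
    ra <- ok[[paste0("ratio_", mode)]]
    tibble(test = mode,
           l_approx = mean(la), l_approx_sd = sd(la),
           l_mean = mean(lm), l_mean_sd = sd(lm),
           ratio = mean(ra), ratio_sd = sd(ra))
  }
  structure(
    list(spec = spec, replicates = reps,
         summary = dplyr::bind_rows(summarise_mode("joint"),
                                    summarise_mode("marginal")),
         n_failed = spec$reps - nrow(ok)),
    class = "gweis_sim")
}

# Counter-based replicate seeds, kept inside 32-bit integer range.
replicate_seed <- function(master, r) {
  as.integer((as.double(master) + 1000003 * as.double(r)) %% 2147483647)
}

#' @export
print.gweis_sim <- function(x, ...) {
  s <- x$spec
  cat("<gweis_sim> scenario ", s$scenario, " (",
      paste(s$effects, collapse = ","), "), ", s$family,
      ", n = ", s$n, ", L = ", s$L, ", reps = ", s$reps,
      if (x$n_failed > 0) paste0(" (", x$n_failed, " failed)"), "\n",
      sep = "")
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname run_replicates
#' @param x A `gweis_sim` object.
#' @param ... Unused.
#' @method tidy gweis_sim
#' @export
tidy.gweis_sim <- function(x, ...) x$replicates

#' @rdname run_replicates
#' @method glance gweis_sim
#' @export
glance.gweis_sim <- function(x, ...) {
  meta <- tibble(
    scenario = x$spec$scenario,
    effects = paste0("(", paste(x$spec$effects, collapse = ","), ")"),
    family = x$spec$family, n = x$spec$n, L = x$spec$L,
    reps = x$spec$reps - x$n_failed)
  dplyr::bind_cols(meta[rep(1, nrow(x$summary)), ], x$summary)
}

#' @rdname run_replicates
#' @param object A `gweis_sim` object.
#' @method autoplot gweis_sim
#' @export
autoplot.gweis_sim <- function(object, ...) {
  ok <- dplyr::filter(object$replicates, .data$ok)
  long <- dplyr::bind_rows(
    tibble(test = "joint", l_approx = ok$l_approx_joint,
           l_mean = ok$l_mean_joint),
    tibble(test = "marginal", l_approx = ok$l_approx_marginal,
           l_mean = ok$l_mean_marginal))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$l_mean, y = .data$l_approx,
                                     colour = .data$test)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "l_mean (genome scan)",
                  y = "l_approx (scan-free)",
                  title = sprintf("Scenario %s (%s)", object$spec$scenario,
                                  paste(object$spec$effects, collapse = ","))) +
    ggplot2::theme_minimal()
}
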