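# Score statistics: oracle agreement with glm's Rao test, invariances,
# degenerate-locus handling and the vectorised scan path.

test_that("joint statistic matches glm anova Rao score test (both families)", {
  set.seed(31)
  for (family in c("gaussian", "binomial")) {
    d <- if (family == "gaussian") make_gaussian_data(n = 250, seed = 33) else
      make_binomial_data(n = 250, seed = 33)
    g <- rbinom(nrow(d), 2, 0.3)
    d$g <- g
    fit <- fit_null(d, "y", covar = "z", env = "e", family = family)
    t_pkg <- joint_gxe_stat(fit, g)
    fam <- if (family == "gaussian") stats::gaussian() else stats::binomial()
    null_glm <- tight_glm(y ~ z + e, data = d, family = fam)
    full_glm <- tight_glm(y ~ z + e + g + g:e, data = d, family = fam)
    an <- anova(null_glm, full_glm, test = "Rao")
    expect_equal(t_pkg, an$Rao[2], tolerance = 1e-8)
  }
})

test_that("marginal statistic matches the glm Rao oracle", {
  d <- make_binomial_data(n = 220, seed = 35)
  set.seed(36)
  g <- rbinom(nrow(d), 2, 0.25)
  d$g <- g
  fit <- fit_null(d, "y", covar = "z", env = "e", family = "binomial")
  t_pkg <- marginal_stat(fit, g)
  null_glm <- tight_glm(y ~ z + e, data = d, family = stats::binomial())
  full_glm <- tight_glm(y ~ z + e + g, data = d, family = stats::binomial())
  rao <- anova(null_glm, full_glm, test = "Rao")$Rao[2]
  expect_equal(t_pkg, rao, tolerance = 1e-8)
})

test_that("joint test with no environment variables equals the marginal test", {
  d <- make_gaussian_data(n = 150, seed = 37)
  fit <- fit_null(d, "y", covar = "z")  # X reduces to the intercept
  set.seed(38)
  for (i in 1:20) {
    g <- rbinom(150, 2, runif(1, 0.1, 0.5))
    expect_equal(joint_gxe_stat(fit, g), marginal_stat(fit, g),
                 tolerance = 1e-10)
  }
})

test_that("statistic is invariant to affine reparameterisation of environment", {
  d <- make_gaussian_data(n = 180, seed = 39)
  d$e2 <- 2 + 3 * d$e
  set.seed(40)
  g <- rbinom(180, 2, 0.3)
  f1 <- fit_null(d, "y", covar = "z", env = "e")
  f2 <- fit_null(d, "y", covar = "z", env = "e2")
  expect_equal(joint_gxe_stat(f2, g), joint_gxe_stat(f1, g), tolerance = 1e-8)
})

test_that("statistic is invariant to rescaling the genotype dosages", {
  d <- make_binomial_data(n = 160, seed = 41)
  fit <- fit_null(d, "y", covar = "z", env = "e", family = "binomial")
  set.seed(42)
  g <- rbinom(160, 2, 0.4)
  expect_equal(joint_gxe_stat(fit, 10 * g - 3), joint_gxe_stat(fit, g),
               tolerance = 1e-8)
})

test_that("degenerate loci are skipped, not errors", {
  d <- make_gaussian_data(n = 100, seed = 43)
  fit <- fit_null(d, "y", env = "e")
  expect_true(is.na(joint_gxe_stat(fit, rep(1, 100))))     # monomorphic
  expect_true(is.na(joint_gxe_stat(fit, rep(NA_real_, 100))))  # all missing
})

test_that("missing dosages are mean-imputed within locus", {
  d <- make_gaussian_data(n = 120, seed = 45)
  fit <- fit_null(d, "y", env = "e")
  set.seed(46)
  g <- rbinom(120, 2, 0.3)
  gm <- as.numeric(g)
  gm[1:5] <- NA
  gfill <- gm
  gfill[1:5] <- mean(gm, na.rm = TRUE)
  expect_equal(joint_gxe_stat(fit, gm), joint_gxe_stat(fit, gfill),
               tolerance = 1e-12)
})

test_that("gaussian_rescale matches hand values and is monotone", {
  expect_equal(gaussian_rescale(0, 10, 100), 0)
  expect_equal(gaussian_rescale(5, 10, 100), 100)  # 5 / ((10-5)/100)
  tg <- seq(0, 9, by = 0.5)
  Tg <- gaussian_rescale(tg, 10, 50)
  expect_true(all(diff(Tg) > 0))
  expect_error(gaussian_rescale(10, 10, 50), "exceed")
})

test_that("vectorised scan equals the per-locus reference path", {
  for (family in c("gaussian", "binomial")) {
    d <- if (family == "gaussian") make_gaussian_data(n = 150, seed = 47) else
      make_binomial_data(n = 150, seed = 47)
    fit <- fit_null(d, "y", covar = "z", env = "e", family = family)
    G <- simulate_genotypes(150, 40, seed = 48)
    G[1:3, 5] <- NA           # partial missing
    G[, 9] <- 1               # monomorphic
    for (mode in c("joint", "marginal")) {
      scan <- genome_scan(fit, G, mode = mode)
      ref <- reference_scan_t(fit, G, mode = mode)
      expect_equal(scan$loci$t, ref, tolerance = 1e-10)
    }
  }
})

test_that("scan summary accounting is correct", {
  d <- make_gaussian_data(n = 100, seed = 49)
  fit <- fit_null(d, "y", env = "e")
  G <- simulate_genotypes(100, 10, seed = 50)
  G[, 4] <- 0
  scan <- genome_scan(fit, G)
  expect_equal(scan$n_loci, 10)
  expect_equal(scan$n_skipped, 1)
  expect_true(scan$loci$skipped[4])
  ok <- !scan$loci$skipped
  expect_equal(scan$t_mean, mean(scan$loci$t[ok]), tolerance = 1e-12)
  expect_equal(scan$l_mean, mean(scan$loci$T[ok]) / scan$p_df,
               tolerance = 1e-12)
  expect_equal(scan$p_df, 2)
  expect_equal(nrow(tidy(scan)), 10)
  expect_equal(nrow(glance(scan)), 1)
})

test_that("scan is invariant to locus order", {
  d <- make_gaussian_data(n = 120, seed = 51)
  fit <- fit_null(d, "y", env = "e")
  G <- simulate_genotypes(120, 30, seed = 52)
  set.seed(53); perm <- sample.int(30)
  s1 <- genome_scan(fit, G)
  s2 <- genome_scan(fit, G[, perm])
  expect_equal(s2$loci$t, s1$loci$t[perm], tolerance = 1e-12)
  expect_equal(s2$l_mean, s1$l_mean, tolerance = 1e-12)
})

test_that("under a correct null the statistics follow the reference chi-squared law", {
  set.seed(55)
  n <- 400
  d <- data.frame(y = rnorm(n), z = rnorm(n), e = rnorm(n))
  fit <- fit_null(d, "y", covar = "z", env = "e")
  G <- simulate_genotypes(n, 5000, seed = 56)
  scan <- genome_scan(fit, G)
  t_ok <- scan$loci$t[!scan$loci$skipped]
  ks <- suppressWarnings(ks.test(t_ok, "pchisq", df = 2))
  expect_gt(ks$p.value, 0.001)
  expect_equal(scan$l_mean, 1, tolerance = 3 * sd(t_ok) / 2 / sqrt(length(t_ok)) + 0.02)
})

test_that("binomial correct-null scan mean is near one", {
  set.seed(57)
  n <- 1000
  d <- data.frame(z = rnorm(n), e = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.5 * d$z + 0.5 * d$e))
  fit <- fit_null(d, "y", covar = "z", env = "e", family = "binomial")
  G <- simulate_genotypes(n, 2000, seed = 58)
  scan <- genome_scan(fit, G)
  t_ok <- scan$loci$t[!scan$loci$skipped]
  se <- sd(t_ok) / 2 / sqrt(length(t_ok))
  expect_equal(scan$l_mean, 1, tolerance = 3 * se + 0.02)
})

test_that("gaussian scan lambda is computed on the scale-free rescaled statistic", {
  d <- make_gaussian_data(n = 200, seed = 54)
  G <- simulate_genotypes(200, 100, seed = 55)
  f1 <- fit_null(d, "y", covar = "z", env = "e")
  d$y10 <- 10 * d$y   # raw t scales by 100; T and lambda must not move
  f2 <- fit_null(d, "y10", covar = "z", env = "e")
  s1 <- genome_scan(f1, G)
  s2 <- genome_scan(f2, G)
  expect_equal(s2$lambda_median, s1$lambda_median, tolerance = 1e-10)
  expect_equal(s2$lambda_mean, s1$lambda_mean, tolerance = 1e-10)
  expect_equal(s1$lambda_mean, s1$l_mean, tolerance = 1e-12)
})

test_that("scan input validation", {
  d <- make_gaussian_data(n = 50, seed = 59)
  fit <- fit_null(d, "y", env = "e")
  expect_error(genome_scan(fit, matrix(0, 49, 3)), "one row per sample")
  expect_error(genome_scan(fit, matrix(1, 50, 3)), "All loci were skipped")
})
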