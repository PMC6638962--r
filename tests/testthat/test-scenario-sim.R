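# Scenario simulator: construction invariants, per-scenario structure,
# reproducibility and small directional replicate studies.

test_that("scenario_spec validates its inputs and fills defaults", {
  sp <- scenario_spec("Base")
  expect_s3_class(sp, "gweis_scenario")
  expect_equal(sp$params$assoc_delta, 0.1)
  expect_equal(sp$params$ld_rho, 0.8)
  sp2 <- scenario_spec("4a", params = list(ld_rho = 0.5))
  expect_equal(sp2$params$ld_rho, 0.5)
  expect_equal(sp2$params$quad_coef, 1)
  expect_error(scenario_spec("zzz"), "Unknown scenario")
})

test_that("generated data has coherent shapes for every scenario", {
  for (sc in c("Base", "1a", "1b", "1c", "1d", "2a", "2b", "2c", "2d", "2e",
               "3a", "3b", "3c", "3d", "4a", "4b", "4c")) {
    sp <- scenario_spec(sc, n = 80, L = 30, reps = 1)
    dat <- generate_scenario_data(sp, seed = 131)
    expect_length(dat$y, 80)
    expect_equal(dim(dat$G), c(80, 30))
    expect_equal(nrow(dat$Z_null), 80)
    expect_equal(ncol(dat$X), 2)
    expect_true(all(dat$G %in% 0:2))
  }
})

test_that("replicates are reproducible from the master seed", {
  sp <- scenario_spec("Base", n = 60, L = 20, reps = 1, seed = 7)
  d1 <- generate_scenario_data(sp, seed = replicate_seed(7, 1))
  d2 <- generate_scenario_data(sp, seed = replicate_seed(7, 1))
  expect_identical(d1, d2)
  d3 <- generate_scenario_data(sp, seed = replicate_seed(7, 2))
  expect_false(identical(d1$y, d3$y))
})

test_that("replicate seeds are distinct and within the 32-bit range", {
  seeds <- vapply(1:500, function(r) replicate_seed(1, r), integer(1))
  expect_equal(length(unique(seeds)), 500)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("covariate-omission scenarios drop the covariate from the null design", {
  for (sc in c("2a", "2b")) {
    dat <- generate_scenario_data(scenario_spec(sc, n = 50, L = 10), seed = 133)
    expect_equal(colnames(dat$Z_null), c("(Intercept)", "env"))
    expect_true("covar1" %in% colnames(dat$Z_true))
  }
  base <- generate_scenario_data(scenario_spec("Base", n = 50, L = 10), seed = 133)
  expect_true("covar1" %in% colnames(base$Z_null))
})

test_that("distribution scenarios draw the advertised variable types", {
  d3a <- generate_scenario_data(scenario_spec("3a", n = 70, L = 5), seed = 135)
  expect_equal(sum(startsWith(colnames(d3a$Z_null), "covar")), 5)
  d3b <- generate_scenario_data(scenario_spec("3b", n = 300, L = 5), seed = 135)
  expect_true(all(d3b$Z_null[, "covar1"] >= 0 & d3b$Z_null[, "covar1"] <= 1))
  d3c <- generate_scenario_data(scenario_spec("3c", n = 300, L = 5), seed = 135)
  expect_true(all(d3c$Z_null[, "covar1"] %in% 0:1))
  d3d <- generate_scenario_data(scenario_spec("3d", n = 300, L = 5), seed = 135)
  expect_true(all(d3d$Z_null[, "covar1"] %in% 0:4))
})

test_that("quadratic scenario generates an environment-squared signal", {
  dat <- generate_scenario_data(scenario_spec("2c", n = 2000, L = 5), seed = 137)
  E <- dat$Z_null[, "env"]
  expect_gt(cor(dat$y, E^2), cor(dat$y, E) + 0.2)
  expect_true("env_sq" %in% colnames(dat$Z_true))
})

test_that("outlier scenarios inject the advertised number of gross outliers", {
  d1 <- generate_scenario_data(scenario_spec("2d", n = 400, L = 5), seed = 139)
  fl1 <- cooks_flags(data.frame(y = d1$y, e = d1$Z_null[, "env"]), "y", "e")
  expect_gte(sum(fl1$flag), 1)
  d10 <- generate_scenario_data(scenario_spec("2e", n = 400, L = 5), seed = 139)
  expect_gt(max(abs(scale(d10$y))), 4)
  expect_gt(sum(abs(scale(d10$Z_null[, "env"])) > 3), 5)
})

test_that("genotype-association scenarios tilt allele frequency with the factor", {
  dat <- generate_scenario_data(
    scenario_spec("1a", n = 4000, L = 50, params = list(assoc_delta = 1)),
    seed = 141)
  f <- dat$Z_true[, "covar1"]
  r <- mean(vapply(1:50, function(l) cor(dat$G[, l], f), numeric(1)))
  expect_gt(r, 0.05)
})

test_that("LD scenarios produce correlated neighbouring loci", {
  dat <- generate_scenario_data(scenario_spec("4a", n = 2000, L = 10), seed = 143)
  r_adj <- mean(vapply(1:9, function(l) cor(dat$G[, l], dat$G[, l + 1]),
                       numeric(1)))
  expect_gt(r_adj, 0.2)
})

test_that("run_replicates returns coherent replicate and summary tables", {
  sim <- run_replicates(scenario_spec("Base", n = 150, L = 60, reps = 4,
                                      seed = 3))
  reps <- tidy(sim)
  expect_equal(nrow(reps), 4)
  expect_true(all(reps$ok))
  gl <- glance(sim)
  expect_equal(nrow(gl), 2)
  expect_setequal(gl$test, c("joint", "marginal"))
  expect_equal(gl$l_approx[gl$test == "joint"], mean(reps$l_approx_joint),
               tolerance = 1e-12)
  expect_equal(gl$ratio[gl$test == "marginal"],
               mean(reps$ratio_marginal), tolerance = 1e-12)
  # re-running is deterministic
  sim2 <- run_replicates(scenario_spec("Base", n = 150, L = 60, reps = 4,
                                       seed = 3))
  expect_equal(tidy(sim2), reps)
})

test_that("genuine genetic effects inflate the scan but not the approximation", {
  # omitted-covariate scenario: the scan mean rises above the scan-free
  # prediction, which is exactly the diagnostic gap the ratio reports
  sim <- run_replicates(scenario_spec("2a", effects = c(1, 1, 0),
                                      n = 500, L = 400, reps = 3, seed = 17,
                                      params = list(assoc_delta = 1)))
  gl <- glance(sim)
  expect_gt(gl$l_mean[gl$test == "marginal"],
            gl$l_approx[gl$test == "marginal"] + 0.05)
})

test_that("quadratic misspecification inflates gaussian l_approx and l_mean together", {
  sim <- run_replicates(scenario_spec("2c", n = 400, L = 300, reps = 3,
                                      seed = 19))
  gl <- glance(sim)
  j <- gl[gl$test == "joint", ]
  expect_gt(j$l_approx, 1.5)
  expect_gt(j$l_mean, 1.5)
  expect_equal(j$ratio, 1, tolerance = 0.15)
})
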