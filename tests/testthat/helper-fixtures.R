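# Small fixtures built in code; every helper takes a seed so tests are
# reproducible without stored data.

make_gaussian_data <- function(n = 200, seed = 101) {
  set.seed(seed)
  data.frame(y = rnorm(n), z = rnorm(n), e = rnorm(n))
}

make_binomial_data <- function(n = 400, seed = 202) {
  set.seed(seed)
  d <- data.frame(z = rnorm(n), e = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.3 * d$z - 0.2 * d$e))
  d
}

# independent slow reference: per-locus statistics via the single-locus path
reference_scan_t <- function(fit, G, mode = "joint") {
  f <- if (mode == "joint") joint_gxe_stat else marginal_stat
  vapply(seq_len(ncol(G)), function(l) f(fit, G[, l]), numeric(1))
}

tight_glm <- function(formula, data, family) {
  stats::glm(formula, data = data, family = family,
             control = stats::glm.control(epsilon = 1e-14, maxit = 200))
}
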