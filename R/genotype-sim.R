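#' Simulate genotype dosage matrices under Hardy-Weinberg equilibrium
#'
#' Generates an `n x L` dosage matrix. Unlinked loci are i.i.d.
#' `Binomial(2, maf_l)` per sample. Linkage disequilibrium is emulated by a
#' latent per-sample AR(1) standard-normal sequence across loci for each of
#' the two allele copies, thresholded at the MAF-matched normal quantile, so
#' the marginal per-locus law is still HWE `Binomial(2, maf_l)` while
#' neighbouring loci are positively correlated.
#'
#' @param n Number of samples.
#' @param L Number of loci.
#' @param maf Optional length-`L` vector of minor allele frequencies; drawn
#'   from `maf_dist` when `NULL`.
#' @param maf_dist `"uniform"` (on `maf_range`) or `"beta"` (shape
#'   parameters `beta_shape`, mapped onto `maf_range` by quantile
#'   truncation).
#' @param maf_range MAF bounds, within (0, 0.5].
#' @param beta_shape Two shape parameters for the beta MAF spectrum.
#' @param ld `"none"` (linkage equilibrium) or `"ar1"`.
#' @param rho AR(1) correlation of the latent allele process when
#'   `ld = "ar1"`.
#' @param seed Optional RNG seed for reproducibility.
#' @return Integer-valued matrix of dosages in `{0, 1, 2}` with the MAF
#'   vector attached as attribute `"maf"`.
#' @examples
#' G <- simulate_genotypes(100, 20, seed = 1)
#' range(G)
#' @export
simulate_genotypes <- function(n, L, maf = NULL,
                               maf_dist = c("uniform", "beta"),
                               maf_range = c(0.05, 0.5),
                               beta_shape = c(1, 3),
                               ld = c("none", "ar1"), rho = 0.8,
                               seed = NULL) {
  maf_dist <- match.arg(maf_dist)
  ld <- match.arg(ld)
  stopifnot(n >= 1, L >= 1)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must lie within (0, 0.5].")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) {
    maf <- switch(maf_dist,
      uniform = runif(L, maf_range[1], maf_range[2]),
      # truncate the beta spectrum to the admissible MAF window by
      # inverse-cdf sampling between the window's beta quantiles
      beta = {
        pr <- stats::pbeta(maf_range, beta_shape[1], beta_shape[2])
        qbeta(runif(L, pr[1], pr[2]), beta_shape[1], beta_shape[2])
      })
  }
  if (length(maf) != L) abort("`maf` must have length L.")
  if (any(maf <= 0) || any(maf > 0.5)) abort("MAFs must lie in (0, 0.5].")

  if (ld == "none") {
    G <- matrix(rbinom(n * L, 2L, rep(maf, each = n)), n, L)
  } else {
    thr <- qnorm(maf)
    G <- matrix(0L, n, L)
    for (copy in 1:2) {
      latent <- matrix(rnorm(n * L), n, L)
      for (l in 2:max(L, 2)) {
        if (l > L) break
        latent[, l] <- rho * latent[, l - 1] + sqrt(1 - rho^2) * latent[, l]
      }
      G <- G + (latent < rep(thr, each = n))
    }
  }
  storage.mode(G) <- "double"
  colnames(G) <- paste0("snp", seq_len(L))
  attr(G, "maf") <- maf
  G
}

#' Recode genotype dosages
#'
#' Additive coding is the identity on minor-allele counts; dominant maps
#' `{0,1,2}` to `{0,1,1}`; recessive maps `{0,1,2}` to `{0,0,1}`.
#'
#' @param g Dosage vector or matrix with values in `{0, 1, 2}`.
#' @param coding `"additive"`, `"dominant"` or `"recessive"`.
#' @return Recoded vector/matrix of the same shape.
#' @export
code_genotype <- function(g, coding = c("additive", "dominant", "recessive")) {
  coding <- match.arg(coding)
  switch(coding,
         additive = g,
         dominant = (g >= 1) + 0,
         recessive = (g >= 2) + 0)
}
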