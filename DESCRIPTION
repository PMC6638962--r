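Package: gweischeck
Title: Quick Assessment of Systematic Test-Statistic Inflation in
    Genome-Wide Environment Interaction Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scan-free diagnosis of systematic inflation or deflation of
    joint gene-environment (GxE) interaction score statistics caused by
    null-model misspecification. Implements the closed-form approximation
    l_approx to the scaled mean of genome-wide joint 2df GxE score
    statistics, computed from phenotype, environment and covariates alone;
    the per-locus joint and marginal score tests themselves; genotype and
    scenario simulators that validate the approximation; an
    l_approx-driven Box-Cox phenotype transformation; and companion
    diagnostics (genomic-control lambda, Cook's-distance flags, QQ data).
    PLINK bed/bim/fam and delimited-text genotype input are supported with
    the usual missingness/HWE/MAF quality-control filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    knitr,
    MASS,
    optparse,
    readr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
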