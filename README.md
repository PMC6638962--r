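# gweischeck

Quick assessment of systematic inflation or deflation in genome-wide
environment interaction studies (GWEIS) — *before* running the scan.

## The problem

A GWEIS tests, at every locus, the joint effect of a genotype and its
interaction with an environment variable: a 2-degree-of-freedom score test
of the block `(g, g×E)` on top of a null regression of the phenotype on
covariates and the environment main effect. When that null model is
misspecified — a skewed phenotype, a missing covariate, a nonlinear
environment effect, gross outliers — *every* locus-wise statistic drifts up
or down together, producing genome-wide inflation or deflation that is easy
to mistake for (or to hide) real signal.

The usual check is to run the whole scan and inspect the mean statistic

```
l_mean = mean(t_l) / p
```

(`p` = degrees of freedom of the test; for the Gaussian family the per-locus
statistics are first rescaled to the chi-squared scale). That costs a full
genome scan per phenotype–environment pair, which is prohibitive when
screening, say, five phenotypes against a hundred candidate environment
variables.

## The idea

Under independent genotypes, the expected per-locus joint statistic has a
closed-form, **genotype-free** approximation computable from the null model
alone:

```
t_approx = tr(A⁻¹ B),   A = Σᵢ x̃ᵢx̃ᵢᵀ (Q_Z̃)ᵢᵢ,   B = Σᵢ x̃ᵢx̃ᵢᵀ (Q_Z̃ ũ)ᵢ²
```

where `x̃ᵢ` are the weighted rows of the tested multiplier design
`X = [1, E]`, `(Q_Z̃)ᵢᵢ` is the complement of the leverage of the weighted
null design, and `(Q_Z̃ ũ)ᵢ` are the projected weighted residuals. Dividing
by `p` (after the same chi-squared rescaling for the Gaussian family) gives

```
l_approx ≈ l_mean
```

in a fraction of a millisecond, with no genotype data at all. `l_approx ≈ 1`
means the scan would be well calibrated; large departures flag the null
model before any scan is run. When the phenotype is the problem, a Box–Cox
transformation optimised for `|l_approx − 1|` (rather than for normality,
which is not the same thing and often insufficient) repairs the calibration.

The method follows the published account of this approximation; the
simulation scenarios shipped in the package reproduce that study's design,
and the test suite reproduces its summary tables at reduced scale.

## Worked example

A phenotype with a quadratic environment effect, analysed with a linear
null — the classic misspecification the diagnostic is built to catch:

```r
library(gweischeck)
set.seed(42)
n <- 2000
d <- data.frame(age = rnorm(n, 60, 8), e = rnorm(n))
d$y <- 0.02 * d$age + d$e^2 + rnorm(n)

fit <- fit_null(d, pheno = "y", covar = "age", env = "e")
l_approx(fit)
#> # A tibble: 1 × 6
#>   t_approx T_approx l_approx  p_df family   flag
#>      <dbl>    <dbl>    <dbl> <int> <chr>    <chr>
#> 1     14.5     4.68     2.34     2 gaussian problematic
```

The scan-free diagnostic predicts 2.34-fold inflation. A real joint GxE
scan over 500 simulated independent loci confirms it:

```r
G <- simulate_genotypes(n, 500, seed = 7)
glance(genome_scan(fit, G))
#> # A tibble: 1 × 10
#>   mode  family    p_df t_mean T_mean l_mean lambda_median lambda_mean n_loci
#>   <chr> <chr>    <int>  <dbl>  <dbl>  <dbl>         <dbl>       <dbl>  <int>
#> 1 joint gaussian     2   14.3   4.62   2.31          2.12        2.31    500
#>   n_skipped
#>       <int>
#> 1         0
```

Repair the phenotype with the Box–Cox transformation chosen to drive
`l_approx` to one (the normality-optimised transformation would not fix
this), then re-scan:

```r
bc <- optimize_lapprox(d, "y", covar = "age", env = "e")
glance(bc)
#> # A tibble: 1 × 5
#>   criterion lambda criterion_value l_approx_before l_approx_after
#>   <chr>      <dbl>           <dbl>           <dbl>          <dbl>
#> 1 lapprox    -1.16   0.00000000158            2.34          1.000

d$y_bc <- bc$y_transformed
glance(genome_scan(fit_null(d, "y_bc", covar = "age", env = "e"), G))
#> # A tibble: 1 × 10
#>   mode  family    p_df t_mean T_mean l_mean lambda_median lambda_mean n_loci
#>   <chr> <chr>    <int>  <dbl>  <dbl>  <dbl>         <dbl>       <dbl>  <int>
#> 1 joint gaussian     2 0.0107   2.04   1.02          1.02        1.02    500
#>   n_skipped
#>       <int>
#> 1         0
```

To triage many candidate environment variables at once, sweep them without
touching genotypes:

```r
l_approx_sweep(d, pheno = "y", covar = "age", env = c("e", "..."))
```

## What's in the package

| Area | Functions |
|---|---|
| Null model | `fit_null()`, `fit_null_matrix()`, `dichotomize_at_mean()` |
| Score tests | `joint_gxe_stat()`, `marginal_stat()`, `genome_scan()`, `gaussian_rescale()` |
| Scan-free diagnostic | `l_approx()`, `t_approx_stat()`, `l_approx_sweep()`, `mc_oracle_mean_t()` |
| Box–Cox | `optimize_lapprox()`, `optimize_normality()`, `boxcox_transform()`, `shift_positive()` |
| Simulation | `simulate_genotypes()`, `code_genotype()`, `scenario_spec()`, `generate_scenario_data()`, `run_replicates()` |
| Diagnostics | `genomic_lambda()`, `gc_adjust()`, `cooks_flags()`, `qq_points()` |
| Files & QC | `read_plink()`, `write_plink()`, `read_dosage_tsv()`, `write_dosage_tsv()`, `hwe_test()`, `qc_filter()`, `align_samples()` |

Both Gaussian (quantitative) and binomial (case/control, logistic)
phenotypes are supported throughout; environment variables may be
multivariate.

A command-line interface is installed at `exec/gweischeck` inside the
installed package (`system.file("exec", "gweischeck", package = "gweischeck")`),
with subcommands `lapprox`, `scan`, `simulate`, `boxcox`, `diagnose` and
`make-fixtures` operating on PLINK bed/bim/fam filesets and TSV phenotype
tables.

## License

MIT (see `LICENSE`).
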