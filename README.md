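# betaimt

Specification testing for the beta distribution in its mean–precision
parametrization.  Fractional data — mortality rates, proportions, fractions
of a population — are commonly modelled as i.i.d. draws from the beta law
B(μ, ϕ), with density

    f(y; μ, ϕ) = Γ(ϕ) / (Γ(μϕ) Γ((1−μ)ϕ)) · y^{μϕ−1} (1−y)^{(1−μ)ϕ−1},
    0 < y < 1,   E(Y) = μ,   Var(Y) = μ(1−μ)/(1+ϕ).

`betaimt` answers the question practitioners rarely test formally: *is
that model actually compatible with the data?*  It implements information
matrix misspecification tests, which check the information matrix equality
A(θ0) + B(θ0) = 0 (expected Hessian plus expected score outer product)
through the sample restriction vector Dn(θ̂).  All statistics are the
quadratic form ζ = n Dnᵀ V⁻¹ Dn over q = 2 active restrictions; the five
variants differ in the covariance estimate V and the reference law:

* `zeta1` — White covariance, asymptotic χ²_q critical values;
* `zeta2` — Chesher–Lancaster covariance (no third-order derivatives), χ²_q;
* `zeta3` — parametric-bootstrap estimate of the exact finite-n covariance,
  Hotelling T²(q, B−1) reference via its scaled-F form;
* `zeta1B`, `zeta2B` — the ζ1/ζ2 statistics compared against parametric
  bootstrap critical values (each resample refitted and re-scored).

The asymptotic variants are strongly liberal in small samples; the
bootstrap variants hold their nominal size down to n = 50.  The package
also ships the surrounding study apparatus: a Monte Carlo harness for
size and power experiments (with size-adjusted power and plot-ready
p-value / size–power curves), samplers for the alternative laws used to
probe power (Kumaraswamy, unit Weibull, simplex, beta with a neglected
logit mean regression, zero-inflated beta), and an applied workflow for
rate datasets with cluster-robust standard errors and information-criteria
comparison against competing unit-interval laws.

For whom: statisticians and epidemiologists fitting beta models to rates
and proportions who want a calibrated goodness-of-specification check,
and anyone reproducing or extending the associated size/power study.

## Worked example

```r
library(betaimt)
set.seed(1)
y <- rbeta_mp(100, 0.2, 40)        # a correctly specified sample
beta_fit(y)
#> Beta distribution fit (mean-precision parametrization)
#>   mu  = 0.2053 (0.0061)
#>   phi = 43.4407 (6.1019)   [expected_info SEs]
#>   log-likelihood 140.2234 on n = 100; converged: TRUE (|grad| = 5.18e-13)

imtest(y, "zeta1B", B = 500, seed = 2)
#> Information matrix test (zeta1B) for beta specification
#>   statistic = 1.0180, q = 2, reference: parametric bootstrap, B = 500
#>   p-value = 0.6986
```

The MLEs are close to the truth and the bootstrap test finds no evidence
against the beta specification (p = 0.70), as it should.  On a
heterogeneous sample — the bundled synthetic fixture pooling two beta
regimes with different means and precisions, mimicking rates collected
across two structurally different reporting periods — the battery reacts:

```r
d <- synthetic_state_rates("period2", seed = 3)   # n = 50, two regimes pooled
analyze_rates(d, B = 500, seed = 4)
#> Beta specification analysis of 'synthetic-period2' (n = 50)
#>   mu  = 0.1438 (0.0119)
#>   phi = 15.2813 (0.9697)   [clustered SEs]
#> Information matrix tests (B = 500):
#>   zeta1B  statistic =   3.1322   p-value = 0.3054
#>   zeta2B  statistic =  36.5333   p-value = 0.0060
#>   zeta3   statistic =   1.4358   p-value = 0.4890
#> Information criteria (smaller is better):
#>        family  loglik      AIC     AICc      BIC     HQIC
#>          beta 56.6000 -109.200 -108.945 -105.376 -107.744
#>   kumaraswamy 56.0446 -108.089 -107.834 -104.265 -106.633
#>  unit_weibull 57.3327 -110.665 -110.410 -106.841 -109.209
#>       simplex 58.5663 -113.133 -112.877 -109.309 -111.676
```

The pooled fit's precision collapses (ϕ̂ ≈ 15 versus ≈ 40 in either
single regime) and `zeta2B` rejects the beta specification at the 1%
level, while the flexible simplex law tops the criteria table — the
pattern expected when heterogeneity, not the marginal family, is the
problem.  Note the test variants disagree here by design: `zeta3` has
little power against this symmetric-overdispersion alternative at small
n (see the vignette).

Monte Carlo experiments use the same machinery:

```r
cfg <- sim_config(dgp_spec("beta", mu = 0.2, phi = 40), n_grid = 100,
                  alpha_grid = 0.10, reps = 2000, tests = c("zeta1", "zeta2"),
                  seed = 11)
run_size(cfg)$rates
#>    test   n alpha  dgp   rate   mc_se reps
#>   zeta1 100   0.1 beta 0.1740 0.00848 2000
#>   zeta2 100   0.1 beta 0.3865 0.01089 2000
```

— the documented small-sample liberality of the asymptotic variants
(17–39% rejection at a nominal 10%).

A thin command-line wrapper for shell use lives at
`inst/scripts/betaimt-cli.R` (`fit`, `test`, `compare`, `simulate`).

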