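# rglmi

Multiple imputation of mixed binary/continuous data under the
**restricted general location (RGL) joint model** and by **chained
equations (FCS)** with the compatible linear and logistic conditionals —
plus the machinery to compare the two routes head to head.

## Why

When missing data are handled by multiple imputation, the practitioner
chooses between a *joint model* (draw missing values from the posterior
predictive of one joint distribution) and *full-conditional
specification* (cycle through one regression per partially observed
variable). For mixed binary and continuous data, the default FCS
conditionals — main-effects linear and logistic regressions — are
exactly the conditionals of an RGL model:

```
P(Y = y) ∝ exp(θ_y' y + y' θ_yy y)          (main effects + pairwise interactions)
W | Y    ~ N(θ_w0 + θ_wy Y, θ_v)            (common residual covariance)
```

so the two routes impute from the same distribution asymptotically.
That equivalence does **not** make the pooled (Rubin's rules) estimators
equally efficient, nor equally robust when the joint model is wrong.
`rglmi` implements both engines and the estimators, scenarios and
simulation studies needed to quantify both gaps:

* `rgl_impute()` — data-augmentation Gibbs sampler for the (C)RGL model:
  Bayesian iterative proportional fitting for the pairwise log-linear
  layer, conjugate matrix-normal/inverse-Wishart draws for the Gaussian
  layer, exact conditional draws of the missing values.
* `fcs_impute()` — chained equations with Bayesian linear draws and
  approximate-posterior logistic draws (Firth fallback under
  separation).
* `implied_logistic()`, `implied_linear()` — closed-form conditionals of
  an RGL/CRGL model (the compatibility identities).
* `fit_logistic()`, `fit_lda()`, `fit_linear()`, `fit_loglinear4()`,
  `estimate_marginal_mean()`, `pool_rubin()`, `pool_analysis()` — the
  analysis models with Rubin's-rules pooling.
* `scenario()`, `missingness_spec()`, `apply_missingness()` — the
  synthetic generating mechanisms (with analytic truths) and MCAR/MAR
  masking.
* `asymptotic_re_lda_logistic()`, `exact_re_loglinear_logistic()`,
  `mi_re_simulation()`, `bias_study()`, `run_experiment()` — the
  relative-efficiency and robustness studies.

## A worked example

Generate the one-binary/two-continuous mechanism (Y ~ Bernoulli(0.3),
W1 | Y ~ N(10 + Y, 9), W2 | Y, W1 ~ N(9 + 8/9 + W1/9 + Y, 8 + 8/9)),
mask half of `Y` completely at random, impute with the joint-model
engine and pool a logistic regression:

```r
library(rglmi)
sc  <- scenario("lda_model", p = 0.3, gamma1 = 1, gamma2 = 1)
set.seed(1)
dat <- sc$sample(2000)
inc <- apply_missingness(dat, missingness_spec("MCAR", "Y", rate = 0.5),
                         roles = sc$roles, seed = 2)
imp <- rgl_impute(inc, M = 25, seed = 3)
pool_analysis(imp, "logistic", "Y", c("W1", "W2"))
#> Rubin's-rules pooled logistic estimate (M = 25 )
#>             estimate     se
#> (Intercept)  -2.4687 0.3172
#> W1            0.0464 0.0192
#> W2            0.1002 0.0242
round(sc$truth$logistic, 3)
#> (Intercept)          W1          W2
#>      -3.183       0.099       0.112
```

The pooled estimates sit within three pooled standard errors of the
analytic truth (the implied coefficients of the generating model); at
n = 2000 with half the outcomes missing that is the expected precision
for a single dataset.
Complete-data efficiency comparisons need no simulation at all when the
variables are all binary — the expected informations are 16-cell sums:

```r
exact_re_loglinear_logistic(c(3, 3, 3))
#> Relative efficiency (%): log-linear vs logistic, complete data (exact)
#>   scenario: four_binary (3,3,3)
#>   parameter    re
#> 1    theta1 105.4
#> 2   theta12 102.2
#> 3   theta13 102.2
#> 4   theta14 102.2
```

Even at the strongest published association setting, fitting the joint
log-linear model buys at most ~5% asymptotic efficiency over the implied
logistic regression.

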