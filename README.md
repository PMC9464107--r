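# pmqlreg

Count data in epidemiology, insurance and sports statistics are routinely
*overdispersed* — the conditional variance exceeds the conditional mean —
and their covariates are often nearly collinear, which makes maximum
likelihood coefficient estimates explode in variance.  `pmqlreg` addresses
both problems at once: it fits the **Poisson–Modification-of-Quasi-Lindley
(PMQL) regression model** for overdispersed counts and stabilises the fit
under multicollinearity with **Liu and ridge shrinkage estimators**.

## The model and the estimators

The PMQL law is a mixed Poisson distribution whose pmf is a two-component
mixture of a geometric and a negative binomial,

    P(Y = y) = p·Geom(y; θ/(1+θ)) + (1−p)·NB(y; δ, θ/(1+θ)),
    p = α³/(α³+1),

with mean μ = (α³+δ)/((α³+1)θ) and variance μ + μ²·c/(α³+δ)², where
c = α³(α³+2+δ(δ−1)) + δ; the index of dispersion is always above one.
Regression enters through the log link log μᵢ = xᵢ′β and the
reparameterization θᵢ = (α³+δ)/((α³+1)·exp(xᵢ′β)).  Coefficients are
estimated by iteratively weighted least squares with model-based weights;
the converged fit carries X′ŴX = ΓΛΓ′, the canonical coefficients Γ′β̂, the
covariance (X′ŴX)⁻¹, and the scalar mean square error SMSE = Σⱼ 1/λⱼ.

Under collinearity the smallest eigenvalues λⱼ inflate the SMSE, and the
package provides the two classical remedies with their full MSE theory:

* **Liu estimator** β̂(d) = (X′ŴX+I)⁻¹(X′ŴX+dI)β̂ with d ∈ [0,1]
  (d = 1 is the plain fit), with selectors D1–D5 built from
  gⱼ = (α̂ⱼ²−1)/(1/λ̂ⱼ+α̂ⱼ²);
* **ridge estimator** β̂(k) = (X′ŴX+kI)⁻¹X′ŴX β̂ with k ≥ 0, with
  selectors k2, k7, k12;

plus matrix-superiority checks (`theorem1_check()`, `theorem2_check()`)
that certify MSE dominance through a quadratic form in the bias vector,
and a Monte Carlo engine (`sim_cell()`, `sim_factorial()`) that estimates
each estimator's SMSE = E‖β̂−β‖² over factorial designs with controlled
collinearity.

## Worked example

A severely multicollinear, strongly overdispersed data set (n = 400 counts,
p = 4 covariates with pairwise correlation 0.9998, generating coefficients
(1, 0.5, 0.5, 0.5, 0.5), dispersion α = 0.25, δ = 0.04):

```r
library(pmqlreg)

d <- sim_fixture("multicollinear-overdispersed", seed = 42)
sample_stats(d$y)
#>   skewness excess_kurtosis dispersion_index
#> 1     12.9            181.             941.

fit <- pmql_fit(d, y ~ ., alpha = 0.25, delta = 0.04)
glance(fit)
#>   logLik   AIC  smse condition_number  nobs n_iter converged
#> 1  -435.  881.  937.           21259.   400     44 TRUE
```

The response is wildly overdispersed (dispersion index 941) and the design
is severely ill-conditioned (condition number 21259, far above the usual
1000 alarm).  The unshrunken coefficients show the classic symptom — slope
estimates of ±14–26 with standard errors of 15–16, even though the data
were generated with every slope equal to 0.5:

```r
tidy(fit)
#>   term        estimate std.error statistic  p.value
#> 1 (Intercept)    0.957     0.248     3.86  0.000114
#> 2 x1            26.3      15.4       1.71  0.0870
#> 3 x2            13.7      15.4       0.887 0.375
#> 4 x3           -15.2      14.7      -1.04  0.299
#> 5 x4           -22.9      15.8      -1.45  0.146
```

The D5-selected Liu estimate (here d = 0, maximal shrinkage) pulls the
slopes back to 0.36–0.51 — close to the generating 0.5 — with standard
errors nearly 200 times smaller:

```r
liu <- liu_estimate(fit, select_d(fit, "D5"), selector = "D5")
tidy(liu)
#>   term        estimate std.error     bias
#> 1 (Intercept)    0.908    0.233   -0.0488
#> 2 x1             0.511    0.0794 -25.8
#> 3 x2             0.470    0.0795 -13.2
#> 4 x3             0.373    0.0808  15.6
#> 5 x4             0.359    0.0787  23.3
```

(The reported `bias` and plug-in SMSE evaluate the shrinkage bias at the
unstable β̂ itself, so they are pessimistic exactly when shrinkage helps
most; the Monte Carlo engine, which knows the generating β, is the honest
judge of estimator quality.)  One such comparison:

```r
sim_cell(n = 100, p = 2, rho = 0.99, beta0 = 1, alpha = 0.25, delta = 0.04,
         reps = 200, seed = 1, estimators = c("MLE", "LE(D5)", "RE(k2)"))
```

returns a tibble with the estimated SMSE and its Monte Carlo standard
error per estimator.

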