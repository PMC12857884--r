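# gplmbar

Broken adaptive ridge (BAR) variable selection and estimation for
**generalized partly linear models** — logistic or Poisson regression with a
high-dimensional penalized linear block (e.g. SNP dosages), unpenalized
indicator covariates, and nonparametric additive effects of continuous
covariates estimated by a Bernstein polynomial sieve.

The intended user is a biostatistician screening thousands of genetic
markers for association with a binary phenotype while clinical covariates
(age, BMI, ...) enter flexibly: the model is

```
g(E[y_i]) = beta' x_i + alpha' w_i + sum_j psi_j(z_ij)
```

where each smooth `psi_j` is expanded in the degree-m Bernstein basis
`B_k(z, m, c, u) = C(m,k) t^k (1-t)^(m-k)`, `t = (z-c)/(u-c)`, centered so
`psi_j` vanishes at the interval midpoint. Selection on `beta` uses the BAR
estimator — the limit of iteratively reweighted ridge fits

```
beta^(s) = argmin  -2 loglik + lambda_n * sum_j beta_j^2 / beta_j^(s-1)^2
```

initialized at a ridge fit with penalty `xi_n`. The limit carries exact
zeros and approximates L0 (best-subset) selection while every step is a
smooth convex problem. `lambda_n` is fixed by an information-criterion
preset rather than cross-validated: `2` (AIC), `log n` (BIC), or
`log(log n) log p` (HBIC) for `p >> n`.

## Worked example

Simulate a benchmark dataset (n = 600 observations, p = 300 correlated
Gaussian covariates of which 5 are truly active, 5 binary covariates, 4
continuous covariates with nonlinear effects) and fit with the BIC preset:

```r
library(gplmbar)
sim <- gen_scenario("1", n = 600, p = 300, seed = 42)
fit <- fit_gplm_bar(sim$data, control = bar_control(lambda_rule = "bic"))
print(fit)
#> GPLM-BAR fit (logistic family): n = 600, p = 300
#>   lambda = 6.397, xi = 1 | 16 outer iterations (converged)
#>   selected 5 covariate(s); log-likelihood -241.5131
#>    x1=0.867, x2=-1.049, x298=-0.752, x299=0.766, x300=0.906
compute_metrics(fit$coef$beta, sim$truth)
#>         mse TP FP FN MS MC TM
#> 1 0.1175993  5  0  0  5  0  1
```

The fit recovered exactly the five true covariates (coordinates 1, 2, 298,
299, 300; truth `(1, -1, -1, 0.75, 0.75)`): TP = 5 true positives, FP = 0
false positives, TM = 1 (exact support recovery), and quadratic-form error
`(beta_hat - beta0)' Sigma_X (beta_hat - beta0) = 0.118` against the true
AR(1) design covariance. Replicated studies aggregate these metrics:

```r
run_study("1", 600, 300, reps = 20,
          methods = list(bar_bic = bar_control(lambda_rule = "bic"),
                         oracle = "oracle"), base_seed = 100)$table
#>    method       MMSE    MMSE_SD   TP FP   MS   MC TM_pct
#> 1 bar_bic 0.29485364 0.18657010 4.85  0 4.85 0.15     85
#> 2  oracle 0.05946638 0.05354964 5.00  0 5.00 0.00    100
```

Smooth estimates come from the fitted sieve coefficients:

```r
grid <- seq(1, 5, length.out = 101)
psi1 <- evaluate_psi(fit$coef$gamma[1:4], grid, fit$spec, j = 1)
# psi1 tracks the true 0.1 * (z - 3)^2, exactly 0 at z = 3
```

SNP preprocessing for real dosage data (MAF filter, then univariate
logistic screening) and bootstrap standard errors:

```r
scr <- screen_snps(y, G, maf = 0.1, p_threshold = 0.1)   # G: n x p dosages
bse <- bootstrap_se(data, control = bar_control(lambda_rule = "aic"),
                    B = 100, seed = 1)
```

## Command line

```sh
Rscript exec/gplm-bar simulate --scenario 1 --n 600 --p 300 --reps 100 \
    --methods bar_bic,oracle --seed 7 --out study.csv
Rscript exec/gplm-bar fit --input data.csv --response y \
    --categorical w1,w2 --continuous age,logbmi --lambda-rule bic \
    --out-prefix results/fit
Rscript exec/gplm-bar screen --input dosages.csv --response y \
    --maf 0.1 --pvalue 0.1 --out-prefix results/scr
```

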