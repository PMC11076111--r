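# ismreg

Measurement-error-corrected estimation of the effect of higher education on
intelligence from pretest–posttest cohort data.

## The problem

Longitudinal studies estimate how much adult intelligence gains per year of
higher education by regressing an adult test score on years of education
with a childhood intelligence score as covariate. Two measurement problems
bias that analysis in opposite directions:

- the childhood score measures latent ability at the start of higher
  education only up to a test–retest reliability ρ < 1, so covariate
  adjustment removes the ability selection effect only partially and the
  remainder is misattributed to education (upward bias);
- the adult score often comes from a short test with a coarse, left-skewed
  discrete distribution, so its measurement error is correlated with
  ability and education (a generalized ceiling effect; bias direction
  depends on the discretization).

`ismreg` implements three nested estimators of the education effect
`b_HE` (IQ points per year) and the ability slope `b_start`:

| method | corrects | estimator |
|---|---|---|
| `estimate_cov()` | nothing (standard practice) | covariate-adjusted OLS |
| `estimate_eiv()` | pretest reliability | errors-in-variables regression |
| `estimate_ism()` | reliability + discretization | iterated-simulations fixed point |

All three solve the moment system

```
[ var(H)     cov(C,H)/ρ ] [ b_HE    ]   [ cov(A,H) − cov(e_after,H) ]
[ cov(C,H)   ρ·var(C)   ] [ b_start ] = [ cov(A,C) − cov(e_after,C) ]
```

(C = childhood score, H = centred years of education, A = observed adult
score). `cov` sets ρ = 1 and the error covariances to zero; `eiv` uses the
known ρ; `ism` additionally *simulates* the error covariances of the
discretized outcome at the current parameter guesses — drawing latent
start-of-education IQ consistent with the observed data, discretizing the
implied outcome with the observed scheme, and iterating to a fixed point
(typically four or five iterations at the default tolerance 0.01 with
D = 25 simulated datasets per iteration).

The package also provides the surrounding study machinery: rank-based
discretization schemes (`make_scheme()`, `numeracy_scheme()`),
selection-into-education simulators (`p_selection()`, `p2_selection()`,
calibrated multi-level `quota_selection()`), a synthetic cohort emulator
reproducing the reference cohort structure (`emulate_cohort()`),
nonparametric bootstrap inference (`bootstrap_estimates()`), per-level
model-fit diagnostics (`fit_diagnostics()`), reliability construction from
retest correlations (`estimate_reliability()`), preprocessing of raw
cohort extracts (`prepare_cohort()`), and reproducible simulation-study
runners (`run_toy_grid()`, `run_matched_study()`). Results are tibbles or
objects with `tidy()`/`glance()`/`autoplot()` methods throughout.

## Worked example

```r
library(ismreg)

# a synthetic cohort with the reference-design structure: n = 6766, education
# groups 3877/655/1808/426 at 0/2/6/10 years, latent group means
# -6.2/2.8/8.1/18.0, reliability 0.84, true b_HE = 0.45, b_start = 0.6,
# 23-level left-skewed adult measure
cohort <- emulate_cohort(seed = 11)

estimate_cov(cohort)
#> <he_fit: cov>  b_HE = 0.944 IQ points/year,  b_start = 0.459

estimate_eiv(cohort, rho = 0.84)
#> <he_fit: eiv>  b_HE = 0.403 IQ points/year,  b_start = 0.608  (rho = 0.84)

fit <- estimate_ism(cohort, rho = 0.84, seed = 12)
fit
#> <he_fit: ism>  b_HE = 0.474 IQ points/year,  b_start = 0.609  (rho = 0.84)
#>   converged: TRUE after 2 iterations (D = 25 , tol = 0.01 )
```

The true effect is 0.45: the standard covariate analysis roughly doubles
it, errors-in-variables over-corrects because of the discretized outcome,
and the iterated-simulations estimate lands near the truth. Per-level fit
diagnostics (observed minus final-iteration simulated mean adult IQ)
should be flat when the linear model fits:

```r
fit_diagnostics(cohort, fit)
#> # A tibble: 4 × 5
#>   level     n observed simulated difference
#>   <dbl> <int>    <dbl>     <dbl>      <dbl>
#> 1     0  3877    -4.99     -4.92    -0.0702
#> 2     2   655     2.41      1.80     0.615
#> 3     6  1808     6.65      6.68    -0.0312
#> 4    10   426    13.4      13.6     -0.175
```

A positive 2-year entry recurring *across replicates* (around +1.2 IQ
points, see `run_matched_study("nonlinear", ...)`) is the signature of a
front-loaded education effect that a linear model understates; within one
cohort it is sampling noise (replicate s.d. ≈ 0.5).

At study scale:

```r
study <- run_matched_study("linear", reps = 200, seed = 1)
tidy(study)
#> # A tibble: 3 × 5
#>   method mean_b_HE sd_b_HE mean_b_start  reps
#>   <chr>      <dbl>   <dbl>        <dbl> <int>
#> 1 cov        0.939  0.0502        0.450    200
#> 2 eiv        0.411  0.0614        0.595    200
#> 3 ism        0.460  0.0645        0.600    200
```

A command-line front end over the same functions ships in
`inst/cli/ismreg.R`:

```sh
Rscript inst/cli/ismreg.R estimate --method ism --rho 0.84 --csv cohort.csv
Rscript inst/cli/ismreg.R bootstrap --method ism --rho 0.84 --B 1000 \
    --csv cohort.csv --out results.json
```

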