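# mortraj

Bayesian age-specific mortality trajectories from annual
capture-mark-recapture (CMR) data.

Wild-population monitoring programmes mark individuals and redetect them
in some of the years they are alive; deaths are almost never observed.
`mortraj` estimates the full age trajectory of mortality from such data —
the setting it was built for is a 24-year nest-box study of the hazel
dormouse, a small hibernating rodent with a maximum lifespan of about six
years — and is aimed at population ecologists and biodemographers who want
survivorship curves, life expectancies and ageing (senescence) rates per
sex and demographic period, with honest posterior uncertainty.

## The model

The hazard at age *x* is the competing-risk (Siler-family) form

    mu(x) = exp(a0 - a1 x) + c + mu_a(x)

with an exponentially declining juvenile term, an age-independent term
`c`, and an adult component `mu_a` that is Gompertz
(`exp(b0 + b1 x)`), Weibull (`b0 b1^b0 x^(b0-1)`), or logistic
(`exp(b0 + b1 x) / {1 + b2 (e^b0/b1)(e^{b1 x} - 1)}`, reducing to Gompertz
at `b2 = 0`). From the cumulative hazard `U(x)` (closed form for all three
families) follow survivorship `S(x) = exp(-U(x))`, the age-at-death density
`f(x) = mu(x) S(x)`, life expectancy `e0 = ∫ S`, and the ageing rate
`d log mu / dx` at any age.

Inference is joint Metropolis–Hastings over the mortality parameters, the
annual detection probability `p`, and the latent birth/death years of
every record whose bounds leave them uncertain (deaths are bounded by the
last-recapture-plus-2-years rule and the 6-year maximum longevity). The
likelihood treats a death as interval-censored to its year, models annual
Bernoulli detection for every alive year in the study window, and
conditions on each animal having been detected at least once — the data
contain only marked animals. Models are compared by DIC, convergence by
the Gelman–Rubin statistic, and posteriors of any quantity are compared
between groups by calibrated Kullback–Leibler discrepancies in [0, 1],
with values above 0.75 read as evidence of a difference.

A synthetic-data generator (`simulate_cmr()`, `make_study_fixture()`)
draws datasets from exactly this observation process with known mortality,
so the whole pipeline is testable end to end without field data.

## Worked example

Simulate one stratum of 400 marked individuals from a known Siler-Gompertz
truth (life expectancy 0.928 years) with annual detection probability 0.6,
then fit it:

```r
library(mortraj)

truth <- mortality_params("gompertz", a0 = -0.5, a1 = 1.5, c = 0.72,
                          b0 = -2.6, b1 = 0.35)
life_expectancy(truth)
#> [1] 0.9278

strata <- tibble::tibble(sex = "female", start_year = 1999, end_year = 2006,
                         n = 400L, params = list(truth))
records <- simulate_cmr(sim_config(strata, p_detect = 0.6), seed = 42)
count_summary(records)
#> # A tibble: 1 × 3
#>   n_individuals n_detection_years n_captures
#>           <int>             <int>      <int>
#> 1           400               535         NA

fit <- run_mcmc(records, family = "gompertz",
                config = chain_config(n_chains = 3, n_iter = 10000,
                                      burn_in = 3001, thin = 10),
                seed = 1)
tidy(fit)
#> # A tibble: 6 × 6
#>   term   estimate std.error  conf.low conf.high  rhat
#>   <chr>     <dbl>     <dbl>     <dbl>     <dbl> <dbl>
#> 1 a0    -5.12e+ 0  7.19e+ 0 -2.11e+ 1   7.92e+0 1.00
#> 2 a1     1.27e+12  4.08e+13  3.70e- 9   9.79e+8 1.000
#> 3 c      4.97e- 1  4.73e- 1  6.53e- 9   1.10e+0 1.21
#> 4 b0    -6.75e+ 0  7.73e+ 0 -2.41e+ 1   9.12e-2 1.36
#> 5 b1     1.09e- 1  3.71e- 1  2.97e-10   1.34e+0 1.02
#> 6 p      6.04e- 1  3.14e- 2  5.39e- 1   6.65e-1 1.000

derived <- derived_posteriors(fit)
derived[derived$name %in% c("e0", "ar_2"), 1:5]
#> # A tibble: 2 × 5
#>   name     mean     se   lower  upper
#>   <chr>   <dbl>  <dbl>   <dbl>  <dbl>
#> 1 e0    0.973   0.0513  0.874  1.07
#> 2 ar_2  0.00229 0.0175 -0.0175 0.0443
```

Reading this: the detection probability (true 0.6) and life expectancy
(true 0.928) are recovered tightly; the individual juvenile parameters
`a0` and `a1` are honestly reported as unidentified at annual resolution
(enormous credible intervals along a likelihood ridge — see the methods
vignette), which is exactly why reporting centres on derived quantities
like `e0` and the ageing rates. The near-zero ageing rate at age 2
reflects the juvenile-plus-constant mortality dominating at this truth.

The full workflow — stratify by sex and period, fit all three adult
families, select by DIC, summarise, compare periods by calibrated KLD —
is one call:

```r
records <- make_study_fixture(seed = 1, scale = 0.5)
run <- run_full_analysis(records, seed = 1)
run$summary_table
run$kld_table
autoplot(run)
```

See `vignette("mortality-trajectories")` for the model, the likelihood
construction, numerical choices and limitations.

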