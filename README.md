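# lvcomposite

Latent-variable analysis of composite responder endpoints that mix two
continuous, one ordinal and one binary component — the structure of the
systemic lupus erythematosus (SLE) responder endpoint, where SLEDAI and
physician's-global-assessment changes (continuous), the BILAG organ grade
(five-level ordinal) and corticosteroid taper (binary) must *all* meet
their thresholds for a patient to count as a responder.

The usual analysis collapses everything into one 0/1 index and fits a
logistic regression, discarding most of the information. `lvcomposite`
instead treats the discrete components as thresholded latent Gaussian
variables and models all four components jointly:

- Y<sub>1</sub>, Y<sub>2</sub> observed continuous, with baseline
  adjustment: Y<sub>ij</sub> = intercept + effect·T<sub>i</sub> +
  slope·y<sub>ij0</sub> + ε<sub>ij</sub>
- Y\*<sub>3</sub>, Y\*<sub>4</sub> latent, cut at ordered thresholds
  τ<sub>13</sub> < … < τ<sub>43</sub> (ordinal) and at 0 (binary)
- (ε<sub>1</sub>, ε<sub>2</sub>, ε\*<sub>3</sub>, ε\*<sub>4</sub>) ~
  N(0, Σ) with free scales for the continuous components, unit latent
  variances and six free correlations (21 free parameters in all)

Overall response is the orthant event {Y<sub>1</sub> ≤ η<sub>1</sub>,
Y<sub>2</sub> ≤ η<sub>2</sub>, Y\*<sub>3</sub> ≤ τ<sub>43</sub>,
Y\*<sub>4</sub> ≤ 0}. After maximum-likelihood fitting, each patient's
response probability is computed under both counterfactual treatment
assignments and averaged, giving a marginal (covariate-standardised) odds
ratio with a delta-method standard error. The package also provides the
two comparator analyses (standard binary logistic regression and the
augmented binary joint model), a trial simulator with normal or
skew-normal errors for bias/coverage/power/relative-precision studies, and
a bootstrap bias-correction procedure.

## Worked example

```r
library(lvcomposite)

sc    <- baseline_scenario()          # calibrated generating model, n = 300
trial <- generate_trial(sc, seed = 2026)
fit   <- fit_latent(trial)
glance(fit)
#> # A tibble: 1 × 6
#>   logLik     n converged n_iter cov_repaired method
#>    <dbl> <int> <lgl>      <int> <lgl>        <chr>
#> 1 -1373.   300 TRUE          58 FALSE        latent

effect_measures(fit, trial, sc$criteria)
#> <lv_effect> method: latent
#>   p0 = 0.3088, p1 = 0.3546
#>   log-OR = 0.2070 (SE 0.1671), 95% CI [-0.1205, 0.5344], p = 0.2154
#>   OR = 1.230, RR = 1.148, RD = 0.046
```

`p0` and `p1` are the averaged counterfactual response probabilities (the
probability a patient from this trial would respond without and with
treatment), and the odds ratio compares them on the odds scale; this
replicate's estimate (OR 1.23) sits below the generating value of 1.58, as
single trials of n = 300 routinely do. The standard binary analysis of the
same trial is noticeably less precise:

```r
tidy(fit_standard_binary(trial, sc$criteria)$effect)
#> # A tibble: 1 × 12
#>   method             p0    p1 odds_ratio … log_or std.error …
#> 1 standard_binary 0.321 0.332       1.05 … 0.0521     0.257 …
```

Bias correction by resampling:

```r
bootstrap_bias_correct(trial, sc$criteria, method = "standard_binary",
                       n_boot = 200, seed = 1)
#> <lv_bootstrap> method: standard_binary  resamples: 200 ( 0 failed )
#>   original log-OR   0.0521
#>   bootstrap mean    0.0484  (bias -0.0037)
#>   corrected log-OR  0.0557
#>   95% percentile CI [-0.4703, 0.5323]
```

Simulation studies run through `run_scenario()` /
`performance_summary()` / `relative_precision()`, with
`plot_performance()` and `autoplot()` for figures, and
`bootstrap_bias_correct()` closing the loop on bias. A thin command-line
interface lives at `inst/cli/lvcomposite.R` (subcommands `fit`,
`simulate`, `bootstrap`).

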