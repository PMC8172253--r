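---
title: "Latent-variable analysis of composite responder endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable analysis of composite responder endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Composite responder endpoints class a patient as a responder only when
predefined thresholds are crossed in *every* component outcome. In systemic
lupus erythematosus (SLE) the endpoint combines two continuous
disease-activity measures (SLEDAI and the physician's global assessment), a
five-grade ordinal per-organ assessment (BILAG) and a binary corticosteroid
taper indicator. The usual analysis collapses all of this into a single 0/1
responder index and fits a logistic regression, discarding the information
in how far each patient was from each threshold.

This package keeps the components on their own scales for as long as
possible: the discrete outcomes are treated as thresholded versions of
underlying (latent) Gaussian variables, all four components are modelled
jointly, and only *after* fitting is the joint distribution collapsed into a
response probability. The package implements this latent-variable analysis,
the two standard comparators, a trial simulator for assessing the
operating characteristics of all three, and a bootstrap bias correction.

## The model

For patient $i$ with treatment indicator $T_i \in \{0,1\}$ and baseline
measures $y_{i10}, y_{i20}$:

$$
\begin{aligned}
Y_{i1} &= \alpha_0 + \alpha_1 T_i + \alpha_2 y_{i10} + \varepsilon_{i1} \\
Y_{i2} &= \beta_0 + \beta_1 T_i + \beta_2 y_{i20} + \varepsilon_{i2} \\
Y^*_{i3} &= \gamma_1 T_i + \varepsilon^*_{i3} \\
Y^*_{i4} &= \psi_0 + \psi_1 T_i + \varepsilon^*_{i4}
\end{aligned}
$$

$Y_{i1}, Y_{i2}$ are observed; $Y^*_{i3}, Y^*_{i4}$ are latent. The observed
five-level ordinal outcome is $Y_{i3} = w$ when
$\tau_{(w-1)3} \le Y^*_{i3} < \tau_{w3}$ with
$\tau_{03} = -\infty < \tau_{13} < \dots < \tau_{43} < \tau_{53} = \infty$,
ordered so level 1 is the best grade and level 5 the worst
("non-responder") category. The observed binary outcome is
$Y_{i4} = \mathbf 1\{Y^*_{i4} \ge 0\}$, with 0 the responder side. The
errors are jointly normal with covariance

$$
\Sigma = \begin{pmatrix}
\sigma_1^2 & \rho_{12}\sigma_1\sigma_2 & \rho_{13}\sigma_1 & \rho_{14}\sigma_1\\
\cdot & \sigma_2^2 & \rho_{23}\sigma_2 & \rho_{24}\sigma_2\\
\cdot & \cdot & 1 & \rho_{34}\\
\cdot & \cdot & \cdot & 1
\end{pmatrix}.
$$

Unit latent variances, $\gamma_0 = 0$ and the fixed binary cut-point at 0
are the usual probit identifiability constraints, not modelling
assumptions. An equivalent parameterisation would fix $\psi_0$ and estimate
the binary cut-point instead; we estimate $\psi_0$, which keeps all
thresholds fixed or ordered and the treatment effect interpretation
uniform across components.

Each patient's likelihood contribution factorises into the bivariate normal
density of $(Y_{i1}, Y_{i2})$ times the conditional probability of the
observed (ordinal, binary) cell — a rectangle probability of the
conditional bivariate normal of the latent pair given the continuous
outcomes. The conditional moments are the closed-form Schur complement of
the continuous block; a property-based test checks the closed forms against
generic multivariate-normal conditioning on random parameter sets.

### Response probability and treatment effect

Overall response is
$S_i = \mathbf 1\{Y_{i1} \le \eta_1,\, Y_{i2} \le \eta_2,\,
Y^*_{i3} \le \tau_{43},\, Y^*_{i4} \le 0\}$: response in both continuous
components, an ordinal grade below the top category, and binary taper
success. Its probability is an orthant probability of the 4-variate normal.
The integration region is a product of half-lines, so we evaluate it as a
multivariate normal CDF rather than by generic cubature: CDF evaluation is
deterministic, fast and directly testable against Monte-Carlo responder
fractions.

The treatment effect is the marginal (covariate-standardised) odds ratio:
for every patient we compute the response probability under treatment
($\tilde p_{i1}$) and under control ($\tilde p_{i0}$) at their own
baselines, average each over *all* patients in both arms (the natural
reading of per-patient counterfactual averaging; the alternative of
averaging each arm's own patients only was rejected because it conflates
the effect with baseline imbalance), and form

$$
\tilde\delta = \frac{\sum_i \tilde p_{i1} / (N - \sum_i \tilde p_{i1})}
                    {\sum_i \tilde p_{i0} / (N - \sum_i \tilde p_{i0})}.
$$

Risk ratio and risk difference come from the same averaged probabilities.
The variance of $\log\tilde\delta$ is first-order delta method,
$g^\top \widehat{\mathrm{Cov}}(\hat\theta)\, g$, with $g$ the numerical
gradient with respect to the *unconstrained* parameter vector. Note that
the responder thresholds on the latent scales are fitted quantities
($\tau_{43}$ and the fixed 0), so the gradient correctly propagates
cut-point uncertainty into the effect.

## Estimation

Optimisation runs on a 21-dimensional unconstrained scale:
$\sigma_j = e^{\omega_j}$, $\rho_{jk} = 2\,\mathrm{expit}(\omega_{jk}) - 1$,
and cut-points stored as $\tau_{13}$ plus three log-increments
$\tau_{(j+1)3} = \tau_{j3} + e^{\zeta_j}$, which guarantees ordering for
any real vector (the scale/correlation transforms follow standard practice
for this model class; the cut-point reparameterisation is our choice —
the constraint must hold at every optimiser iterate, not just the optimum).

* Starting values are deterministic and data-driven: least squares for the
  continuous outcomes, ordered probit (empirical-quantile fallback) for the
  ordinal, probit for the binary, and crude moment correlations from
  residuals and integer-coded outcomes clipped to $(-0.95, 0.95)$. These
  are documented package choices; nothing here is prescribed by the model.
* The objective is minimised with the PORT quasi-Newton routine
  (`nlminb`), relative objective tolerance `1e-8`, at most 500 iterations.
* Correlation combinations whose implied $\Sigma$ is not positive definite
  receive a penalty of `1e10` plus the distance to positive definiteness
  (the magnitude of the most negative eigenvalue), keeping the surface
  informative so the optimiser can back out of the invalid region.
* Cell probabilities are clipped at `1e-300` before logging to protect the
  quasi-Newton steps from `-Inf`.
* The covariance of the estimates is the inverse of the
  Richardson-extrapolated numerical Hessian (`numDeriv::hessian` with its
  standard second-derivative defaults: initial relative step 0.1, four
  extrapolation levels — small initial steps lose the Hessian to
  cancellation noise). A non-positive-semi-definite inverse is replaced by
  its nearest positive-definite matrix (Higham's alternating projections)
  and flagged; the repair applies to the covariance of the estimates only,
  since $\Sigma$ itself is kept valid by parameterisation plus penalty.

### Numerical evaluation of the normal probabilities

The bivariate normal CDF uses the Drezner–Wesolowsky/Genz Gauss–Legendre
algorithm (absolute error below `1e-14`). The 4-variate CDF uses
separation-of-variables: the two outer coordinates are integrated with
tensor Gauss–Legendre quadrature after the inverse-CDF transformation and
the inner pair collapses to one bivariate CDF per node. With the default 20
nodes per outer dimension the absolute error is about `1e-5`; simulation
loops use 12 nodes (error about `1e-4`), which is negligible against
replicate-to-replicate variation in the estimates (standard errors of the
log odds ratio near 0.17 at $n = 300$). Both routines are tested against an
independent Monte-Carlo oracle and an established multivariate-normal
implementation.

## Comparator methods

*Standard binary*: logistic regression of the collapsed responder index on
treatment and both baselines; the treatment coefficient and its Wald
standard error are used directly. This is a conditional odds ratio and is
reported as such — the deliberate mismatch with the latent method's
marginal estimand mirrors how the methods are compared in practice.

*Augmented binary*: a Gaussian linear model for one continuous component
(default `Y1`, configurable — the most informative continuous outcome
should be retained) and a logistic model for the indicator that collapses
the remaining three components, both on treatment and the two baselines.
As the fitted collapse model does not depend on `Y1`, the per-patient joint
response probability factorises exactly into the Gaussian tail times the
logistic probability. A documented variant flag adds `Y1` to the collapse
model (the classical form of this method); it is off by default so the
default matches the factorised form. Delta-method variances use the stacked
parameter vector of both sub-models with block-diagonal covariance (the two
likelihoods share no parameters), including the log residual scale with its
asymptotic variance $1/(2\,\mathrm{df})$.

## The simulator and the shipped scenarios

`generate_trial()` draws Gaussian baselines, allocates patients 1:1
(deterministic counts), draws the four error components jointly normal (or
skew-normal, below), forms the latent outcomes from the mean structure and
discretises. It emulates a single-timepoint randomised trial generated
exactly under the model. It does **not** emulate dropout or missing
components, longitudinal follow-up, measurement error in the baselines, or
non-Gaussian baseline distributions — passing simulation checks therefore
demonstrates correctness of the machinery and behaviour under (mild
departures from) the assumed model, not robustness to everything real data
can do.

The shipped baseline scenario is a **calibrated fixture**: the published
generating-parameter table for the original simulation study lives in
supplementary material that is not part of the sources available here, so
the package ships a parameter set whose correlation pattern is moderate and
positive (strongest among the three disease-activity components,
$\rho \approx 0.45$–$0.5$; weakest for the taper component,
$\rho \approx 0.2$–$0.25$) and whose thresholds and effects are solved —
via the exact marginal orthant probability — to give a control-arm response
probability of 0.280 and a treatment-arm probability of 0.380 (odds ratio
1.58). Unit residual scales, baseline slopes of 0.5 and standard-normal
baselines complete the fixture. Ordinal cut-points $(-1.65, -0.85, -0.05,
0.85)$ put roughly 5/15/28/32/20% of control patients in the five grades,
so every level is well occupied at $n = 300$. The driver-subset variants
loosen the thresholds of non-driving components (continuous to $\infty$;
ordinal/binary to values that block response for about 1% of patients — a
compromise that keeps the top ordinal level observable at $n = 300$, since
an empty level leaves its cut-point unidentified) and are re-calibrated to
the same 0.28/0.38 probabilities for comparability.

Performance criteria (bias, coverage, bias-corrected coverage, power, MSE)
are computed on the log-odds scale, the scale on which the Wald inference
is performed and effects are reported. Relative precision is the
per-replicate ratio of estimated variances of the log odds ratio. Note
that the *magnitude* of the latent method's precision gain is highly
sensitive to the generating correlation strengths: the stronger the
correlations, the closer the composite comes to being determined by the
continuous components and the larger the gain. The fixture's moderate
correlations therefore give conservative gains; users exploring their own
settings should treat the correlation pattern as the first dial to vary.

### Skew-normal sensitivity

`generate_trial_skew()` draws the errors from a multivariate skew-normal
with the model's $\Sigma$ as scale matrix and a user-specified slant
vector, implemented through the standard conditioning representation (an
auxiliary standard normal whose sign is reflected onto the error vector).
By default the errors are recentred to exactly zero mean — the mean of a
skew-normal is otherwise $\sqrt{2/\pi}\,\omega\delta$ — so that the mean
structure is preserved and any bias observed under skew reflects
distributional shape, not a shifted intercept; an uncentred option exists.
Slant magnitudes for specific published sensitivity scenarios are not
available in the sources here, so no defaults are pretended: the slant is
always user-specified, and the closed-form skew-normal skewness serves as
the test oracle for the generator.

## Bootstrap bias correction

The latent method can acquire bias when the joint-normality assumption
fails or effects are large. `bootstrap_bias_correct()` resamples whole
patient records with replacement from the pooled trial (an option
stratifies by arm, off by default to match the pooled procedure), refits
the chosen method, estimates bias as bootstrap mean minus original
estimate, and reports the corrected estimate
$2 \times \text{original} - \text{bootstrap mean}$ with a percentile
interval at the ordered-resample ranks $\lceil \alpha/2\, n_\text{boot}
\rceil$ and $\lceil (1 - \alpha/2)\, n_\text{boot} \rceil$. Because
"bootstrap estimate" is ambiguous between the bootstrap mean and the
corrected value, the result object reports both, labelled.

## Problem sizes used for desk-scale verification

Full-scale operating characteristics of this design are conventionally
estimated with thousands of replicates. For routine verification the
package uses smaller, fixed sizes chosen so the whole suite runs on a
single CPU in minutes: 150 replicates for the baseline operating
characteristics, 60 for the driver-subset and null scenarios, Monte-Carlo
oracles of $10^6$ draws, and a parameter-recovery fit at $n = 5000$. All
Monte-Carlo tolerances in the tests are computed from the replicate counts
actually used (three binomial or bootstrap standard errors), so shrinking
or growing the runs rescales the checks coherently. The acceptance script
uses 100/40 replicates for the same summaries.

## Known limitations

* Exactly two continuous, one five-level ordinal and one binary component;
  other endpoint structures need generalised code paths.
* Quasi-Newton ML with numerical derivatives: robust at this dimension
  (21 parameters) but not built for much larger latent systems.
* The marginal odds ratio is compared against the comparators' conditional
  odds ratio where noted; users should not read the difference as bias.
* Weighted-least-squares estimation, EM-type algorithms, copula
  dependence, longitudinal extensions and goodness-of-fit diagnostics are
  out of scope.
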