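---
title: "Modelling whole BMI distributions: methods behind colreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole BMI distributions: methods behind colreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colreg)
```

## The model

Classical analyses of body mass index dichotomise or categorise the outcome
first (obese yes/no, the four WHO classes, ...) and then fit a binary or
proportional-odds logistic regression. Every choice of categories yields a
different model with different parameters, and precision in the measured
heights and weights is thrown away. `colreg` instead models the conditional
distribution function itself:

$$\mathrm{logit}\, P(Y \le b \mid \text{stratum}, x) \;=\;
  \alpha_{\text{stratum}}(b) + x^\top\beta, \qquad b > 0 .$$

* One *intercept function* $\alpha_s(\cdot)$ per stratum. It must be
  monotonically increasing in $b$ (it parameterises a distribution
  function) but is otherwise unrestricted, so each stratum can have an
  arbitrary continuous outcome distribution — no normality or symmetry
  assumption. Stratifying on the exposure factors (e.g. smoking × sex)
  lets the exposure move *every* moment of the distribution, not just its
  location.
* A constant shift $\beta$ for the remaining covariates. This is the
  proportional odds assumption: $e^{\beta_j}$ is the odds ratio of the
  event $Y \le b$ for **every** cut-off $b$ simultaneously. The sign
  convention follows from modelling $P(Y \le b)$: $e^\beta > 1$ means
  higher odds of *lower* outcome values. This is the model's one real
  behavioural assumption, and the residual diagnostics below are designed
  to probe it.

Binary logistic regression at a single cut-off and proportional-odds
regression on the WHO classes are exactly the special cases in which
$\alpha_s$ is a step function with one or three steps; `colreg_fit_binary()`
and `basis = "step"` reproduce them, which provides strong independent
cross-checks (they must agree with `glm()` and with a brute-force
categorical MLE, and they do, to $10^{-5}$ and $10^{-4}$ in the test
suite).

With `link = "cloglog"` the same machinery estimates a fully parameterised
proportional-hazards (Lehmann) family instead; in a stratified model with
no covariates the two links describe the same set of distributions, and the
test suite checks that the fitted distribution functions agree to within
estimation error.

## The monotone Bernstein basis

Each $\alpha_s$ is a Bernstein polynomial of order $m$ (default 5, so six
coefficients per stratum) on a finite *support window* $[l, u]$:
$\alpha_s(b) = \sum_k \theta_{s,k}\, B_{k,m}\!\big((b-l)/(u-l)\big)$.
Because the Bernstein basis is a partition of unity with the variation
diminishing property, the response is monotone iff the coefficient vector is
non-decreasing — a finite set of linear constraints, which also acts as an
implicit regulariser: the effective dimension is below $m+1$, so no
smoothing penalty is needed. Order 5 is flexible enough for unimodal,
skewed BMI distributions; `order` is user-settable between 1 and 20, and
tied coefficients are allowed (they give locally flat distribution
functions, i.e. zero density).

**Support window.** By default the window spans the 1st–99th percentile of
the observation midpoints widened by 5 outcome units on each side, clamped
to the hard bounds (0 and $\infty$ for BMI). This keeps the flexible part of
the basis where the data are.

**Beyond the window.** Distribution functions must be defined for *all*
positive outcomes, so the transformation is continued linearly outside the
window, using the endpoint value and endpoint slope. This was a genuinely
open design point: linear continuation preserves monotonicity, keeps value
and first derivative continuous at the window edges (checked to $10^{-9}$
in the tests), and gives log-logistic-type tails that vanish quickly. At
the hard bounds themselves the CDF is pinned to 0 and 1 exactly.

## One likelihood for every measurement scale

Each subject contributes the probability of what was actually observed:

* **interval** $(b̲, b̄]$ — categories of any grid, or the rounding
  interval implied by reported height and weight —
  $F(b̄) - F(b̲)$, with $F = 0$/$1$ at the hard bounds;
* **"exact"** value $b$ — the conditional density, i.e. the limit of the
  interval contribution for vanishing width. The per-observation agreement
  between the density and a width-$2\times10^{-4}$ interval contribution is
  below $10^{-4}$ in the tests, which is the quantitative justification for
  treating measured values as "exact".

Scales can be mixed row by row (`apply_scheme()` supports per-subject
schemes), which is what makes pooled analyses of differently-coded studies
possible. Optional non-negative weights multiply the per-row
log-contributions.

The central empirical property — the *reason* to trust category-coded data —
is scale insensitivity: refitting the same synthetic sample (n = 5,000)
under exact and rounding-interval likelihoods moves the stratum
probabilities at the WHO cut-offs by less than 0.005 and the covariate odds
ratios by less than 0.01 (acceptance suite; `compare_scales()` reports the
same comparison for any dataset). Coarser grids lose a little more
information but remain consistent.

## Estimation

* **Constraints.** Each stratum block is reparameterised as
  $\theta_1 = \gamma_1$, $\theta_{k+1} = \theta_k + \mathrm{softplus}(\gamma_{k+1})$,
  which maps the admissible (non-decreasing) set one-to-one onto an
  unconstrained space. Optimisation is plain BFGS there, with an analytic
  score assembled on the probability scale (the density term uses the
  identity that the derivative of a Bernstein response is a non-negative
  combination of the coefficient increments, evaluated via the derivative
  basis rows).
* **Starting values.** The pooled weighted empirical CDF at the basis knots,
  pushed through the link, with increments floored at 0.05 — feasible and
  data-adaptive; $\beta$ starts at 0.
* **Tolerances.** The fit is declared converged when the score sup-norm
  falls below $10^{-6}(1 + |\ell|)$; up to two restarts from the current
  point are attempted first. 500 iterations maximum. All are settable via
  `colreg_control()`.
* **Degenerate contributions.** Interval probabilities and transformation
  derivatives are floored at $10^{-12}$ before the log; floored evaluations
  at the optimum are counted and reported in `glance()` rather than
  silently producing $-\infty$.
* **Covariance.** Central finite differences of the analytic score (step
  $10^{-5}(1+|\theta|)$) give the Hessian in the free parameterisation;
  its inverse is the reported covariance. Working in the free space keeps
  the Hessian well-defined under active constraints; natural-scale
  covariances (`vcov(fit, "natural")`, stratum contrasts) are obtained by
  the delta method through the softplus chain rule. The delta-method SE of
  a stratum log-odds-ratio agrees with a 500-replicate parametric bootstrap
  within 15% in the tests, and pooled 95% Wald coverage for $\beta$ across
  200 simulated cohorts of n = 2,000 sits near 0.96.
* **Separation.** At a cut-off with no events in a stratum the categorical
  MLE diverges; step-basis intercepts (and $\beta$) beyond ±25 flag the fit
  as divergent instead of returning silently. Bernstein tail coefficients
  are deliberately *not* policed: in regions of the support window with no
  data they sit in flat likelihood directions and may legitimately take
  extreme values without affecting any identified quantity.
* **Flat directions and reproducibility.** Those same flat tail directions
  mean two runs differing only in row order agree to optimizer precision in
  the identified quantities ($\beta$ to ~$10^{-5}$, all distribution
  function values to ~$10^{-4}$, the log-likelihood to $10^{-6}$ relative)
  but not bitwise in the data-free tail coefficients. The tests assert
  invariance of the identified quantities.

## Post hoc inference

`proportional_or()` exponentiates $\beta$ with Wald limits.
`stratum_or(fit, a, r, at = b)` evaluates
$\exp\{\alpha_a(b) - \alpha_r(b)\}$ — because the intercept functions are
smooth this works at *any* $b$, not only at the category boundaries used
during fitting; intervals are Wald on the log scale via the delta method
(Wald-on-log is the standard choice for such contrasts and is
bootstrap-validated in the tests). `cdf_table()` and
`colreg_curve()`/`autoplot()` evaluate the fitted distributions at
*baseline covariates*, interpreted as all design columns zero — reference
categories and zero/centred continuous covariates. Continuous covariates
are not centred automatically; centring (e.g. age at 40) is the caller's
choice and the generator's `age_c` column shows the intended pattern.

**Residuals.** $U_i = \hat P(Y \le b_i \mid s_i, x_i)$ is standard uniform
under a correctly specified model (the probability integral transform, the
analogue of Cox–Snell residuals). For interval rows, $U$ is evaluated at
the interval midpoint and flagged approximate (at the finite category
boundary for step fits). One practical subtlety, found while validating the
diagnostic: the *global* KS statistic has essentially no power against an
omitted covariate in a stratified model, because the flexible intercepts
simply absorb the covariate-marginalised mixture, whose PIT is uniform by
construction. Misspecification of $\beta$ must therefore be probed by
testing uniformity of $U$ **within covariate subgroups** (the test suite
demonstrates this with an omitted log-OR-3 covariate: subgroup KS
statistics inflate, global ones do not). Under correct specification the
global KS p-value exceeds 0.01 in at least 95 of 100 replicate fits at
n = 1,000.

## The synthetic cohort generator

There is no freely redistributable individual-level survey of this kind, so
the generator is a first-class module. `bmi_preset()` defines ground truth
as an exact member of the fitted family: ten strata (five smoking levels ×
two sexes) whose intercept coefficients are the logit of right-skewed
targets at the Bernstein knots on a [13, 45] window — medians near
22.3 kg/m² for females and 24.8 for males, with small smoking-level shifts —
plus shift coefficients for centred age, alcohol (g/day), fruit/vegetable
consumption, physical activity, education, nationality and language region
with odds-ratio magnitudes typical of population BMI surveys. Outcomes are
drawn by inverse-CDF sampling: a uniform draw is pushed through the
conditional quantile function (dense-grid inversion polished by Newton
steps, exact in the linear tails; cross-checked against bracketed
root-finding to $10^{-6}$). True height (by sex) and weight consistent with
the outcome are generated, then rounded to 0.01 m and 1 kg to produce the
reported values feeding the rounding scheme, whose endpoints
$((w-\tfrac12)/(h+0.005)^2,\,(w+\tfrac12)/(h-0.005)^2]$ always contain the
true value.

What the generator does **not** emulate: survey sampling design and
non-response, reporting bias in self-reported height/weight (only rounding
error), data-cleaning exclusions, and truncation. Passing tests therefore
demonstrate correctness of the estimator under the stated model, not
robustness to those real-data features.

## Problem sizes and runtime choices

The validation suite uses cohorts of 1,000–20,000 subjects: n = 2,000 for
the categorical-oracle equivalence, n = 5,000 for scale insensitivity,
n = 10,000 for point recovery, 200 replicates of n = 2,000 for interval
coverage, 100 replicates of n = 1,000 for PIT uniformity, and n = 20,000
for the generator round trip. These sizes put Monte Carlo noise comfortably
below each check's tolerance while keeping a full run of suite plus
acceptance script around ten minutes on one CPU. One statistical caveat is
made explicit in the round-trip test: with survey-like strata frequencies
the smallest of ten strata holds under a thousand subjects, whose binomial
noise floor exceeds a flat 0.02 probability band, so small strata are
checked against a 3.5-standard-error band instead.

## Known limitations

* $\beta$ is constant in $b$; outcome-varying coefficients (distribution
  regression with $\beta(b)$, conditional transformation models) are out of
  scope, as is automatic order selection for the basis.
* Left/right truncation (enrolment restricted to an outcome range) is not
  supported.
* Weights are plain per-row likelihood multipliers; design-based survey
  variance estimation is not implemented.
* The Hessian is numerical; for very large models an analytic Hessian
  would be faster, but the score is analytic and the finite-difference
  step is applied to it, not to the likelihood.
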