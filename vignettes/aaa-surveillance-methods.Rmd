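---
title: "Joint growth/rupture modelling and optimal intervention timing for AAA surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint growth/rupture modelling and optimal intervention timing for AAA surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Men with a small abdominal aortic aneurysm (AAA, 30–54 mm) detected by
screening enter a surveillance pathway: the aneurysm diameter is measured by
ultrasound at regular visits, and elective repair is currently offered once a
measurement reaches 55 mm. The 55 mm rule is a population-level compromise.
`aaadecide` implements a personalised alternative: model each subject's
latent growth curve jointly with their rupture hazard, convert the fitted
model into a dynamic conditional rupture probability that updates with every
new scan, and choose the elective repair time that maximises the subject's
expected remaining life-years given their age, operative risk and non-AAA
mortality.

## The joint model

The observed diameters are noisy versions of a smooth subject-specific
trajectory,

$$y_{ij} = m_i(t_{ij}) + \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \sim N(0, \sigma_\varepsilon^2),$$

with, in the default specification,

$$m_i(t) = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,t + \beta_2 t^2,
  \qquad b_i \sim N(0, \Sigma).$$

Growth accelerates slowly over surveillance time scales, which the fixed
curvature term captures; between-subject heterogeneity is carried by the
random intercept and random linear slope (`trajectory_spec()`). A purely
linear trend with random intercept is also available.

Rupture intensity follows a proportional-hazards sub-model sharing the
random effects:

$$h_i(t) = h_0(t)\, \exp\{\gamma^\top w_i + \alpha^\top f(m_i(t))\},$$

where `f` extracts features of the latent trajectory. Four association
structures are supported (`association()`): current value; slope only;
value and slope (the default, the most interpretable clinically — how big
the aneurysm is and how fast it is growing); and value plus cumulative area
under the trajectory. The baseline hazard is constant
(`exponential`, the default) or Weibull, parameterised as
$h_0(t) = e^{\lambda} k t^{k-1}$. Time is measured in years since study
entry and diameters in millimetres, so $\alpha_1$ is a log hazard ratio per
mm and $\alpha_2$ per mm/year.

The default parameter values (`aaa_growth_params()`) are estimates
representative of a large UK screening cohort of men with small AAAs:
$\beta = (36.5, 2.05, 0.097)$, $\sigma_\varepsilon = 2.91$,
$(\sigma_0, \sigma_1, \rho) = (6.63, 1.79, 0.567)$,
$\log h_0 = -11.0$ and $\alpha = (0.084, 0.579)$. They serve as the
generating values for the cohort simulator and as a worked-example model.

## Likelihood and fitting

Conditional on $b_i$ the longitudinal and event processes are independent,
so each subject contributes

$$L_i = \int \Big[\prod_j N(y_{ij}; m_i(t_{ij}), \sigma_\varepsilon^2)\Big]\,
   h_i(T_i)^{\delta_i}\, e^{-\int_0^{T_i} h_i(s)\,ds}\, N(b; 0, \Sigma)\, db.$$

Numerical choices, all configurable:

* **Random-effects integral.** Adaptive Gauss–Hermite quadrature with 9
  nodes per dimension (81 for the default two random effects). The grid is
  centred at each subject's conditional mode and rescaled by the curvature
  there. The log-integrand is strictly concave in $b$ (Gaussian terms plus
  a negated sum of exponentials that are linear in $b$), so the mode is
  found by a damped Newton iteration with analytic gradient and Hessian;
  this is why the quadrature remains stable even for subjects with extreme
  histories. Tests show 9 and 25 nodes agree to about $10^{-7}$.
* **Cumulative hazard.** $\exp(\text{polynomial})$ has no closed-form
  integral, so $\int h$ uses 15-point Gauss–Legendre quadrature on
  $(0, T_i)$. Against a $10^5$-step trapezoid oracle this is accurate to
  well below $10^{-6}$ relative for the exponential baseline; for a Weibull
  baseline the $t^{k-1}$ factor is mildly singular at 0 and accuracy drops
  to roughly $10^{-4}$ relative, which is ample for likelihood work.
* **Optimiser.** BFGS on an unconstrained scale: logs for
  $\sigma_\varepsilon, \sigma_0, \sigma_1$ and the Weibull shape,
  $\tanh^{-1}$ for $\rho$. Standard errors come from the numeric Hessian of
  the negative log-likelihood at the optimum, mapped back to the natural
  scale by the delta method.
* **Starting values.** Two-stage: `lme4::lmer` (maximum likelihood) for the
  growth parameters, then a Poisson working model for the hazard with
  empirical Bayes trajectories plugged in. Any starting point can be
  supplied instead; the longitudinal-only degenerate fit (event sub-model
  fixed off) reproduces the `lmer` solution to $10^{-3}$ from neutral
  starts.
* **Ties.** Repeated measurement times are allowed and treated as
  conditionally independent given $b$.

`fit_joint_model()` reports the log-likelihood, AIC
($-2\ell + 2\,\text{npar}$), the natural-scale estimates with standard
errors, and per-subject empirical Bayes modes. On synthetic data generated
with a quadratic trajectory, AIC comparison prefers the quadratic over the
linear specification, mirroring how the trajectory form is chosen in
practice.

## Dynamic prediction

For a subject alive at landmark time $t$ with measurement history
$Y_i(t)$, the probability of rupture by a future time $u$ is

$$F_i(u \mid t) = 1 - \int
  \frac{S_i(u \mid b)}{S_i(t \mid b)}\;
  p(b \mid T_i^* > t, Y_i(t))\, db ,$$

ignoring competing risks inside the predictive probability (non-AAA death
enters only in the decision model). `conditional_rupture_prob()` evaluates
this by Monte Carlo:

1. draw a parameter vector $\theta^*$ from the asymptotic normal
   distribution of the estimates, on the unconstrained scale so every draw
   is a valid parameter set;
2. draw $b^*$ from $p(b \mid T^* > t, Y(t), \theta^*)$ by a single
   independence Metropolis–Hastings step against a multivariate-$t$
   proposal (df 4, scale inflated twofold) centred at the conditional mode
   under the point estimates — the chain state carries over between
   iterations while the target is refreshed with each $\theta^*$;
3. compute the survivor ratio for each draw and summarise across draws by
   the mean and 2.5/97.5 percentiles.

The landmark convention applies throughout: measurements after $t$ are
never used. If no measurement precedes $t$ the posterior falls back to the
prior conditioned on survival alone, with a warning. Acceptance rates on
simulated subjects sit comfortably inside (0.1, 0.9), and seeded runs are
bit-reproducible.

When the prediction machinery is used with published estimates instead of a
fitted model (`as_jm_fit()`), parameter uncertainty is limited to the
reported standard errors treated as independent. Real estimate covariances
(in particular the strong negative coupling between $\log h_0$ and
$\alpha$) are then unavailable, so percentile bands and coefficients of
variation computed this way are conservative — wider than those a full
fitted covariance would give. This is the main reason uncertainty summaries
built from published values should be read qualitatively.

## The decision model

Let $p_E(a)$ be elective operative mortality at age $a$ and $p_R$ the
short-term case fatality of rupture, composed as
$p_R = (1 - q_s) + q_s\, p_{em}$: death before reaching emergency surgery
plus death from the emergency operation itself. Defaults
(`operative_risk()`): $p_{em} = 0.37$, $q_s = 0.45$ (so $p_R = 0.7165$),
and either a constant $p_E = 0.019$ (Model 1) or age bands
0.6% / 1.6% / 2.4% / 3.0% for <66, 66–75, 76–85, 86+ (Model 2, the
default).

Expected remaining life-years for an elective repair at time $T_x$ are

$$\mathrm{ELY}(T_x) = \int_t^{T_x} S_{\text{nonAAA}}(u)\,
  S_{\text{AAA}}(u \mid t)\, du
  + (1 - p_E(a_{T_x})) \int_{T_x}^{\infty} S_{\text{nonAAA}}(v)\, dv,$$

with $S_{\text{AAA}}(u \mid t) = 1 - F(u \mid t)\, p_R$ and
$S_{\text{nonAAA}}$ from a life table under a piecewise-constant annual
hazard (fractional years pro-rated on the hazard scale; ages beyond the
table are absorbing). Implementation choices:

* **Grid and integration.** Candidate times every 0.25 years (3-monthly)
  from $t$ up to the age-105 horizon; trapezoidal rule for both integrals.
  Halving the grid step moves the optimal value by less than 0.01 years in
  tests. Reaching the final grid point encodes "never operate": the
  post-operative term vanishes there by construction.
* **Post-intervention term.** As written above, the post-operative integral
  is not weighted by the probability of actually reaching $T_x$ free of
  AAA death. The default (`ely_variant = "literal"`) keeps that form; the
  self-consistent alternative multiplying the second term by
  $S_{\text{AAA}}(T_x \mid t)$ is available as
  `ely_variant = "aaa_weighted"`. The two differ only when rupture risk by
  $T_x$ is substantial.
* **Age coupling.** Age at a future time $u$ is baseline age plus $u$
  (times are years since study entry); the life table and the Model 2 bands
  are evaluated at that age.
* **Uncertainty.** The whole curve is computed per Monte-Carlo draw (1000
  by default); the per-draw argmax gives the distribution of the optimal
  time $T_{x,\text{opt}}$, reported with a percentile interval and the
  coefficient of variation of the *waiting time* $T_{x,\text{opt}} - t$
  (the CV of a quantity with an arbitrary origin is not meaningful). Ties
  at the argmax break to the earliest time, deferring risk the least. The
  point estimate is the argmax of the draw-averaged curve, and the diameter
  at the optimum substitutes the optimal time back into each draw's growth
  curve.
* **Threshold-policy comparison.** `compare_with_threshold_policy()` lets
  each draw's *latent* trajectory trigger surgery at the first grid time it
  reaches 55 mm (never, if it never crosses). Using the latent rather than
  a noisy measured trajectory makes the comparison a policy contrast rather
  than a measurement-process simulation; simulating measurement-triggered
  referral is out of scope here. The optimal policy dominates any fixed
  threshold draw by draw, up to grid resolution, by the argmax property.

A worked run for a 65-year-old presenting with a single 45 mm scan, using
the canonical parameter set, a synthetic Gompertz life table and Model 2:

```{r, eval = FALSE}
library(aaadecide)
fit <- as_jm_fit(aaa_growth_params())
subj <- subject_history("new", baseline_age = 65, times = 0, diameters = 45)
dec <- optimal_intervention(fit, subj, gompertz_life_table(),
                            operative_risk(model = 2),
                            t = 0, n_mc = 1000, seed = 1)
dec
```

## The synthetic cohort generator

`simulate_cohort()` emulates a screening surveillance programme: baseline
ages uniform on 65–74; subjects enter only if the *measured* baseline
diameter (latent value plus $N(0, \sigma_\varepsilon^2)$ error, as
screening actually observes it) lies in 30–54 mm; scans repeat annually
below 45 mm and 3-monthly at 45 mm and above, driven by the latest
measurement; follow-up ends at the first of rupture (the event), non-AAA
death drawn from the life table, the first scan at or above 55 mm
(referral, treated as censoring), or administrative censoring at 15 years.
Rupture times are drawn exactly, by solving $H(0, T) = E$ with
$E \sim \text{Exp}(1)$ via geometric bracketing and root-finding to
$10^{-6}$ years on the quadrature cumulative hazard.

At the default parameters and design the generator produces cohorts of the
scale the defaults describe — about 1100 subjects, roughly 6000
person-years, a mean follow-up near 5.5 years and event counts of the order
of 25–35 — which the acceptance script recomputes on every run.

Two deliberate properties matter for interpretation:

* **Threshold censoring is missing at random** — it depends only on
  observed measurements — so refitting on simulated cohorts recovers the
  generating parameters without systematic bias. The package's recovery
  tests check exactly this.
* **Baseline eligibility selection is not MAR-neutral for the
  population parameters**: conditioning entry on a 30–54 mm measured
  baseline truncates the random-intercept distribution, so the
  marginal-normal random-effects model then estimates the *screened*
  population's parameters (a larger mean intercept, a smaller intercept
  SD), not the generating ones — exactly as estimates from a real screening
  cohort describe the screened population. Parameter-recovery tests
  therefore run with the eligibility filter disabled, and the filter is
  kept for cohort-scale emulation. The true baseline-diameter distribution
  of a screened population is not identified by the window alone; the
  rejection-sampling window is an approximation.

What the generator does *not* emulate: loss to follow-up other than
administrative censoring, elective surgery uptake or contraindication,
measurement-error distributions other than Gaussian, and secular trends in
scan scheduling. Passing tests on these cohorts therefore demonstrate
internal consistency of estimator, predictions and decisions under the
stated model, not robustness to the messiness of real surveillance data.

## Discrimination

`dynamic_auc()` estimates, at landmark $t$ with window $\Delta t$, the
probability that a subject rupturing in $(t, t + \Delta t]$ receives a
higher predicted $F(t + \Delta t \mid t)$ than one surviving beyond
$t + \Delta t$ (ties count one half). Subjects censored inside the window
are excluded rather than reweighted — a documented simplification (no
inverse-probability-of-censoring weights). `ddi()` summarises landmarks
(yearly by default) by an average weighted by the number of events in each
window. Published dynamic-discrimination values for real cohorts are not
reproduction targets for this weighting; the package's checks are
structural (exact agreement with exhaustive pair counting, invariance to
monotone transforms of the risk scale) plus the qualitative level achieved
on large synthetic cohorts.

## Problem sizes used by the tests and acceptance script

The test suite favours many small, sharp checks: 3-subject likelihood
instances against $5\times 10^4$-draw Monte-Carlo integration;
$2\times 10^5$-draw event-time simulations for the survivor and
conditional-risk oracles; parameter recovery over 6 replicate cohorts of
600 subjects; decision checks at 100–300 Monte-Carlo draws. The acceptance
script uses a 1122-subject cohort for emulation and discrimination, one
600-subject refit, and 1000-draw decision quantities. These sizes are the
package's own choices balancing Monte-Carlo error against turnaround; all
scale up by changing one argument.

## Known limitations

* No competing-risks structure inside the rupture prediction (by design);
  non-AAA death enters only the decision layer.
* No spline or free-knot trajectories, no Bayesian/MCMC fitting, no left
  truncation.
* Discrimination has no censoring weights; with heavy within-window
  censoring the AUC estimates are biased toward the uncensored.
* The bundled Gompertz life table is a smooth synthetic stand-in; use a
  real national table for substantive work.
* Uncertainty from `as_jm_fit()` with published standard errors omits
  estimate correlations (see above); refit on data when the full
  covariance matters.
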