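---
title: "Estimating lifetime prevalence from aggregated rates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lifetime prevalence from aggregated rates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevpde)
```

## The estimation problem

Registries publish cancer incidence and mortality as rates over five-year
age groups and calendar years, and claims data can supply a prevalence
profile for a single baseline year. None of these sources follow
individuals over time, so prevalence in later years cannot be counted — it
has to be *reconstructed* from the relation between prevalence, incidence
and mortality. `prevpde` does this reconstruction for a progressive chronic
condition (no remission), reporting prevalence by single year of age (0–85),
sex, and calendar year, plus absolute survivor counts when multiplied with
population tables.

## Model

The illness-death model has three states — healthy, ill (ever diagnosed),
dead — and three transitions: incidence $i(t,a)$, mortality of the
non-diseased $m_0(t,a)$, and mortality of the diseased $m_1(t,a)$.
Writing $p(t,a)$ for the prevalence among those alive at calendar time $t$
and age $a$, the balance of flows gives

$$(\partial_t + \partial_a)\,p \;=\; (1-p)\,i \;-\; p\,(1-p)\,(m_1 - m_0).$$

$m_0$ is unobservable for most diseases, so it is eliminated using the
general-population mortality $m = p\,m_1 + (1-p)\,m_0$, which turns the
equation into the form actually solved:

$$(\partial_t + \partial_a)\,p \;=\; (1-p)\,i \;-\; p\,(m_1 - m).$$

The two forms are algebraically identical under the mixing relation; the
package uses the first (in $m_0$/$m_1$) only inside the synthetic-truth
generator, precisely so that the generator is an independent route from the
production solver. Note the structural guarantee $0 \le p < 1$: the
right-hand side is non-negative at $p=0$ and the $(1-p)$ factors prevent
crossing 1 whenever $m_1 \ge m$ (consistent inputs).

### Assumptions

* **Healthy at birth:** $p(t, 0) = 0$ for cohorts born inside the study
  window. For cancer this is a good approximation — newborns with cancer
  are not yet diagnosed and registered.
* **No remission:** "ever diagnosed" is an absorbing property; this is the
  lifetime-prevalence (cancer-survivor) definition, not a clinical-cure one.
* **Closed population:** no migration adjustment.
* **Cause-specific mode (default):** all deaths attributed to the disease
  occur among the diseased, and the diseased die of *other* causes at the
  same rate as the non-diseased, $m_0 = m - \mu_c$. Then
  $m_1 = \mu_c/p + m - \mu_c$ is the unique diseased mortality consistent
  with the mixing relation. These two assumptions are what makes
  cause-of-death statistics usable in place of unobservable cohort
  mortality; they ignore the (real) excess non-cancer mortality of cancer
  patients, which is why a direct `diseased_mortality` mode is also exposed.

## Numerical solution

The PDE's characteristics are lines of constant $a - t$ (birth cohorts),
along which it is an ODE. Every output cell $(t,a)$ lies on exactly one
characteristic, started either from the interpolated baseline profile at
$t_0$ (if the cohort was already alive then) or from $p=0$ at birth.
Characteristics are mutually independent, so the solution is embarrassingly
parallel and order-independent; the implementation advances all of them in
one vectorised sweep.

Numerical choices:

* **Scheme and step.** Default RK4 with step 0.1 year; explicit Euler is
  available for order-of-accuracy checks. The validation suite verifies the
  theoretical orders (error ×2 per halving for Euler, ×16 for RK4) against
  a step-$10^{-4}$ reference, and that the constant-incidence analytic
  solution $1 - e^{-ia}$ is reproduced to better than $10^{-6}$.
* **Cause-specific mode at $p = 0$.** $m_1 = \mu_c/p + m - \mu_c$ is
  singular at $p=0$, but the term the equation needs, $p\,(m_1-m)$, has the
  finite limit $\mu_c$; the solver uses that limit, which is exactly the
  value implied by the simplified algebra $(1-p)(i-\mu_c)$.
* **Clamping only at output.** Solutions are clamped into
  $[0, 1-10^{-9}]$ only when written to the output grid, and every clamp
  event is counted and reported. With consistent inputs the count is zero;
  a non-zero count flags a data problem rather than being silently hidden.
* **Negative excess.** $m_1 < m$ can occur with noisy inputs. It is legal,
  counted, and *not* clamped: forcing the excess to zero would bias
  prevalence upward invisibly.
* **Rate interpolation in time.** Rates between annual grid points are
  linear in $t$ (bilinear surfaces), consistent with the age interpolation.

## From published tables to rate surfaces

A five-year group $[L, L+4]$ covers continuous ages $[L, L+5)$ and is
anchored at its midpoint $L + 2.5$ — the standard demographic convention;
sources do not state their anchors, so this is a package choice. Between
midpoints values are interpolated linearly, outside the span of midpoints
they are held constant.

Two conventions matter at the boundaries:

* **Open 85+ group.** It pools all ages above 84 and has no defensible
  anchor age, so it contributes no node; values above 82.5 are constant.
  This is why the analysis stops at age 85, and it concentrates the method's
  error in ages 83–85 (see *Limitations*).
* **Anchor at birth.** Baseline prevalence below the youngest data age is
  anchored linearly to 0 at age 0 (`anchor_prevalence_at_birth = TRUE`),
  implementing the healthy-at-birth assumption when claims data only start
  at, say, age 15. Incidence and mortality tables are not anchored; their
  values below the youngest midpoint are constant.

## The synthetic scenario generator

Because the real claims and registry inputs are not redistributable, the
package ships a parametric generator whose truth is known exactly:

* incidence $i(t,a) = \alpha\, f_{\text{sex}}\, e^{\beta a}\,
  \max\{0,\, 1 + \gamma\,(t-t_0)\}$ — exponential in age, linear secular
  trend. The trend factor is clamped at zero so rates stay non-negative for
  cohorts born long before the study window; this makes the oldest cohorts'
  histories start later, a deliberate simplification.
* background mortality $m_0(a) = a_G\, e^{b_G a}$ (Gompertz, time-constant);
* diseased mortality $m_1 = m_0 + \delta(a)\,\max\{0,\,
  1 - \eta\,(t-t_0)\}$ with constant excess $\delta$ by default and an
  optional declining trend $\eta$.

Defaults ($\alpha = 10^{-5}$, $\beta = 0.09$, $\gamma = 0.02$,
$a_G = 2\times10^{-5}$, $b_G = 0.095$, $\delta = 0.02$, males at 1.3×
female incidence) were fixed once to emulate cancer registry magnitudes:
incidence of roughly 2 per 100 person-years at age 85, lifetime prevalence
rising to about 0.2–0.35 at the oldest ages (the range reported for cancer
in high-income countries, with males above females), and general mortality
around 0.06/yr at 85. The male factor of 1.3 reflects the well-documented
male excess in cancer incidence.

The true prevalence is obtained by integrating the cohort ODE (the
$m_0/m_1$ form) at step $10^{-3}$ years; the generator then emits the
*consistent* general mortality $m = p^* m_1 + (1-p^*) m_0$ and
cause-specific mortality $\mu_c = p^*(m_1 - m_0)$, so the mixing relation
holds at every node by construction, and a deterministic population table
whose survivorship follows $m$ (optionally with a Gaussian birth-cohort
bump mimicking a baby boom).

`aggregate_to_groups()` collapses the truth into the registry schema using
**person-time-weighted averages** over each group (weights from the implied
survivorship) rather than midpoint sampling — this mimics how registries
compute rates (events over person-years) and deliberately reproduces the
mismatch between grouped data and midpoint interpolation that a real
analysis faces.

What the generator does **not** emulate: claims-data ascertainment
artifacts (under-documentation, the two-quarter confirmation rule),
registry completeness corrections, migration, cohort effects beyond the
linear trend, and rate noise. Passing the validation suite therefore shows
the *method* recovers a truth of this smooth structure from its aggregated
form; it does not certify accuracy under real-data artifacts.

## The microsimulation oracle

An independent check that cannot share the solver's discretisation errors:
individuals are simulated through the three states in discrete time
(default $dt = 0.05$ years), with per-step exit probabilities
$1 - e^{-\text{rate}\,dt}$ evaluated at the current $(t, a)$ and a healthy
individual's exit split between illness and death in proportion to the
competing rates. One shared random stream per run makes results exactly
reproducible from the seed. Prevalence estimates among the alive carry
binomial standard errors, and `oracle_comparison()` checks the PDE cell-wise
against them within $3\,\mathrm{SE} + 0.002$, the allowance covering the
discretisation bias of both sides (at $dt = 0.05$ and rates below ~0.1/yr
this bias is well under $10^{-3}$). Cells with nobody alive are flagged
missing, not zero. State counts are conserved exactly by construction, and
the suite asserts it.

## Validation problem sizes

The shipped checks run at: 200,000 simulated individuals per sex for the
oracle comparison (≥ 99% of the 1,720 grid cells must agree within the
bound); reference integrations at step $10^{-3}$ (truth) and $10^{-4}$
(order measurement over a 30-year characteristic); and the full ten-year,
two-sex, 86-age pipeline for the aggregation round trip. These sizes make
the statistical bounds sharp enough to detect systematic solver bias above
about $2\times10^{-3}$ in prevalence.

## Design decisions that were genuinely open

* **Cause-specific mode as default:** it matches what official statistics
  publish; the conversion assumptions are stated above and testable via the
  mode-equivalence identity $p\,(m_1 - m) = \mu_c\,(1 - p)$.
* **Equation form:** the excess term enters as $p\,(m_1 - m)$ without a
  $(1-p)$ divisor; this is the form consistent with the mixing relation and
  the cohort ODE, and the equivalence is verified numerically in the suite.
* **Tie-breaking** for "age of highest prevalence" goes to the older age,
  matching the epidemiological expectation that lifetime prevalence peaks at
  the oldest ages.
* **Survivor counts stay unrounded** in tables; rounding happens only in
  printed reports, so totals are exact sums.
* **Sexes are processed independently end to end**; there is no combined-sex
  mode (combined results are sums of survivor counts, never pooled rates).

## Limitations

* **Ages 83–85 inherit the open-group boundary.** With no node above 82.5,
  the baseline profile is flat there, while true prevalence keeps rising
  with age; in the default scenario this produces errors up to a few
  percentage points in the handful of first-year cells at ages 83–85,
  decaying over the decade as those cohorts age out. Below age 83 the
  aggregation round trip recovers the truth to a few times $10^{-3}$.
  Any real analysis of this design carries the same structural uncertainty
  at the top ages — it is the reason the estimates stop at 85.
* **Linear interpolation** of grouped rates slightly over-weights convex
  stretches (exponential incidence), an inherent bias of the published-data
  format rather than of the solver.
* **No uncertainty propagation:** rates enter as point values; confidence
  intervals are out of scope.
* The cause-specific conversion ignores excess non-cause mortality among
  the diseased; where cohort studies supply $m_1$ directly, prefer
  `mortality_mode = "direct"`.
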