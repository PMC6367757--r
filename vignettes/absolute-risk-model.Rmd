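---
title: "Projecting absolute breast-cancer risk under competing mortality"
author: "bcAbsRisk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting absolute breast-cancer risk under competing mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcAbsRisk)
```

## The scientific problem

Relative risks from case-control studies tell a woman how much more
likely she is to develop breast cancer than a reference woman, but a
screening programme must act on her *absolute* risk: the probability
that she develops the disease within the next $\tau$ years, given that
she may instead die of another cause first. `bcAbsRisk` implements a
Gail-type cause-specific competing-risk model for Han Chinese women
driven by six questionnaire factors (number of abortions, age at first
live birth, benign breast disease history, BMI, breast-cancer family
history, life-satisfaction score), chosen so that no biopsy, imaging or
genetic data are required.

## Model and assumptions

**Multiplicative relative risk.** Each factor $j$ is coded into
categories $0, 1, \dots$ with category relative risks
$\mathrm{RR}_j(\cdot)$, $\mathrm{RR}_j(0) = 1$. A woman's composite
relative risk is $r = \prod_j \mathrm{RR}_j(c_j)$. This assumes no
interaction between factors on the log-risk scale and that the RRs,
estimated in a case-control design, transport to the cohort being
projected.

**Attributable-risk calibration.** Registry incidence $h_1(t)$ mixes
women at all factor levels, so the hazard of the all-reference woman is
lower. Bruzzi's estimator uses the distribution of *cases* over risk
strata, $\rho_j$, and the stratum RRs $r_j$:
$$\mathrm{AR} = 1 - \sum_j \rho_j / r_j, \qquad
  h_1^*(t) = h_1(t)\,(1 - \mathrm{AR}).$$
Only the case distribution is needed — a property that makes the
estimator usable when the population joint factor distribution is
unpublished. The AR is a property of one region's population and is
deliberately never defaulted: `regionModel()` requires it alongside the
region's own rate tables.

**Absolute risk with competing mortality.** With competing
(non-breast-cancer) mortality $h_2(t)$, the probability of breast
cancer over $[a, a+\tau)$ for composite RR $r$ is
$$P(a, \tau, r) = \int_a^{a+\tau} r\,h_1^*(t)\,
  \exp\!\Big(-\!\int_a^t \big[r\,h_1^*(u) + h_2(u)\big]\,du\Big)\,dt .$$
Deaths from other causes are *not* treated as independent censoring —
they remove the woman from risk, which is why $P$ strictly decreases
when $h_2$ rises.

## Numerical scheme

All rates are piecewise constant on twelve 5-year bands (ages 25–29
through 80–84, half-open intervals $[s, s+5)$). On each sub-interval
$k$ of length $\Delta_k$ intersecting the horizon, with total hazard
$\lambda_k = r h^*_{1k} + h_{2k}$ and accumulated survival $S_k$, the
closed-form contribution is
$$\frac{r\,h^*_{1k}}{\lambda_k}\, S_k\,\big(1 - e^{-\lambda_k \Delta_k}\big),$$
and $\lambda_k = 0$ contributes nothing. Fractional ages and horizons
simply split the first and last band at $a$ and $a+\tau$. The choice of
closed form over numerical quadrature is exact and fast; the test suite
nevertheless holds it to agreement with adaptive quadrature of the
defining integral to $10^{-10}$ across 1,000 random rate
configurations, and the telescoping identity
$P_{\text{event}} + P_{\text{competing}} + P_{\text{survive}} = 1$ is
verified to machine precision.

Probabilities are carried as proportions throughout; percent rendering
rounds half away from zero to 2 decimals only at output
(`roundHalfUp()`), so 0.028748 prints as 2.87.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| band width | years | 5 | registry rates are published in 5-year bands |
| grid range | years | [25, 85) | the model's supported age span; queries beyond 85 are rejected, not extrapolated |
| attributable risk | — | none (0.78 in the bundled region) | region-specific; must accompany the region's rates |
| risk-table grids | — | ages 25–70, durations 5–30, RR 1–25 | the published lookup layout |
| `nulliparousCode` | code | 0 | see Open design choices |
| `lossToFollowUp` | probability | 0 | administrative censoring only, unless enabled |

## Risk-table interpolation

`buildRiskTable()` evaluates the engine on an age × duration × RR grid;
`interpolateRisk()` then interpolates **along the RR axis only**,
linearly between the two bracketing grid columns. Age and duration are
never interpolated: off-grid queries on those axes are rejected and
should be routed to the exact engine, which is no slower. The bundled
reference table is ragged (no 30-year projection from age 70 on a grid
ending at 85), so such cells are `NA` and interpolation through them
errors rather than guessing. Extrapolation beyond the outermost RR
segment is off by default and logged when enabled.

## Validation metrics

*Calibration.* $E = \sum_i P(a_i, \tau_i, r_i)$ sums each woman's model
probability over her **realized** follow-up, and is compared with the
observed count $O$ via $E/O$. The 95% CI uses the log-normal Poisson
approximation $E/O \cdot \exp(\mp 1.96/\sqrt{O})$; this CI method is
this package's documented choice, since several variants circulate.
A fixed-horizon mode (`horizon =`) is available when all women should
be projected over a common window.

*Discrimination.* The concordance statistic is computed by the rank
(Mann–Whitney) identity with midranks for ties, $O(n \log n)$, with the
Hanley–McNeil standard error. The risks being ranked are projected over
a **common fixed horizon** for all women (default: the cohort's maximum
follow-up). Using realized follow-up here would truncate cases at their
diagnosis date, mechanically assigning them *smaller* predicted risks
and deflating the statistic — the one place where the calibration and
discrimination inputs deliberately differ.

*E/O wording.* The ratio is expected over observed, as the name says;
a value of 1.03 with $E > O$ indicates slight over-prediction.

## The synthetic-cohort generator

`simulateCohort()` produces cohorts with exactly the structure the
model assumes: factor codes drawn independently from marginal
prevalences (defaults: the cancer-free women of a 13,142-woman cohort,
e.g. positive family history 0.68%, BMI ≥ 28 3.14%), composite RR
multiplicative, event times piecewise-exponential with total hazard
$r h_1^* + h_2$, cause assigned with probability
$r h_1^*/(r h_1^* + h_2)$ at the event time (the standard latent
cause-specific construction), and fixed administrative censoring at 7
years. Entry ages are uniform on [25, 70), matching the validation
cohort's recruitment span and approximating its mean age of about 47.
Optional uniform loss to follow-up is off by default.

What the generator does *not* emulate: correlation between factors
(only marginals are published; a joint-table mode exists via
`simulationConfig()` with a custom scheme), secular trends in rates,
age-varying relative risks, and informative loss to follow-up. Passing
tests on simulated cohorts therefore demonstrates internal consistency
— the estimator recovers the generating model — not transportability to
real cohorts, where those violations are the interesting part.

Two closure properties anchor the suite: Bruzzi's AR applied to 50,000
sampled case profiles recovers the enumerated analytic AR (216 strata)
within ±0.02, and over 500 simulated 13,176-woman cohorts the E/O 95%
CI covers 1 at close to its nominal rate. These problem sizes keep the
full suite around half a minute while leaving Monte-Carlo error well
inside the asserted tolerances.

## Synthetic region rates

The bundled `taixing_synthetic_*` tables are plausible for a Chinese
county registry — female breast-cancer incidence rising from 3/100,000
person-years at 25–29 to about 55/100,000 at 60–64 and declining after,
non-breast-cancer female mortality rising from 40 to 7,200/100,000
across the bands — and are labelled synthetic in both filename and
documentation: they are **not** official surveillance figures. Under
these rates a simulated 13,176-woman, 7-year cohort yields on the order
of 25–30 incident cases, the same order as the validation cohort the
defaults emulate. Users with official rate tables drop them in via the
region YAML (`incidence_table`, `mortality_table`, `attributable_risk`).

The bundled *reference risk table* is the published projected-risk grid
(percent scale) and backs the interpolation workflow; because the
official registry rates behind it are distributed as a supplementary
file not reproduced here, the exact engine under the synthetic rates
will not reproduce its cells, and the package makes no attempt to
reverse-engineer them.

## Open design choices

* **Nulliparous women.** The coding rules give no age-at-first-birth
  category for women with no live birth. Default: reference code 0,
  with a message, configurable via `nulliparousCode` — conservative in
  the sense of not inflating risk on an unstated rule. Users with a
  local convention (some models treat nulliparity like a late first
  birth) can pass code 2.
* **Satisfaction score range.** Six items scored 1–5 give totals 6–30;
  the threshold ≥ 13 is applied to the raw sum.
* **BMI bands.** "24–27.9" is the half-open interval $[24, 28)$, so
  27.95 codes 1 and 28.0 codes 2, consistent with "≥ 28" for obesity.
* **E over realized follow-up.** Expected counts use each woman's own
  observed time at risk rather than a fixed horizon; for rare events
  this matches the counting-process compensator closely and keeps E/O
  centred at 1 under the generating model (verified by simulation).

## Known limitations

* No projection beyond age 85, and no lifetime-risk extrapolation.
* Relative risks are inputs: fitting the conditional logistic
  regression that produces them is out of scope.
* Time-invariant RRs; no secular-trend adjustment of rates.
* The Hanley–McNeil SE is asymptotic and can be optimistic with very
  few cases; with $O$ in the tens the C-statistic CI is wide and should
  be read accordingly.
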