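---
title: "Models and methods: DNA gut-content decay, corrected predation, and expected IGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: DNA gut-content decay, corrected predation, and expected IGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igpsim)
```

`igpsim` implements the inferential chain used in molecular gut-content
studies of aphidophagous ladybirds: how long prey DNA remains detectable
after a meal, how to compare field predation across predators that digest
at different rates, and whether field intraguild predation (IGP) matches
what laboratory bioassays predict. This vignette documents the models,
their assumptions, every tunable parameter, and the design decisions
taken where the methodology left choices open.

## 1. Detectability decay and T50

Feeding trials follow a standard design: larvae are fed a single prey
item and screened by diagnostic PCR at fixed times post feeding
(0–24 h for ladybird prey, 0–36 h for the faster-decaying aphid marker;
5–6 larvae per time point in a typical trial). `fit_decay()` fits the
binomial GLM

$$\mathrm{logit}\, P(\text{detected}) = \beta_0 + \beta_1 t,$$

with $t$ in hours and $\beta_1 < 0$ for a usable decay model. The
half-detectability time is $T_{50} = -\beta_0/\beta_1$, the solution of
$P(\text{detected}) = 1/2$; `detect_prob(model, model$t50)` returns 0.5
identically, which the test suite checks to $10^{-10}$.

Assumptions worth stating: detection is Bernoulli given time (no
overdispersion within a time point), decay is monotone on the logit
scale, and no covariates beyond time (meal size, predator body size and
temperature all matter in reality, but trials standardize them).

Numerical choices:

* **Separation.** Five-to-six larvae per point invite complete
  separation. A fit is flagged non-converged when any coefficient
  exceeds 15 on the logit scale, when all outcomes are identical, or
  when IRLS fails; flagged fits carry `NA` coefficients and refuse to
  produce probabilities rather than returning silently absurd numbers.
* **Undefined T50.** When the fitted slope is non-negative or smaller
  than $10^{-6}$ in magnitude (a flat response), `t50` is `NA` with
  `t50_defined = FALSE` instead of a meaningless ratio.
* **Extrapolated T50.** A T50 beyond the trial's last time point is
  reported with a warning; it is a model statement, not an observation.
* **T50 uncertainty.** `t50_ci()` provides a delta-method interval
  (gradient $(-1/\beta_1,\ \beta_0/\beta_1^2)$). Point estimates are the
  primary output; the interval is a diagnostic extra.

`compare_decay_lrt()` tests whether two predators share a decay curve by
comparing `detected ~ hours * predator` against `detected ~ hours`,
$\chi^2$ with **2 df**. Testing the level and the rate jointly is the
conservative reading of "detectability does not differ" as a claim about
the whole curve, rather than about either coefficient alone. The usual
use compares the two predators on the same prey; for the heterospecific
comparison each predator's prey is the *other* ladybird, so the prey
labels necessarily differ and `check_prey = FALSE` relaxes the guard.

## 2. Digestion-rate (detectability) correction

Raw detection proportions confound predation frequency with digestion
speed: a predator that clears prey DNA faster looks like a weaker
predator. `correct_proportion(p, own, ref)` computes

$$t^\* = \frac{\mathrm{logit}(p) - \beta_0^{\text{own}}}{\beta_1^{\text{own}}},
\qquad
p' = \mathrm{plogis}\!\left(\beta_0^{\text{ref}} + \beta_1^{\text{ref}}\, t^\*\right),$$

the proportion the focal species would exhibit if it digested at the
reference's rate. The map is strictly monotone in $p$, is the identity
when the models coincide, and inverts exactly ($A \to B \to A$ returns
$p$); all three properties are tested. When the focal species' observed
proportion exceeds its decay curve's intercept, $t^\*$ is negative and
the reference curve is evaluated by extrapolation — accepted, since the
correction is a curve composition, not a time measurement.

Design decisions:

* Corrected proportions are **only ranked, never re-tested**. Formal
  comparisons use the raw data through the GLMM; the correction answers
  a different question (ordering net of digestion rate) and feeding
  corrected values back into tests would double-use the decay fit.
* The **reference species is an explicit argument** of
  `rank_predators()`. In the bundled two-species scenario the
  convention is to correct *H. variegata* onto the
  *C. septempunctata* reference; `run_replication()` defaults to the
  species with the larger screened sample, which coincides with that
  convention.
* **Boundary proportions** (0 or 1, possible in small synthetic
  surveys) get a continuity adjustment, $(x + 0.5)/(n + 1)$, with a
  warning, because the logit is undefined at the boundary.
* Ties in a ranking are broken alphabetically, so rankings are
  deterministic.

## 3. Mixed-model comparison of predators

`compare_predators_glmm()` compares species on a detection flag with a
binomial GLMM: species as fixed effect, random intercept per sampling
unit, Laplace approximation (`lme4::glmer`). "Larvae nested within
sampling units" admits only this reading for a single Bernoulli response
per larva — a larva-level variance component would be unidentifiable —
so the unit intercept is the model. The generator applies the same
structure (a shared $N(0, \sigma_u^2)$ unit effect on the logit scale
for both prey kinds), making the comparison's operating characteristics
directly checkable: under equal species proportions the Wald test holds
its size, and at the bundled survey scale (proportions 0.709 vs 0.906,
151/53 larvae, 28 units, $\sigma_u = 0.5$) it has better than 50% power;
both are verified by simulation in the test suite.

The Wald p-value is the default; `test = "lrt"` refits without the
species effect and compares likelihoods. If `glmer` fails outright, the
function returns a clearly labelled fallback — fixed-effects GLM with
cluster-robust (unit-level) variance — with `converged = FALSE`, rather
than failing the whole pipeline.

## 4. The two-part observed-vs-expected simulation

The question: is field IGP compatible with the predation rates measured
in laboratory arenas? The expectation is built per larva and per
iteration from two dependent draws:

1. **Predation.** A prey stage class $c$ is drawn from
   `stage_class_weights` (immobile stages, small larvae, similarly aged
   larvae). Predation occurs with probability
   $\mathrm{plogis}(\alpha_c + \gamma_c \cdot s\, d_i)$, from the
   class's logistic lab model (`fit_stage_models()`) evaluated at the
   larva's unit aphid density $d_i$ (scaled by `density_scale` $s$).
2. **Detection.** Only if predation occurred, a feeding time
   $\tau \sim U(0, W)$ is drawn on the encounter window
   ($W = 6$ h) and detection occurs with probability
   $\mathrm{plogis}(\beta_0 + \beta_1 \tau)$ from the predator's decay
   model for the heterospecific prey.

A larva is positive iff both draws succeed; an iteration's value is the
positive count; 5000 iterations give the expected count, the empirical
central 95% interval, and the p-value of the observed count.

Open choices, and how they were fixed:

* **Feeding-time law.** The encounter is assumed to happen within the
  6 h window, but nothing says when. $U(0, W)$ is the maximum-entropy
  choice; the window length is a config parameter, so a degenerate
  "just before collection" variant is one line away.
* **Stage-class weights.** Encounters are "randomly assigned" with no
  stated weights; equal weights $(1/3, 1/3, 1/3)$ add no information
  and are configurable. A weight of zero removes the requirement of a
  lab model for that class; a positive weight without a converged model
  is an error, never a silent re-draw.
* **Per-iteration resampling.** The stage class is re-drawn for every
  larva in every iteration (fresh randomness per simulated dataset),
  the natural reading of simulating whole datasets; densities, by
  contrast, stay fixed at the unit's measured value across iterations,
  reflecting the assumption of no density change within the window.
* **Dependence.** Detection is drawn *conditionally on* predation —
  never marginally multiplied — which keeps the count variance correct.
* **Density units.** The field records aphids per 10 leaves, the lab
  arena a count per dish. `density_scale` defaults to 1 (identity).
  This is a placeholder, prominently so: with access to the original
  arena design one would calibrate the linear map; all bundled
  analyses use the identity and inherit its caveat.
* **p-value.** Two-sided with a +1 continuity correction,
  $p = \min\{1,\ 2\min(r_{\le}, r_{\ge})\}$ with
  $r_{\le} = (\#\{x \le \text{obs}\} + 1)/(B + 1)$, so $p$ is never 0
  and the extreme case at $B = 5000$ reports $2/5001 \approx 4\times
  10^{-4}$ (printed "< 0.001"). One-sided variants are available via
  `alternative`. The CI uses `stats::quantile()` (default type 7) at
  $(1 \pm \text{ci\_level})/2$.

The Monte Carlo mean is validated against an independent quadrature
oracle, $N \sum_c w_c\, p_c(d)\, \frac{1}{W}\int_0^W
\mathrm{plogis}(\beta_0+\beta_1\tau)\,d\tau$, on several small
configurations; under its own null the test rejects at 5% in well under
8% of runs and its 95% interval covers a null-generated observation at
close to nominal rate (slightly above 95%, as expected for an interval
on a discrete count).

## 5. What the synthetic generator does — and does not — emulate

`synthetic_scenario()` holds the generative parameters; the bundled
`default_scenario()` encodes the two-ladybird melon-field study regime:

* **Decay.** Four predator–prey pairs with T50s 11.40, 2.27, 14.64 and
  2.81 h. Slopes are not identified by a T50 alone; they are fixed at
  $-0.21841\,h^{-1}$ for ladybird prey (a gentle decay consistent with
  day-scale detectability) and $-0.9\,h^{-1}$ for the aphid marker
  (fast decay, near-complete loss within the trial window), with
  $\beta_0 = -\beta_1 T_{50}$.
* **Field survey.** 28 sampling units; aphid densities
  negative-binomial (mean 40 per 10 leaves, dispersion 1.5 — field
  aphid counts are strongly overdispersed, and no distribution is
  implied by the design); larvae per unit Poisson with species means
  $151/28$ and $53/28$, reproducing the unequal species totals without
  hand-assignment; instar distribution $(0.05, 0.05, 0.40, 0.50)$,
  putting 90% of mass on instars 3–4 as in the screened subsets
  (136/151 and 46/53); detection probabilities 0.709/0.906 (aphid) and
  0.252/0.283 (heterospecific); unit effect SD 0.5 on the logit scale,
  shared across prey kinds within a unit (the simplest structure
  consistent with unit-level clustering).
* **Laboratory bioassays.** Logistic predation vs arena density with a
  common slope $\gamma = -0.02$ per aphid (predation declines with
  aphid availability) and intercepts anchored so that, at the
  50-aphid grid midpoint, the stronger IG-predator
  (*C. septempunctata*) predates immobile stages and small larvae with
  probability 0.74 and similarly aged larvae with 0.22, and the weaker
  (*H. variegata*) at those values scaled by $43/70$ — the documented
  asymmetry between the two species.

All three generators are deterministic given the scenario seed (each
stage uses a fixed offset from it), and every generated table passes the
schema validators.

What is *not* emulated: meal-size and body-size effects on
detectability, temperature, satiation differences between laboratory
and field, secondary predation (a negligible source of false positives
for a fast-decaying aphid marker, but not modelled at all here),
spatial structure of aphid colonies, and temporal density dynamics.
Passing tests therefore demonstrate that the estimators recover the
truth *under the stated generative model* — internal validity — not
that field data obey that model.

## 6. Validation problem sizes

The acceptance-style checks in `tests/testthat/test-acceptance.R` run at
sizes chosen to make their statistical claims sharp while keeping the
suite fast: T50 recovery over 200 replicates at 200 larvae per time
point for each of the four regimes (median relative error < 10%); LRT
size over 1000 replicates at 30 per point; null calibration and interval
coverage of the observed-vs-expected test over 500 replicates at the
study-scale 136 larvae with 2000 iterations; its power checks at 200
replicates (halved field IGP at $N = 136$ detected; model-implied rate
at $N = 46$ not); GLMM size over 500 and power over 200 simulated
surveys; and the in-silico PCR scanner against a brute-force scan on
100 random planted-site templates.

## 7. Known limitations

* The field-to-lab density transform is an identity placeholder (see
  above); conclusions that hinge on the *level* of expected IGP should
  be read conditionally on it. The *calibration* of the test does not
  depend on the transform.
* T50s are point estimates from small trials; the delta-method CI is
  approximate and can be poor near flat slopes.
* The GLMM assumes a single shared unit variance for both species; a
  species-specific variance would not be estimable at 28 units.
* `correct_proportion()` composes two fitted curves and inherits both
  fits' sampling error; no uncertainty is propagated to the corrected
  proportions, which is one reason they are only ranked.
* The simulation conditions on the screened larvae as fixed: it models
  detection outcomes, not the sampling of larvae.
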