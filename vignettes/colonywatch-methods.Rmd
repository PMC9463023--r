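---
title: "Methods: from time-lapse image scores to breeding-success pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from time-lapse image scores to breeding-success pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonywatch)
```

## The scientific problem

Colonial seabirds such as common guillemots (*Uria aalge*) compete intensely
for breeding sites, and many birds attend their future breeding site
throughout the non-breeding season (roughly October to the end of March).
The site-defense hypothesis predicts that high-quality sites — those with a
high historic breeding success — are occupied earlier and more intensively,
and that this early investment pays off in earlier laying and higher
breeding success the following summer.

`colonywatch` implements the full analysis chain for testing these
predictions from time-lapse photography of breeding ledges: image-score
records (0, 1 or 2 birds per site per image) are reduced to three occupancy
measures, which feed general/generalized linear mixed models with AIC-based
model selection, and finally a five-pathway Bayesian structural path model
with breeding success as the endpoint. Because the field data sit in an
external repository, the package ships a synthetic colony generator with
known ground-truth coefficients; every stage is validated by parameter
recovery against that truth.

## The three occupancy measures

For each site and season, under a presence filter (any bird, exactly two
birds, or exactly one bird):

* **Return date** — the first survey day with a matching presence.
* **Occupancy frequency** — the proportion of survey days, from the return
  day to March 31, on which the site shows a matching presence.
* **Relative time investment (RTI)** — images with the site occupied divided
  by images with at least one bird anywhere in the subcolony, as a ratio of
  sums over the site's *occupied* days from its return day.

A day is a survey day only if at least one scorable image exists for the
subcolony; camera-gap days are excluded from every denominator and are
never scored as absence. This matters because frequency and RTI are
proportions — excluding unsurveyed days keeps them unbiased under sporadic
outages (a toggle to count the literal window instead is exposed as
`rti_days = "window"` / `"season"`).

The RTI day-set deserves a note. A season ratio-of-sums over *all* survey
days from return is bounded near the occupancy frequency, because a site
contributes no numerator on days it never attends while other sites keep
filling the denominator; population means like 46% of days occupied
together with 55% relative investment are only jointly coherent when the
measure conditions on the site's occupied days — RTI is a *daily duration*
measure. The default therefore uses the occupied-day set; the alternative
day-sets are options, not the primary definition.

## Standardization and mixed models

All continuous covariates are standardized within subcolony x season
(sample SD, n−1), so effect sizes are in SD units and the group mapping is
retained for back-transformation (e.g. a −4.67 days/SD quality effect with
a quality SD near 0.28 is about one day earlier per 6% of quality).

Models are fitted with lme4 by maximum likelihood throughout — including
Gaussian responses, where REML would be the usual default — because the
selection step compares models differing in fixed effects, and only ML
AICs are comparable there. Aggregated binomial responses (frequency, RTI)
carry their recorded denominators as trials; breeding success is Bernoulli.
A site random intercept enters every model; subcolony x season enters where
several subcolony-seasons are pooled.

Selection follows a two-step rule: if the AIC gap between the best and
next-best candidate exceeds 2, the lowest-AIC model wins; otherwise the
most parsimonious candidate within 2 units wins (a nested model beats the
model it nests in; residual ties break lexicographically, so selection is
deterministic). The winning fixed structure is then refitted under four
random structures (intercept, correlated intercept+slope, independent
intercept and slope, slope only) and the same rule applied. Confidence
intervals are profile likelihood by default with a recorded Wald fallback;
a term is "significant" when its interval excludes zero. Marginal and
conditional R² follow the Nakagawa decomposition with the logistic link
variance π²/3; collinearity among candidate covariates is screened with a
|r| > 0.7 cutoff; Gaussian responses are checked by a two-sided KS test
against a moment-fitted normal.

One caveat discovered while validating the KS check: a uniform sample of
n = 200 is *not* reliably rejected against its own moment-fitted normal
(its KS distance, about 0.061, sits below the n = 200 critical value), so
the test suite demonstrates the rejection property with a skewed
alternative at n = 200 and with uniform data at n = 1000.

## The Bayesian path model

Five fixed pathways, all starting at site quality and ending at breeding
success:

1. quality → success
2. quality → return date → success
3. quality → lay date → success
4. quality → occupancy frequency → lay date → success
5. quality → return date → occupancy frequency → lay date → success

Each arrow is a single-predictor regression `y = α + β x + ε_site` with a
site random intercept. Gaussian mediators use a Normal(μ, τ) likelihood
(τ a precision); the success endpoint is Bernoulli with a logit link.
Priors are minimally informative: Normal(0, precision 0.001) on α and β
and Gamma(0.001, 0.001) on precisions. (A "gamma with mean 0" is not a
distribution; the shape/rate 0.001 form is the standard minimally
informative reading and is what is implemented.) Continuous variables are
mean-centered and scaled before fitting; the binary endpoint stays 0/1 —
standardizing a Bernoulli response is not model-coherent, and this is
flagged in output metadata rather than silently done.

A pathway's coefficient is, per retained draw, the product of the
standardized edge coefficients along its chain — the classic path-analysis
composition rule. Because the composition rule is a genuinely open design
choice, the direct coefficient of the final edge is reported alongside the
product in every summary. Reported per pathway: posterior mean, 95%
credible interval, and the percentage of the posterior sharing the mean's
sign (taken literally even when the mean is near zero, where it approaches
50).

### Sampling

Gaussian edges are fully conjugate and use plain Gibbs draws. The
Bernoulli endpoint uses Metropolis-within-Gibbs: a joint random-walk on
(α, β) whose proposal covariance is seeded from the logistic ML fit and
re-estimated from the burn-in history, simultaneous univariate random-walk
updates of the site effects, and a conjugate gamma draw for the
random-effect precision. All proposal scales adapt during burn-in only
(Robbins–Monro toward standard acceptance targets), so the post-burn-in
chain is a fixed-kernel, valid MCMC.

Two extra moves are essential with ~50 observations and ~25 sites:

* a **translation move** shifting mass between the intercept and the site
  effects (likelihood-invariant; accepted on the prior ratio), which breaks
  the α-versus-random-intercept ridge; and
* a **joint scale move** rescaling the site effects and their precision
  together (`ε' = s·ε`, `τ' = τ/s²`), whose Gaussian prior terms cancel
  against the Jacobian. This is the standard remedy for the "funnel" that a
  Gamma(0.001, 0.001) precision prior produces; without it the endpoint's
  coefficients mix an order of magnitude more slowly and the effective
  sample-size bar is out of reach at the reduced schedule.

The canonical schedule is the full one — 3 chains × 200,000 iterations,
burn-in 15,000, thinning 3. Routine runs and the convergence report use a
reduced schedule (3 × 20,000, burn-in 2,000, thin 3), marked non-canonical
in outputs. Convergence is declared when every monitored variable (each
edge's α and β plus the pathway product) has a Gelman–Rubin statistic of at
most 1.05 and an autocorrelation-time-based effective sample size
(Geyer initial positive sequence, summed over chains) above 400.

## The synthetic colony generator

The generator is first-class, tested code: it is the study-design stand-in
against which every downstream stage is validated. Defaults emulate the
study system and are not tuned per analysis:

* two subcolonies of 27 and 52 monitored sites, three seasons, 15-min
  daytime scoring (30-min supported), daylight from a precomputed nautical
  dawn/dusk table at 56°N (shipped as a plain-text fixture, so there is no
  astronomy dependency);
* site quality Beta(1.4, 0.6) — a long-term success proportion with mean
  0.7 and SD ≈ 0.26, matching the ~1 day per 6% quality back-transformation;
* mean latent return day 57 (Oct 27) with 10 days residual SD plus a 3-day
  site random effect (total spread ≈ 11.7 days), quality effect −4.67
  days/SD;
* mean occupancy frequency 0.46 (quality effect +0.82 logit/SD), mean RTI
  0.55 (+0.94 logit/SD), lay date ~May 10 with −0.93 days/SD of realized
  frequency, success intercept +0.85 logit with −0.5 logit/SD of realized
  return day;
* a seasonal occupancy curve that rises logistically to a ~0.5 daily
  plateau with early-December and early-February dips, and a diel curve
  that rises log-linearly to a peak 1.5 h after dawn and decays
  exponentially to exactly zero at dusk;
* two short default camera gaps (a week-scale fog and battery outage).

Three internal calibrations make the generator's realized metrics land on
their configured targets rather than merely near them:

1. daily occupancy probabilities are the seasonal shape rescaled so each
   site's expected frequency over its own window equals its logit-scale
   target;
2. image-level presence follows `p = 1 − (1 − ρ)^w`, with `w` the
   mean-normalized diel weight — diel-shaped at small ρ yet saturating to 1
   without a hard cap, so high-investment sites are representable; ρ is
   solved per site by bisection inside a small fixed-point loop over the
   subcolony's expected any-bird image profile;
3. the bisection target discounts the expected count of "forced" images
   (an occupied day that drew no presence keeps one presence at the diel
   peak so day-level and image-level occupancy stay consistent).

Without (2) and (3) the realized quality→RTI slope attenuates by several
standard errors and parameter recovery fails; with them the generating
coefficients are recovered with approximately nominal 95% coverage.

What the generator does **not** emulate: day-to-day weather correlation in
attendance, pair-identity dynamics beyond an independent second-bird
thinning, observer mis-scoring, and any energetic mechanism behind the
seasonal dips. Passing recovery tests therefore demonstrates correctness
of the estimators under the stated generative model, not robustness to
every feature of real field data.

## Problem sizes and numerical choices

The test suite and the acceptance script choose problem sizes as the
package's own design: parameter recovery uses 100 colonies at the default
design with 30-min scoring; selection recovery uses n = 120 with a 1-SD
effect; the path model is exercised on a 50-row subcolony-1 table (the
scale at which the convergence bars are reported) under the reduced
schedule. The Laplace-vs-quadrature identity is asserted at five fixed
parameter points with random-effect SDs of 0.01-0.05, the regime in which
the first-order Laplace approximation is exact beyond the 1e-6 comparison
tolerance; its graceful degradation at larger SDs is checked separately at
a looser tolerance. Ties in AIC selection, degenerate standardization
groups (zero SD), sites never occupied in a season (dropped from models
needing a return date, with a warning count), and constant chains (ESS
undefined) are all explicit, named error or flag paths rather than silent
behavior.

## Known limitations

* The GLMM layer supports the crossed site and subcolony-season grouping
  used here, not arbitrary random-effect structures.
* Model comparison for the path model is posterior-support reporting only
  (no WAIC/LOO), matching its reporting conventions.
* The Bernoulli endpoint's sampler is tuned for the tens-of-observations
  regime of this design; for much larger data the Gaussian edges dominate
  runtime and a conjugate-only schedule would be preferable.
* Real image scoring involves identity checks of ringed birds and
  occasional re-scoring; the package starts at the scored-count level.
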