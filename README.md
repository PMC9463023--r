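# colonywatch

Non-breeding-season occupancy of seabird breeding sites, and what it buys
the birds the following summer.

In many colonial seabirds — the motivating system is the common guillemot
(*Uria aalge*) — pairs attend their future breeding site from autumn
onwards, months before laying. The **site-defense hypothesis** predicts
that high-quality sites (sites with high historic breeding success) are
occupied earlier and more intensively, and that this investment carries
through to earlier laying and higher breeding success. `colonywatch`
implements the full analysis chain for testing that prediction from
time-lapse photography, plus a synthetic colony generator with known
ground truth so the whole pipeline is testable without field data.

## What the package computes

**1. Occupancy metrics** from image-score records (one row per site ×
image with a count of 0, 1 or 2 birds): per site and season the *return
date* (first survey day occupied), *occupancy frequency* (proportion of
survey days occupied from return to March 31) and *relative time
investment* (images occupied over images with any bird present in the
subcolony, across the site's occupied days). Camera-gap days are excluded
from all denominators, never scored as absence. Presence filters: any
bird, pairs only, single birds only.

**2. Mixed models with AIC selection.** Occupancy measures and breeding
outcomes are related by general/generalized linear mixed models (lme4,
ML throughout, site and subcolony-season random terms, covariates
standardized within subcolony × season):

* association models among the occupancy measures,
* quality → occupancy (site defense), e.g. `return_day ~ quality_z × year`,
* occupancy → lay date (Gaussian) and → breeding success (Bernoulli-logit),
  with all two- and three-way interactions in the candidate set.

Selection uses the two-step rule — lowest AIC when the gap to the runner-up
exceeds 2, otherwise the most parsimonious un-nested candidate — then the
same rule across four random-effect structures. Profile (fallback Wald)
CIs, Nakagawa marginal/conditional R², KS residual-normality checks and a
|r| > 0.7 collinearity screen round out the reporting.

**3. A Bayesian path model**: five fixed pathways from site quality to
breeding success (direct; via return date; via lay date; via frequency and
lay date; via return, frequency and lay date). Each edge is a
single-predictor regression with a site random intercept; the endpoint is
Bernoulli-logit; priors are Normal(0, precision 0.001) on coefficients and
Gamma(0.001, 0.001) on precisions. Sampling is Metropolis-within-Gibbs
written in-package (conjugate Gibbs on Gaussian edges; adaptive random-walk
plus translation and funnel-scale moves on the endpoint), with
Gelman–Rubin and effective-sample-size diagnostics. A pathway's
coefficient is the per-draw product of its standardized edge coefficients
(the direct final-edge coefficient is reported alongside).

**4. A synthetic colony generator** (`simulate_colony`) emulating two
subcolonies × 27/52 sites × three seasons of 15/30-min daytime scoring:
diel attendance peaking 1.5 h after dawn and declining to zero at dusk, a
seasonal rise to a ~50% daily plateau with early-December and
early-February dips, quality effects on all three measures, and downstream
lay-date/success generation under known coefficients.

## Worked example

```r
library(colonywatch)

truth  <- simulation_truth(seed = 12)      # study-design defaults, known betas
colony <- simulate_colony(truth)
colony
#> Synthetic colony: 79 sites, 3 seasons, 2479882 image-score records

m <- compute_metrics(colony$image_scores, declared_gaps = truth$gap_spec)
round(c(mean_return = mean(m$return_day, na.rm = TRUE),
        mean_freq   = mean(m$occ_freq,  na.rm = TRUE),
        mean_rti    = mean(m$rti,       na.rm = TRUE)), 3)
#> mean_return   mean_freq    mean_rti
#>      56.312       0.479       0.542
```

Sites return in late October (season day ≈ 57 is Oct 27), are then
occupied on ~47% of survey days and spend ~54% of the subcolony's attended
time on site — the generator's configured means. Site-defense test on the
standardized data:

```r
md  <- prepare_model_data(m, colony$breeding, colony$sites)
fit <- fit_mixed(model_spec("return_day", "quality_z"), md)
fit$coefficients[2, c("estimate", "ci_lo", "ci_hi")]
#>            estimate     ci_lo     ci_hi
#> quality_z -4.903767 -6.250452 -3.557082
```

Higher-quality sites are occupied earlier (here −4.9 days per SD of
quality; the generating value is −4.67 and sits inside the interval). The
path analysis on the 50-row subcolony-1 table:

```r
pd  <- build_path_data(m, colony$breeding, colony$sites, n_rows = 50)
fit <- fit_path_analysis(pd, config = mcmc_config(profile = "fast", seed = 5))
fit$pathways[2, c("pathway", "estimate", "ci_lo", "ci_hi", "pct_same_sign")]
#>                                         pathway  estimate       ci_lo     ci_hi pct_same_sign
#> 2 Breeding success ~ site quality + return date 0.2161446 -0.07596983 0.6996641      91.73889
max(fit$diagnostics$rhat); min(fit$diagnostics$ess)
#> [1] 1.003264
#> [1] 430.0446
```

The quality→return→success pathway carries positive support (91.7% of the
posterior shares the estimate's sign), and the fit converges at the
reduced schedule (all R-hat ≤ 1.05, all effective sample sizes above 400).

`run_pipeline()` chains all stages from a single YAML config and writes
metrics, selection tables, pathway summaries, diagnostics and a run
manifest; `inst/cli/colonywatch` exposes the same stages as shell
subcommands.

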