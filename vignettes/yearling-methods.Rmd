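---
title: "Methods: yearling age structure, habitat greenness, and the hierarchical model"
author: "yearlingr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: yearling age structure, habitat greenness, and the hierarchical model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yearlingr)
```

## The scientific problem

In many landbird species a breeding adult can be aged in the hand as a
one-year-old ("yearling", banding code SY, second calendar year) or an older
adult (ASY), using plumage criteria. The fraction of adults that are
yearlings is a demographic signal: where older adults monopolize good
habitat — by despotic exclusion or simply by prior experience — yearlings
accumulate in poorer or younger habitat. `yearlingr` implements an analysis
chain that turns raw constant-effort mist-netting (MAPS-style) capture
records into that signal and relates it to a remote-sensed measure of
habitat structure, the Enhanced Vegetation Index (EVI).

The chain has five analysis stages and one synthetic-data stage, each a
separate module with its own tests:

1. **Capture curation** — records to *year-unique individuals*;
2. **Age-determination quality** — error rates from recapture histories;
3. **Yearling proportions** — species, community and pooled summaries;
4. **Habitat covariates** — EVI grid aggregation, weighted in-situ cover,
   and the EVI ~ habitat regression;
5. **Hierarchical model** — multispecies Bernoulli/logit model of yearling
   probability against EVI, with post-processing;
6. **Generator** — a forward simulator with known ground truth.

## Capture curation

The unit of analysis is the *year-unique individual*: one banded bird
counted once per calendar year, counted again if recaptured in a later
year. Rules, in order:

* Records with age codes outside {HY, SY, ASY, AHY} or unparseable dates
  are dropped at parse time and counted in a parse report.
* A band-year resolves to a determinate age (SY or ASY) if *any* capture
  that year was determinate; AHY ("adult, exact age unknown") only if none
  was. When both SY and ASY occur within one year the **latest
  determination by date wins**. Rationale: later determinations reflect
  photographic review of earlier field calls, so recency is the best
  available proxy for care. The alternative (first-wins) would freeze the
  provisional field call; majority vote is ill-defined with two captures.
* Juvenile-only (HY) band-years are excluded at *resolve* time, not parse
  time, so juvenile counts stay available for diagnostics.
* A bird captured at several stations in one year is attributed to the
  station of its first capture that year. The choice is ours — the
  underlying protocol does not specify one — and it is deterministic and
  order-independent, which the reproducibility tests require.

A species enters the community analysis when its mean number of adult
year-unique individuals per study year is at least 20 (all of SY, ASY and
AHY count toward the threshold).

## Age-determination error rates

Recaptured birds are aged independently of their earlier determinations, so
recapture histories expose aging errors. For each capture with a
determinate call that is preceded by an earlier determinate call on the
same bird, the earlier call is *propagated* (SY this year is ASY in any
later year; ASY is absorbing) and compared: the event is **eligible**, and
**changed** if the two disagree. Captures whose nearest prior determinate
call is AHY are ineligible. The per-species error rate is
changed / eligible, and the community rate is the unweighted mean over
species with at least one eligible event.

Two subtleties worth recording:

* Comparing against the *most recent* prior determinate call (not the
  first-ever call) localizes errors to single determinations instead of
  letting one early mistake contaminate a whole history.
* Under symmetric per-determination misclassification at rate $e$, two
  same-year determinations disagree with probability $2e(1-e)$ — but across
  a year boundary an error in the *first* call is absorbed by propagation
  (both SY and ASY propagate to ASY), so the across-year disagreement rate
  is $e$. The generator-based calibration checks therefore measure the
  $2e(1-e)$ law on same-year pairs.

## Yearling proportions

The yearling proportion is SY / (SY + ASY); AHY birds enter neither the
numerator nor the denominator (they are handled by the model as missing
outcomes). Two community summaries are computed and deliberately kept
apart: the **unweighted species mean** (every species counts equally) and
the **pooled ratio** (every individual counts equally, dominated by
abundant species). On the packaged 29-species table they differ — 0.407
versus 0.406 — and conflating them is a reporting error the API is designed
to prevent. Proportions are exact internally; presentation rounding is
half-away-from-zero at 3 decimals.

## Habitat covariates

**EVI.** Each station-year is covered by two June composites of 81 EVI
cells (a 9 × 9 grid of 0.25 km cells centred on the station). The
station-year covariate is the flat mean over the up-to-162 values. Missing
cells are excluded from the mean and reported through completeness fields —
never zero-filled, since 0 is a meaningful EVI value. A station-year with
no usable cells is NA and flagged. Before modelling, the covariate is
centred around zero; the mean is stored so intercepts can be mapped back to
the raw EVI scale.

**In-situ cover.** Stations hold 1–5 broad habitat types with areal
proportions and percent cover in three strata (understory 0.5–5 m,
midstory 5–15 m, upperstory > 15 m). Station-scale cover is the
proportion-weighted average per stratum; proportions must sum to 1 ± 0.01
or the input is rejected outright (a silent renormalization would hide
data-entry errors).

**EVI ~ habitat regression.** Ordinary least squares of station-year EVI on
percent natural cover and years since reclamation, over disturbed and
reclaimed stations, with un-reclaimed stations entered as zero years since
reclamation. Predictors are standardized to unit sample variance
(n − 1 denominator) so their coefficients are comparable; the response is
left in EVI units, so a coefficient reads "EVI change per one SD of
predictor". Fully standardizing the response as well would rescale the
coefficients by ~1/sd(EVI) and was rejected because it obscures the
physical units. Confidence intervals are normal-theory 95%; a condition
number above 30 on the design matrix triggers a collinearity warning;
residual quartiles and a standardized-residual-vs-normal quantile summary
are attached for fit diagnostics.

## The hierarchical yearling model

For year-unique adult $i$ of species $j[i]$ captured at station $k$ in
year $t$:

$$y_i \sim \mathrm{Bernoulli}(p_i), \qquad
  \mathrm{logit}(p_i) = \alpha_{j[i]} + \beta_{j[i]} \,\mathrm{evi}_{k,t},$$

with $y_i = 1$ for SY, $0$ for ASY, and *missing* for AHY, and species
effects partially pooled:

$$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2), \qquad
  \beta_j \sim N(\mu_\beta, \sigma_\beta^2).$$

**Hyperpriors.** $\mu_\alpha, \mu_\beta \sim N(0, 10^2)$ and
$\sigma_\alpha, \sigma_\beta \sim \mathrm{Uniform}(0, 10)$ — weakly
informative on the logit scale, configurable via `mu_prior_sd` and
`sigma_upper`. On the logit scale ±10 is far beyond any observable age
ratio, so these priors are effectively flat where the likelihood lives.

**Missing outcomes.** AHY individuals contribute nothing to the
likelihood; under missingness-at-random this is equivalent to integrating
out their latent ages. The paired-run invariance test verifies the
implementation really has this property: with a shared seed, fits with and
without the AHY rows produce identical draws. An optional post-hoc
imputation (`impute_unknown_ages()`) draws latent ages from the fitted
curves for reporting only.

**Sampler.** An adaptive Metropolis-within-Gibbs scheme written in C++:

* each $\alpha_j$ and $\beta_j$ gets a random-walk Metropolis update with
  Robbins–Monro scale adaptation during warmup (target acceptance 0.44,
  the one-dimensional optimum);
* $\mu_\alpha, \mu_\beta$ are conjugate normal Gibbs draws;
* $\sigma_\alpha^2, \sigma_\beta^2$ are inverse-gamma Gibbs draws truncated
  at `sigma_upper`² (for a single-species fit, where the Gibbs shape
  parameter degenerates, a Metropolis step on $\sigma$ substitutes);
* two **block moves** per iteration break the posterior correlation
  between species effects and their hyperparameters, which is what limits
  mixing in the centred parameterization: a *translation* move shifts a
  whole effect block together with its mean, and a *rescale* move contracts
  or dilates the deviations together with their SD (Metropolis-accepted
  with the appropriate Jacobian). Without these moves the effective sample
  size of $\sigma_\beta$ is an order of magnitude smaller.

Defaults: 3 chains × (2 000 warmup + 2 000 sampling), per-chain seeds
`seed + chain − 1`. Convergence is summarized per parameter with split
$\hat R$ (via `coda::gelman.diag`) and effective sample size; the fit warns
loudly when any monitored parameter has $\hat R > 1.1$ or ESS < 400.
Species observed with a single outcome class are permitted — partial
pooling keeps them identified — but flagged. Reproducibility is exact: the
sampler uses R's RNG, so a seed fixes every draw.

**Validation strategy.** The sampler is never trusted on its own: the log
unnormalized posterior has an independently coded scalar-sum oracle
(agreement to 1e−10); the single-species posterior mode is checked against
an exhaustive grid search; the large-n single-species posterior is checked
against the flat-prior MLE located by grid search; and the full
hierarchical posterior is compared against an independent JAGS fit of the
same model on shared data (posterior means within combined posterior SDs).

**Post-processing.** Species are profiled by the capture-weighted mean and
range of station-year EVI over their adult captures, then grouped by
sample quartiles of the species means (linear-interpolation quantiles;
boundary species go to the lower group): lowest quartile = successional,
middle two = intermediate, top = mature forest. Group summaries average
$\beta_j$ within group *per posterior draw*, so group credible intervals
carry the joint posterior uncertainty. The meta-regression of
posterior-mean $\beta_j$ on species EVI mean and range uses the same
standardized-predictor OLS conventions as the habitat regression;
propagating posterior uncertainty of $\beta_j$ into that regression is
deliberately out of scope (point responses are used). Profiles use adult
captures only.

## The synthetic-data generator

The generator runs the inferential model forward so that every stage can
be scored against known truth, with an observation layer mirroring field
realities:

* **Stations**: 15 natural (91–98% natural cover), 15 disturbed (50–88%),
  5 reclaimed, over 6 years — the scale of the motivating study. Reclaimed
  EVI rises linearly with reclamation age and reaches the natural mean
  exactly at `evi_parity_years` (default 20); disturbed stations scale
  with percent natural cover; all get two June composites of 81 cells per
  year with configurable station, year and cell noise. A linear ramp was
  chosen over an asymptotic curve so that "parity at year 20" is exact,
  which the saturation test asserts without tolerance.
* **Community**: J = 29 species with $(\alpha_j, \beta_j)$ drawn from the
  hyperparameters ($\mu_\alpha = -0.38$, i.e. a community mean yearling
  proportion near 0.41; $\sigma_\alpha = 0.5$, spanning roughly the
  0.18–0.61 spread seen across real species; $\mu_\beta = -1.29$,
  $\sigma_\beta = 1$). Species abundance is lognormal
  (`capture_rate_sd = 0.6`) with a log-linear tilt of the Poisson capture
  rate in centred EVI (`abundance_tilt_sd = 5`), which gives species
  realistic habitat associations so the quartile grouping has structure.
  `mean_captures = 1.75` new adults per species-station-year makes the
  default scenario realize ≈ 13 000 adult bird-years.
* **Observation process**: each bird-year is masked to AHY with
  probability 0.118 (independent of true age, i.e. missing at random, the
  model's own assumption; masking overrides every determination that
  year); each unmasked determination independently flips SY↔ASY with
  probability `misclass_rate = 0.042`, so the *measured* same-year
  disagreement rate is $2e(1-e) \approx 0.08$, matching the error level of
  trained banders; extra same-year captures arrive at Poisson rate 0.36
  and birds return the next year with probability 0.08 (≈ the ratio of
  year-unique captures to distinct individuals in real MAPS data).
  Returning birds are truly ASY in later years.
* **Juveniles**: HY captures at 0.3 × the adult rate exercise the
  HY-exclusion path.

What the generator does *not* emulate: net-level capture effort, weather,
within-season timing, movement between stations, direction-biased aging
errors, and density dependence. Passing recovery tests therefore shows the
estimator is correct *under its own assumptions plus a realistic
observation layer* — not that those assumptions hold in any particular
field dataset.

Two properties of the generator matter for interpreting recovery results.
First, misclassification attenuates logistic slopes (a flip rate $e$
shrinks them by roughly $(1-2e)$ near $p = 0.5$). Second, forced-ASY
returning birds dilute the EVI signal slightly. Both are features of real
data, so the recovery target $\mu_\beta = -1.29$ sits near the edge of
what the observed data identify; in a 20-replicate study at the default
scenario the 95% credible interval covered the true $\mu_\beta$ in 19 of
20 replicates, with posterior means averaging about −1.17.

## Problem sizes and run times

Chosen as the package's own trade-off between Monte-Carlo error and
convenience: full fits use the 3 × (2 000 + 2 000) default on ≈ 13 000
individuals (tens of seconds); the 20-replicate coverage study uses
2 chains × (1 500 + 1 500) per replicate, which is ample for a 95%
interval endpoint check; oracle and invariance checks use single chains or
toy datasets. The observation-process calibration uses a denser capture
configuration so that a single simulated study yields ≥ 5 000 same-year
eligible recapture pairs.

## Numerical choices and degenerate inputs

* Bernoulli log-likelihoods use `log1p(exp(·))` with linear/zero tails
  beyond ±35 to avoid overflow.
* Non-finite parameters or out-of-support SDs give a log posterior of
  −∞, never an error, so Metropolis proposals reject cleanly.
* Presentation rounding is half-away-from-zero; all internal arithmetic is
  exact ratios.
* Zero denominators (no determinate adults, no eligible recaptures, no
  usable EVI cells) yield flagged NA values, not silent zeros; empty
  habitat groups and all-undefined communities are hard errors or warnings
  as the aggregation requires.
* The quartile rule assigns boundary species to the lower group, making
  group membership stable under permutation of species order.
* Generator determinism is byte-exact for a fixed seed and config.

## Known limitations

* Yearling proportions are reported raw; misclassification-corrected
  proportions are out of scope (the motivating analyses report raw values
  too), so community comparisons inherit the ~8% determination error.
* The model has no year random effects and no spatial correlation between
  stations, by design.
* EVI saturates once upperstory canopy closes, so the habitat covariate is
  informative mainly over the first ~20–30 years of vegetation
  development; the in-situ cover metrics partially cover the gap.
* The meta-regression treats posterior means of $\beta_j$ as known
  responses; its CIs understate total uncertainty.
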