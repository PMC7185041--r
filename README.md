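# yearlingr

Age structure of breeding landbird communities from constant-effort banding
data: what fraction of the adults at a station are one-year-old birds
("yearlings"), and how does that fraction track habitat structure?

In species where yearlings (banding code SY, second calendar year) can be
told from older adults (ASY) in the hand, the **yearling proportion**
SY / (SY + ASY) is a demographic index of habitat quality: older adults
tend to exclude yearlings from preferred habitat, so poorer or younger
habitat accumulates yearlings. `yearlingr` provides the full analysis chain
for MAPS-style mist-netting data:

* **Capture curation** — validated capture records are collapsed to
  *year-unique individuals* (one bird per calendar year), with determinate
  ages (SY/ASY) taking precedence over indeterminate ones (AHY) and
  juvenile (HY) records excluded from adult analyses.
* **Aging quality** — recaptured birds are aged independently each time, so
  recapture histories expose errors: after propagating the previous
  determinate call forward (SY this year is ASY next year), any
  disagreement counts as a changed determination.
* **Yearling proportions** — per species, as the unweighted community mean,
  and as the pooled ratio (kept strictly apart; they differ).
* **Habitat covariates** — 81-cell Enhanced Vegetation Index (EVI) grids
  averaged over two June composites per station-year;
  proportion-weighted in-situ cover by stratum; OLS of EVI on percent
  natural cover and years since reclamation with standardized predictors.
* **Hierarchical model** — the probability that a captured adult is a
  yearling is modelled as

  logit(p_i) = α_j[i] + β_j[i] · evi_k,t,   α_j ~ N(μ_α, σ_α²),  β_j ~ N(μ_β, σ_β²),

  a multispecies Bernoulli/logit model with species random intercepts and
  slopes, fitted by an adaptive Metropolis-within-Gibbs sampler (Rcpp) with
  block moves for the hyperparameters; adults of unknown exact age (AHY)
  enter as missing outcomes. Post-processing groups species into
  successional / intermediate / mature-forest habitat classes by quartiles
  of their capture-weighted EVI means, summarizes the EVI coefficient per
  group, and meta-regresses species coefficients on their EVI mean and
  range.
* **Synthetic data** — a generator with known ground truth (species
  effects, true ages, masking and misclassification indicators, true EVI
  trajectories) runs the model forward under a realistic observation
  process, so every stage is testable end to end without any download.

A 29-species community summary table from a six-year, 35-station boreal
forest study is packaged (`community_table()`, `study_totals()`) and drives
the exact-value tests.

## Worked example

Community statistics from the packaged table:

```r
library(yearlingr)
t1 <- community_table()
p  <- yearling_proportion(t1$n_SY, t1$n_ASY)
round_half_up(community_mean_proportion(p), 3)                     # 0.407
round_half_up(pooled_yearling_proportion(t1$n_SY, t1$n_ASY), 3)    # 0.406
round_half_up(range(p), 3)                                         # 0.178 0.613
round_half_up(100 * percent_aged(sum(t1$n_SY), sum(t1$n_ASY),
                                 sum(t1$n_AHY)), 1)                # 88.2
```

The community mean yearling proportion is 0.407 (species weighted equally),
the pooled ratio 0.406; species range from 0.178 to 0.613; 88.2% of adults
were aged to an exact class.

A full synthetic study, curated and fitted (about a minute):

```r
sim  <- simulate_study(sim_config(), seed = 1)   # paper-like default scenario
inds <- resolve_year_unique(sim$captures)
sev  <- station_year_evi(sim$evi$cells)
tgt  <- filter_target_species(inds, n_years = 6)
md   <- build_model_data(inds, sev, species = tgt)
fit  <- fit_yearling_model(md, seed = 1)
fit
#> Hierarchical yearling model fit: 28 species, 10642 observed + 1418 unknown-age individuals
#> 3 chains x 2000 iterations (+2000 warmup), converged: TRUE
#>    parameter   mean     sd    q2.5  q97.5 rhat  ess
#>     mu_alpha -0.388 0.1075 -0.5949 -0.180    1 4997
#>      mu_beta -1.129 0.3126 -1.7277 -0.500    1 1180
#>  sigma_alpha  0.545 0.0878  0.4008  0.743    1 3155
#>   sigma_beta  0.430 0.3326  0.0214  1.230    1  522
```

The community EVI effect `mu_beta` is estimated at −1.13 with 95% credible
interval (−1.73, −0.50): the generating value −1.29 is recovered (negative
effect: the yearling share falls as habitat greenness rises). `sim$truth`
carries the ground truth for scoring. Post-processing:

```r
pr <- species_evi_profiles(inds, sev, tgt)
group_coefficient_summary(fit, pr)    # mean beta per habitat group + 95% CrI
coefficient_meta_regression(fit, pr)  # beta_j ~ z(EVI mean) + z(EVI range)
```

A whole run (curation → error rates → covariates → fit → post-processing →
report files + manifest) is one call, or one shell command via the thin
wrapper:

```r
run_pipeline(preset = "paper_like", out_dir = "out", seed = 1)
```

```sh
Rscript inst/scripts/yearlingr-cli.R run-all --preset paper_like --seed 1 --out out
```

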