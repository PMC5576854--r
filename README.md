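# temporaldiv

Partitioning the within-season (temporal) diversity of repeatedly sampled
assemblages — built for bee surveys comparing habitat-fragment plots with
reserve plots, and applicable to any two-treatment design with long-format
count data.

Seasonal assemblages can lose diversity in different ways that pooled
("site-level") analyses cannot distinguish: a site may become poorer at
every point in the season, or its species may stop turning over through
the season, or both.  `temporaldiv` measures the three components
separately and tests treatment differences in each:

* **temporal gamma** — per-plot diversity pooled over all sampling dates:
  rarefied species richness and Pielou evenness (individual-based
  rarefaction to the year's minimum pooled plot abundance, with the
  analytic Hurlbert expectation
  `E[S] = sum_i [1 - C(N - N_i, d)/C(N, d)]` as internal oracle),
  logit-transformed generalist proportion, and cube-root-transformed
  abundance, compared by Welch's *t*-tests;
* **temporal alpha** — the same responses per sampling date (rarefied to
  20 individuals), modelled as
  `response ~ treatment * poly(julian_date, q)` with a plot random
  intercept; the degree `q` in 1–3 is selected by ML-AIC with a
  "ΔAIC < 2 → lowest degree" rule and between-within F tests are
  reported from the REML refit;
* **temporal beta** — Bray-Curtis dissimilarities among all samples,
  NMDS ordination (Kruskal stress-1, PCoA start plus random restarts),
  and per-plot multivariate dispersion: the mean distance between each
  plot's centroid and its samples, compared by Welch's *t*-test.

A seasonal community simulator (`simulateSurvey()`, with scenario
presets) generates surveys with known injected treatment effects —
species-pool deficits, dominance skews, activity-window widening
(turnover loss), phenology shifts, generalist boosts — so that every
stage of the pipeline is testable against ground truth.

## Worked example

```r
library(temporaldiv)

# simulate the 4 + 4 plot x 9 sample design with the "both components
# reduced" disturbance scenario, then analyse it
cfg <- scenarioPreset("scenario3", seed = 42)
sim <- simulateSurvey(cfg, year = 2011)
rep <- runAnalysis(sim$records, sim$traits, seed = 1)

rep$year2011$gamma$tests[, c("response", "t", "df", "p")]
#>                response            t       df            p
#> 1     rarefied_richness  9.823098005 3.945089 0.0006446562
#> 2        evenness_logit  2.600275665 5.919639 0.0411533725
#> 3 generalist_prop_logit -0.208590924 4.676826 0.8435449094
#> 4 abundance_transformed  0.006284175 5.985504 0.9951901962

rep$year2011$beta$test[, c("t", "df", "p")]
#>          t       df           p
#> 1 5.371691 3.885069 0.006299104

dispersionTable(rep$year2011$beta$dispersion)$dispersion
#> [1] 0.6952675 0.6087777 0.6603287 0.5766316 1.1881625 0.9261215
#> [7] 0.9033648 1.0904778
```

Fragment plots (first four dispersion scores) show significantly lower
rarefied richness and evenness, no abundance difference, and roughly 60%
of the seasonal turnover of reserve plots (last four scores) — the
injected "scenario 3" signature.  The mild generalist boost in this
preset is not detectable in a single 4 + 4 plot realisation (p = 0.84
here); power for that effect emerges only across replicates.
`rep$year2011$alpha$terms` holds the per-response mixed-model F tables
(e.g. treatment tested on the plot stratum with `F(1, 6)` denominator
df in this design).

The deficit estimator inverts detection inflation to recover the
injected 36% pool loss from the gamma output, where the naive
richness ratio understates it:

```r
fr <- filterRecords(sim$records, traits = sim$traits)
am <- abundanceMatrix(fr, sim$traits)
estimateRichnessDeficit(am, rep$year2011$gamma$table)
#> $deficit        [1] 0.3975798
#> $naive_deficit  [1] 0.2934579
#> $depth          [1] 379
```

A thin command-line wrapper lives at
`inst/scripts/temporaldiv-cli.R` (`simulate` and `analyze`
subcommands).

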