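# scavsurv

Survival and carcass-use analysis for camera-trap scavenging experiments.

## The science

When a dominant carnivore declines or disappears, the carrion it used to
monopolise becomes available to the rest of the scavenger community —
including invasive species. Field studies of this question deploy animal
carcasses at monitored sites across regions that differ in the dominant
carnivore's status (intact, disease-reduced, absent), watch them with
camera traps, and ask:

* how fast are carcasses **discovered**, and by whom?
* how long do carcasses **persist** before being fully consumed?
* which species **use** carcasses, for how long, and how does that shift
  when the dominant carnivore is missing?

`scavsurv` implements that full analysis chain for Tasmanian-style
devil/quoll/raven/feral-cat communities, plus a synthetic-study generator
with known ground truth so every estimator can be validated end to end.

## What the package does

| Stage | Functions |
| --- | --- |
| Ingest + event reconstruction | `read_detections()`, `read_deployments()`, `read_site_covariates()`, `build_foraging_events()` (4-minute gap rule) |
| Survival records | `discovery_records()`, `persistence_records()`, `use_records()`, `region_summary()` |
| Mixed-effects Cox | `fit_cox()` (penalized partial likelihood, Gaussian site intercept, Laplace-profiled variance), `hazard_ratios()`, `km_estimate()`, `median_persistence_ratio()` |
| Model selection | `score_model()` (LOOCV log partial likelihood), `select_model()` (modified one-SE rule), `candidate_cox_specs()`, `compare_full_model()` |
| Carcass use | `fit_glmm()`, `fit_hurdle()` (binomial use + Gamma duration), `auc()`, `effect_size()`, `score_glmm()` |
| Bootstrap summaries | `site_means()`, `bootstrap_ci()`, `regional_bootstrap()` |
| Simulation | `sim_config()`, `generate_study()`, `render_photo_stream()`, `paperlike_scenario()`, `write_study_csv()` |
| Pipelines | `run_analysis()`, `run_recovery_study()`, `dryad_reproduction()` |

The Cox fit is written in-package (no `coxme` dependency): joint Newton
iterations over fixed effects and site intercepts under a ridge penalty
`b'b / 2σ²`, with σ² profiled on a Laplace-approximate marginal likelihood,
Efron or Breslow ties, and a suffix-sum engine that matches
`survival::coxph()` to near machine precision. Model selection uses the
cross-validated log partial likelihood of Verweij & van Houwelingen, an
optimism-based effective-parameter count `p_eff = within − cv`, and a
paired one-standard-error rule. See `vignettes/methods.Rmd` for the
mathematics and design rationale.

## Worked example

Simulate a small two-region world (devils present vs absent), reconstruct
events, and run the persistence analysis:

```r
library(scavsurv)

config <- sim_config(
  regions = list(
    list(name = "full",   n_sites = 4L, devil_activity_range = c(8, 16),
         quoll_activity_range = c(0, 4)),
    list(name = "simple", n_sites = 4L, devil_activity_range = c(0, 0),
         quoll_activity_range = c(0, 0))),
  carcasses_per_site = c(8L, 10L),
  persistence = list(baseline = 0.02,
                     beta = c(devil_activity = log(1.2),
                              quoll_activity = log(1.2),
                              habitat_wet = -0.2, weight_kg = -0.02)),
  seed = 42)
study <- generate_study(config)          # 71 carcasses, ~12,000 photos

events <- build_foraging_events(study$detections)
region_summary(events, study$deployments)
#>   region species n_foraged pct_foraged hours_foraging prop_total_time
#> 1   full     cat         3    8.333333       1.683333      0.01037707
#> 2   full   devil        35   97.222222      98.133333      0.60495222
#> 3   full   quoll        14   38.888889      27.983333      0.17250591
#> 4   full   raven        12   33.333333      34.416667      0.21216480
#> 5 simple     cat        16   45.714286      16.716667      0.03950530
#> 6 simple   raven        31   88.571429     406.433333      0.96049470
```

Devils dominate carrion where present; ravens and cats take over where they
are absent. Now the mixed-effects Cox fit (true devil hazard ratio: 1.2):

```r
rec <- persistence_records(study$deployments, study$covariates)
fit <- fit_cox(cox_spec("persistence", c("devil_activity", "weight_kg")), rec)
hazard_ratios(fit)
#>             term        beta         se        hr    ci_low  ci_high
#> 1 devil_activity  0.18859178 0.02985204 1.2075479 1.1389227 1.280308
#> 2      weight_kg -0.05204206 0.08782891 0.9492889 0.7991684 1.127609
```

LOOCV model selection over a small candidate ladder:

```r
scores <- lapply(candidate_cox_specs("persistence",
                   families = list(character(0), "devil_activity",
                                   c("devil_activity", "quoll_activity"))),
                 score_model, records = rec)
select_model(scores)
#> Model selection (LOOCV log likelihood, modified one-SE rule)
#>                                                       model_id n_terms
#> 1 persistence:devil_activity+quoll_activity+weight_kg+re(site)       3
#> 2                persistence:devil_activity+weight_kg+re(site)       2
#> 3                               persistence:weight_kg+re(site)       1
#>   cv_loglik p_eff delta se_delta in_candidate_set selected
#> 1    -186.6 3.298 0.000    0.000             TRUE    FALSE
#> 2    -188.3 2.833 1.744    1.796             TRUE     TRUE
#> 3    -191.4 7.991 4.837    1.076            FALSE    FALSE
#> selected: persistence:devil_activity+weight_kg+re(site)
```

The devil-only model trails the best score by less than one SE and has
fewer effective parameters, so the one-SE rule picks it; the no-activity
model is far outside the band. Regional persistence and a bootstrap
use summary:

```r
km <- km_estimate(rec, group = "region")
median_persistence_ratio(km)
#>   numerator denominator     ratio is_bound defined
#> 1      full      simple 0.1374322    FALSE    TRUE
#> 2    simple        full 7.2763136     TRUE    TRUE

ur <- use_records(events, study$deployments, study$covariates, "raven")
regional_bootstrap(site_means(ur, "prop_used"), "raven prop used",
                   n_resamples = 10000, seed = 42)
#>   region       statistic     point    ci_low ci_high n_sites n_resamples seed
#> 1   full raven prop used 0.3187500 0.1000000 0.46875       4       10000   42
#> 2 simple raven prop used 0.8909722 0.8222222 0.96875       4       10000   42
```

Carcasses last at least ~7× longer (median) where devils are absent, and
raven use jumps from ~32% to ~89% of carcasses — the qualitative signature
the package is built to quantify.

One call runs everything (ingest → events → four survival analyses with
selection → use GLMMs → bootstrap), writing a CSV/JSON report bundle:

```r
res <- run_analysis(config, out_dir = "results", seed = 7L)
```

## Verification

* `tests/testthat/` — oracle-first suite: naive reimplementations of the
  gap rule, partial likelihood, IRLS, Mann–Whitney AUC, product-limit
  estimator and double-loop LOOCV, checked against the fast engines;
  closed-form likelihood cases; simulation recovery; end-to-end pipeline
  determinism. `tests/testthat/test-acceptance.R` holds the headline
  criteria.
* `scripts/acceptance.R` — standalone run against the installed package:
  `Rscript scripts/acceptance.R --seed 1 --out acceptance.json`.

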