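# broodr

Reproductive phenology of brooding intertidal invertebrates, estimated from
embryo-stage survey counts and intertidal temperature time series.

Populations of brooding species such as the acorn barnacle *Semibalanus
balanoides* fertilize in fall, hold embryos in the mantle cavity over
winter, and release larvae weeks to months later. Because embryonic
development accelerates exponentially with temperature, the shore's thermal
history controls how long brooding lasts and, therefore, when larvae enter
the water column. `broodr` is for ecologists who have (a) repeated surveys
scoring adults for embryonic stage and (b) hourly-scale intertidal
temperature series, and who want population-level estimates of the
fertilization midpoint (**F50**), the larval-release midpoint (**LR50**),
brooding duration, and the temperature relationships that explain them.

## The method

For each site and season, the fraction of adults carrying fertilized
embryos (ordinal scores 2–5 of the 0–5 embryo scale) is scaled by its
seasonal maximum, split at the midpoint of the dates where the scaled
proportion exceeds 95%, and each limb is fit with a quasi-binomial logistic
regression

&nbsp;&nbsp;&nbsp;&nbsp;logit *p* = β₀ + β₁ · *t*,

inverted at 50% to give F50 (rising limb) and LR50 (falling limb);
brooding duration is LR50 − F50 days. Temperature series are regularized
to an hourly grid, low-pass filtered with the oceanographic **PL64** filter
(129 symmetric taps, half-amplitude at a 33-h period) to remove tidal and
diurnal variability, and summarized over fixed fall windows (early fall
Sep 22–Nov 20; fall Sep 22–Dec 22, both closed intervals). Two linear
models carry the inference:

1. **F50 anomaly ~ fall temperature anomaly** (site-centered, pooled;
   seasons with subzero filtered early-fall temperatures excluded) — days
   of fertilization delay per °C of fall warming;
2. **ln(duration) ~ mean filtered temperature between F50 and LR50** — the
   exponential temperature dependence of embryonic development,
   *D*(*T*) = exp(*a* + *b·T*).

A seeded synthetic-study generator (`sim_study()`) produces temperature
series (seasonal + diel + 12.42-h tidal cycles with AR(1) noise),
per-adult fertilization and temperature-driven development via the
integral ∫ d*t*/*D*(*T*(*t*)) ≥ 1, and periodic multinomial surveys — with
exported ground truth, so every stage of the pipeline is testable by
parameter recovery.

## Worked example

```r
library(broodr)

study <- sim_study(sim_config(), seed = 42)   # 4 sites x 3 seasons
res <- run_study(study$surveys, study$temperatures)
res
#> <brood_study_results: 12 site-season(s)>
#>   F50 anomaly slope: -0.44 d/degC (n = 12, 0 excluded)
#>   duration-law slope: -0.128 per degC (R2 = 0.97)

glance(res$duration_model)
#>    slope intercept ci_low ci_high r.squared statistic df df.residual  p.value
#> 1 -0.128      5.06 -0.145  -0.112     0.967       295  1          10 9.49e-09
```

The duration-law slope −0.128 per °C (generating truth −0.14) says each
degree of warming shortens brooding by ~12%; R² = 0.97 because latitude
separates the sites' thermal regimes cleanly. The F50-anomaly model on a
single 12-season study is intentionally honest about its noise (here
−0.44 d/°C, p = 0.86, against a generating response of +3.7 d/°C): with
±1 °C fall anomalies and ~1–2 d of midpoint noise, n = 12 carries little
power, which is why the anomaly analysis pools as many site-seasons as
possible. Averaged over 200 replicate studies the recovered response is
~3.4 d/°C.

Per-season estimates, calendar-date reports and plots:

```r
res$phenology[, c("site", "season", "f50", "lr50", "duration_days")]
cat(report_study(res), sep = "\n")   # markdown tables, F50/LR50 as dates
autoplot(res$phenology)              # scaled series + fitted limbs
autoplot(res$duration_model)         # ln-duration vs brooding temperature
```

On-disk workflows mirror the in-memory one: `read_survey_table()` /
`read_temperature_csv()` read the CSV layouts documented in those help
pages, and `run_study_dir()` processes a study directory and writes result
CSVs, regression JSON, a markdown report and a run manifest.

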