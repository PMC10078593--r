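# nestdsm

Density surface modeling (DSM) for great-ape nest counts from line-transect
distance sampling, aimed at estimating how many weaned individuals a
landscape holds, where they are, and how fast the population and its
habitat are changing.

Ape surveys in savanna--woodland mosaics rarely see the animals; they count
sleeping nests along transects. Three models take a nest tally to a density
map with honest uncertainty:

1. **Detection** — the probability of spotting a nest falls with its
   perpendicular distance `x` from the line. A detection function `g(x)`
   (half-normal, hazard-rate or uniform key, cosine adjustments, vegetation
   type as a scale covariate on a log link) is fitted to the distances by
   maximum conditional likelihood; its average
   `p = (1/w) ∫₀ʷ g(x) dx` converts strip counts to strip contents, with
   Cramér–von Mises / Kolmogorov–Smirnov goodness of fit and AIC selection.
2. **Spatial counts** — transects are cut into ~0.4 km segments and segment
   counts `n_it` are modeled as

   `log E[n_it] = f(temp range) + f(dist slopes) + f(elevation) +
   f(dist forests) + f(vegetation) + f(year) + f(x, y) + te(x, year) +
   te(y, year) + te(x, y, year) + β·log(pop. density) + log(2 w l p̂)`

   a negative binomial or Tweedie GAM (penalized thin-plate and
   tensor-product smooths, REML) whose offset — the log *effective area*
   `2 w l p̂` — carries detectability into the surface.
3. **Standing-crop conversion** — nests outlive the night they were built,
   so `D_individuals = D_nests / (t · r)` with `t` the nest production rate
   (nests/individual/day) and `r` the mean nest lifetime (days), stratified
   by region × vegetation.

Predictions on a 1×1 km grid give density and SD maps; stratum abundances
carry delta-method uncertainty (`CV² = CV²_detection + CV²_GAM`) with
lognormal confidence intervals; annual population and habitat trends are
log-linear rates. A synthetic landscape-and-survey generator (clustered
nest fields over a three-class vegetation mosaic, vegetation-dependent
detectability, a known multiplicative annual decline) provides ground truth
for every stage, and the test suite is built on recovering it.

## Worked example

Simulate a 900 km² landscape, run seven annual nest surveys against a truth
declining at 2.4%/yr, and recover densities and the trend:

```r
library(nestdsm)

land <- generate_landscape(nx = 30, ny = 30, cellsize = 1000, seed = 7)
land
#> <nest_landscape> 30 x 30 cells of 1000 m (900 km^2)
#>   vegetation: forest 6%, woodland 71%, nonforest 23%

truth <- truth_params(years = 2012:2018)   # -2.4 %/yr decline built in
res <- run_dsm_pipeline(truth = truth, landscape = land,
                        site_pool = 12, sites_per_year = 12,
                        forest_sites = 3, seed = 7)

res$detection
#> <detection_model> key = hn, 0 cosine adj., scale ~ vegetation
#>   n = 1087, w = 50 m, logLik = -3949.44, AIC = 7904.89
#>   average p = 0.476 (CV = 0.024)
#>   sigma (m): forest 17.4, nonforest 23.0, woodland 19.4

res$model
#> <dsm_model> family = nb, n = 1680 segments
#>   AIC = 3483.46, deviance explained = 18.5%, theta = 3.004

subset(res$abundance, year == 2018 & stratum != "all")[,
  c("stratum", "density", "abundance", "lower", "upper")]
#>      stratum density abundance lower upper
#> 25    forest  0.5398      29.1 19.89  42.7
#> 26  woodland  0.1405      89.8 66.37 121.4
#> 27 nonforest  0.0867      18.0  7.46  43.2

res$trends$all
#> <trend_estimate> -2.85% / yr (loglinear), -15.92% over 6 yr
#>   CI: -8.72% to +3.40% / yr
```

Reading the output: detection is hardest in forest (σ = 17.4 m) and easiest
in the open (23.0 m), averaging p̂ = 0.476 within the 50 m strip — about
half the nests present are seen, and every downstream count is corrected
for it. Forest holds ~4× the woodland density (0.54 vs 0.14
individuals/km², truth 0.78 / 0.17 in 2018), woodland holds the most
animals by area, and the recovered trend (−2.85%/yr, CI −8.7 to +3.4)
brackets the true −2.4: a single 7-year survey series bounds but does not
pin down a slow decline, which is exactly why the validation suite judges
trend recovery by the median over 25 replicates.

Lower-level entry points: `fit_detection()` / `select_detection_model()`
(Stage 1), `split_transects()` / `build_segment_table()` / `vif_screen()`
(survey prep), `fit_dsm()` / `cross_validate()` (Stage 2),
`predict_surface()` / `nests_to_individuals()` / `stratum_abundance()` /
`annual_trend()` / `habitat_trend()` / `cap_area_summary()` (prediction and
trends). The methods vignette (`vignettes/nest-density-surfaces.Rmd`)
documents the model, its numerical choices, and what the synthetic
generator does and does not emulate.

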