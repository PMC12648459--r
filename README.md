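# befstress

Freshwater communities rarely face one stressor at a time: warming,
nutrient enrichment, drought and contaminants arrive together, and each can
erode both biodiversity and the ecosystem functions that depend on it
(decomposition, primary production, biomass).  `befstress` is an R package
for meta-analysing factorial multi-stressor experiments to answer two
questions:

1. **Does the biodiversity–ecosystem-function (BEF) relationship steepen as
   stressors accumulate?**  The package fits a nested linear mixed-effects
   model of the function effect size on the diversity effect size,

   `LRR_EF ~ LRR_TR + NS/SC + EF/TG + LRR_TR×NS + LRR_TR×EF + LRR_TR×NS/SC
   + LRR_TR×EF/TG + (1 | study)`,

   where `LRR` is the (small-sample bias-corrected) log response ratio,
   `NS` the number of stressors, `SC` the stressor combination nested in
   `NS`, `EF` the ecosystem-function type and `TG` the organism group
   nested in `EF`.  A positive `LRR_TR × NS` interaction means the cost of
   taxon loss for function grows with each added stressor.

2. **Are joint stressor effects predictable from single-stressor effects?**
   Because effects are log ratios, additivity implies a multiplicative
   null: the predicted joint LRR is the sum of the single-stressor LRRs.
   The model deviation ratio `MDR = exp(s·(LRR_obs − LRR_A − LRR_B))`
   (sign `s` flipped when both stressors act negatively) classifies each
   stressor pair as synergistic (MDR > 2), antagonistic (MDR < 0.5) or
   additive, after a noise filter removes pairs whose single effects are
   opposite-signed and indistinguishable from control variability.

Around these sit the standard meta-analytic diagnostics: Cramér's V
collinearity screening, marginality-respecting backward selection with
Satterthwaite F tests, study-level Cook's distance by exact refits,
leave-one-study-out cross-validation, marginal/conditional R², three-level
REML random-effects meta-analysis with multilevel I² and Q, funnel data and
Egger's regression test — plus a seeded synthetic-data generator with known
ground truth so the whole chain is testable without any external download.

The intended users are ecologists and meta-analysts with arm-level summary
data (mean, SD, n per control/treatment arm and response) from experiments
that crossed two or three stressors against a control.

## Worked example

```r
library(befstress)

cfg <- sim_config(n_studies = 25, seed = 42)   # synthetic 25-study database
report <- run_bef_pipeline(cfg, run_loso = FALSE)
report
#> Multi-stressor BEF pipeline report
#>   BEF model: n = 75, 25 groups; marginal R2 = 0.19, conditional R2 = 0.53
#>   diversity slope = 0.723; slope x stressor-number not retained (NA)
#>   MDR (function): additive 92%, antagonistic 4%, synergistic 4%
#>   MDR (richness): additive 96%, antagonistic 0%, synergistic 4%
#>   MDR correlation: r = -0.165 (p = 0.43, n = 25)
#>   richness: I2 between = 28%, within = 68%, Q = 1259 (df 74), Egger p = 0.00
#>   function: I2 between = 42%, within = 56%, Q = 3756 (df 74), Egger p = 0.29
#>   excluded effect-size values: 0.0%
```

Reading the output: the diversity slope (0.72) is the fitted BEF
relationship — positive, as the generator built in (`bef_slope_base = 0.5`
plus part of the stressor-number increment, since backward selection
pooled the slopes here: at 25 noisy studies the `LRR_TR × NS` interaction
is not always detectable, a power limit the full-scale analysis shares).
MDR proportions near 92/4/4 reflect sampling noise around the exact
multiplicative null used by the generator (`interaction_delta = 0`), and
the gap between marginal (0.19) and conditional (0.53) R² follows from the
generator's between-study variance.  The richness-side Egger p-value is
small because binomial richness sampling couples effect and SE — a
structural feature worth knowing when interpreting Egger's test on
count-derived effect sizes.

Individual stages are ordinary data-frame functions that compose with the
pipe:

```r
db <- generate_database(cfg)
effects <- db$observations |>
  harmonise_observations() |>
  add_effect_sizes()

classify_interactions(effects)$proportions   # MDR classes by response
tidy(backward_select(bef_model_data(effects)$data)$fit)
plot_mdr(classify_interactions(effects)$results)
```

To analyse a real database, pass a data frame in the harmonised schema
(one row per study × arm × time point; see `?validate_observations`) to
`run_bef_pipeline()` instead of a `sim_config`.

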