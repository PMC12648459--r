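---
title: "Methods: multi-stressor effects on the biodiversity–ecosystem-function relationship"
author: "befstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-stressor effects on the biodiversity-ecosystem-function relationship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(befstress)
library(dplyr)
```

`befstress` implements a meta-analytic inference chain for a recurring
question in freshwater ecology: does the relationship between biodiversity
change and ecosystem-function change (the BEF relationship) depend on how
many anthropogenic stressors act at once?  The package takes arm-level
summary statistics from factorial multi-stressor experiments (control and
treatment mean, SD and replicate count for taxon richness, Shannon
diversity and one ecosystem-function response) and carries them through
harmonisation, effect-size computation, a multiplicative-null interaction
analysis, nested mixed-effects moderator models, and multilevel
heterogeneity and publication-bias diagnostics.

This vignette documents the statistical model behind each stage, the
tunable parameters and their defaults, the design decisions taken where the
methodology was genuinely open, and what the synthetic-data generator can
and cannot tell you about behaviour on real data.

## Effect sizes: bias-corrected log response ratios

The effect-size currency is the log response ratio,
$\mathrm{LRR} = \log(\bar{x}_T/\bar{x}_C)$, computed per response variable
(richness $\mathrm{LRR}_{TR}$, Shannon $\mathrm{LRR}_{SD}$, function
$\mathrm{LRR}_{EF}$).  With few replicates the plug-in estimator is biased
because $E[\log \bar{x}] < \log E[\bar{x}]$ by an amount that scales with
the sampling variance of each arm mean; the bias survives in the ratio
whenever the two arms have unequal coefficients of variation.
`lrr_corrected()` applies the second-order delta-method correction to both
the point estimate and the sampling variance:

$$\mathrm{LRR} = \log\frac{\bar{x}_T}{\bar{x}_C}
  + \frac{1}{2}\left[\frac{s_T^2}{n_T \bar{x}_T^2}
  - \frac{s_C^2}{n_C \bar{x}_C^2}\right],\qquad
v = \frac{s_T^2}{n_T \bar{x}_T^2} + \frac{s_C^2}{n_C \bar{x}_C^2}
  + \frac{1}{2}\left[\frac{s_T^4}{n_T^2 \bar{x}_T^4}
  + \frac{s_C^4}{n_C^2 \bar{x}_C^4}\right].$$

Zero or negative arm means (zero richness from sporulation assays, negative
production rates under biomass loss) make the log undefined.  Those values
are flagged and set to `NA` with a machine-readable reason
(`zero_richness`, `negative_production`) rather than raising an error, so a
single bad arm never silently drops a study.  `exclusion_report()` counts
exclusions both over individual values and over observation rows, since an
"excluded fraction" can be defined either way.

## Harmonisation

Three operations turn raw arm-level records into the analysis table:

* `drop_pre_exposure()` removes measurements taken before stressor exposure.
* `select_highest_level()` keeps, per study and stressor, only arms at the
  maximal reported intensity level; a joint arm survives only if every one
  of its stressors sits at its maximum.  Ties are broken by first
  occurrence, with a warning.
* `aggregate_time()` collapses repeated measurements to one row per
  observation.  The default averages arm means over post-exposure time
  points; the alternative `max_richness_deviation` keeps the single time
  point where treatment richness deviates most from the control, as a
  sensitivity analysis.

How SDs should be combined when means are averaged over time points is not
fixed by any convention we know of; the package pools them as the
root-mean-square of the per-time-point SDs, which is symmetric in the time
points and never smaller than the mean of the SDs.  The choice is isolated
in one internal function (`pool_sd_rms`) so alternatives can be swapped.

Moderator labels (organism group, ecosystem-function type, stressor
category) are validated against a fixed vocabulary, and organism-group ×
function pairs are checked against the a-priori attribution table
(`attribution_table()`): photosynthesis is attributable to algae, leaf
decomposition to heterotrophic microorganisms and macroinvertebrates, and
so on.  Unknown labels are rejected, never coerced — silently relabelled
moderators would corrupt the nested moderator models downstream.

## The multiplicative null model and model deviation ratios

Because effects are log ratios, "no interaction" between two stressors
means the joint response ratio is the *product* of the single-stressor
ratios — sums on the log scale.  For every two-stressor joint arm whose
both single-stressor arms exist, the model deviation ratio compares the
observed joint effect with that prediction as a ratio of response ratios:

$$\mathrm{MDR} = \exp\!\big(s\,(\mathrm{LRR}_{obs} -
  \mathrm{LRR}_A - \mathrm{LRR}_B)\big),\qquad
s = \begin{cases}-1 & \mathrm{LRR}_A < 0 \text{ and } \mathrm{LRR}_B < 0\\
  +1 & \text{otherwise.}\end{cases}$$

$\mathrm{MDR} > 2$ is classified as synergism, $\mathrm{MDR} < 0.5$ as
antagonism, and everything in between — including the boundary values
themselves — as additive.  The sign flip makes "joint decline stronger than
predicted" register as $\mathrm{MDR} > 1$ when both stressors act
negatively; without it the synergism and antagonism boundaries would be
reversed for shared declines.  Note that for a plain ratio
$\mathrm{LRR}_{obs}/(\mathrm{LRR}_A + \mathrm{LRR}_B)$ the flip would
cancel between numerator and denominator and carry no information, which is
why the exponentiated-difference form is the default; the plain-ratio
variant remains available (`form = "plain-ratio"`) for sensitivity
analysis.

Joint arms of three or more stressors are omitted (no agreed classification
boundaries exist for higher-order deviations); three-stressor studies
contribute their three pairs.

**Noise filter.**  When both single-stressor effects are indistinguishable
from control-level sampling variability *and* point in opposite directions,
the MDR is the ratio of two random numbers near zero and its
classification is an artefact.  Such pairs are excluded.  The noise band is
defined from the global coefficient of variation of control arms (computed
per response variable, never pooled): an effect is "within noise" if
$|\mathrm{LRR}| \le \theta$ with $\theta = \log(1 + f \cdot
\mathrm{CV}_{global})$ and $f = 0.25$ by default.  Mapping the fraction of
the control CV onto the log-ratio scale through $\log(1+x)$ is the minimal
interpretation of a "±25 % of control variability" band; $\theta$ is
recorded in the output metadata.  Whether the noise rule should compare the
two single-stressor effects (implemented, consistent with "opposite
signs") or observed-versus-predicted joint effects is ambiguous in the
wider MDR literature; the alternative is not implemented.

`mdr_moderator_models()` then asks whether deviation from the null depends
on organism group, stressor combination or function type, by fitting linear
mixed models of $\log \mathrm{MDR}$ (symmetric around additivity at zero)
with a random study intercept, and `mdr_correlation()` tests whether
richness and function MDRs co-vary across matched pairs.

## The nested BEF mixed model

The central model regresses the function effect size on the diversity
effect size and its moderators:

$$\mathrm{LRR}_{EF} \sim \mathrm{LRR}_{TR} + NS/SC + EF/TG +
\mathrm{LRR}_{TR}\times NS + \mathrm{LRR}_{TR}\times EF +
\mathrm{LRR}_{TR}\times NS/SC + \mathrm{LRR}_{TR}\times EF/TG
+ (1\,|\,\text{study}),$$

with the number of stressors $NS$ continuous, stressor combination $SC$
nested within $NS$, and organism (taxonomic) group $TG$ nested within
ecosystem-function type $EF$.  The slope of
$\mathrm{LRR}_{EF}$ on $\mathrm{LRR}_{TR}$ — the BEF relationship — and its
interaction with $NS$ are the quantities of interest: a positive
interaction means the consequences of taxon loss for function steepen as
stressors accumulate.  Nested categorical terms are encoded as
level-specific treatment contrasts via the standard `a + a:b` expansion;
a Shannon-diversity variant (`covariate = "shannon"`) runs the same
pipeline with $\mathrm{LRR}_{SD}$.

Before fitting, `cramers_v_screen()` computes Cramér's V between every
moderator pair and flags pairs above 0.7.  Flagged pairs are *reported, not
dropped*: nested pairs such as organism group within function type exceed
the threshold by construction of the attribution table, and removing them
would destroy the nesting the model requires.  The flag is prominent in the
output so the analyst can judge.

**Term tests and selection.**  `backward_select()` iteratively removes the
least significant removable term with $p > \alpha$ (default 0.05),
where "removable" excludes any term contained in a retained higher-order
term — main effects of retained interactions and nesting parents of
retained nested terms are never dropped, so marginality holds at every
step.  Ties break by larger p-value, then later position in the term list;
the procedure is deterministic and every removal is logged in a selection
trail.  Term p-values come from type-II F tests with Satterthwaite
denominator degrees of freedom on the REML fit.  We initially used
maximum-likelihood likelihood-ratio chi-square tests and found them
severely anticonservative at this design's size (roughly 25 fixed-effect
columns on 100–300 observations): in null simulations, multi-degree-of-
freedom moderator terms reached $p < 0.05$ far above the nominal rate and
backward selection retained spurious moderators in most runs.  The
Satterthwaite F approximation is calibrated in the same simulations
(rejection rates 0.04–0.07 at $\alpha = 0.05$) and is therefore the
default.  Model rank deficiency (nested contrasts only partly observed) is
tolerated: terms whose design columns are entirely aliased test as $p = 1$
and are removed first.

**Fit statistics and diagnostics.**

* Variance-partition $R^2$: marginal
  $R^2_m = \sigma^2_f/(\sigma^2_f + \tau^2 + \sigma^2)$ and conditional
  $R^2_c = (\sigma^2_f + \tau^2)/(\sigma^2_f + \tau^2 + \sigma^2)$, with
  $\sigma^2_f$ the variance of the fixed-effect linear predictor.
* `cooks_distance_by_study()` measures study influence by exact deletion
  refits: $D_j = (\hat\beta - \hat\beta_{-j})^\top
  \widehat{V}(\hat\beta)^{-1} (\hat\beta - \hat\beta_{-j})/p$, with the
  conventional conservative threshold 0.5.  With ~50 studies the 50 refits
  are cheap, so no one-step approximation is used.  If deleting a study
  removes a factor level, the comparison uses the shared coefficients and
  the study is flagged.
* `loso_cv()` refits once per held-out study and summarises sign stability
  and range of the diversity slope and its $NS$ interaction.
* The unweighted LMM is the default — the model treats each observation's
  LRR as the response without inverse-variance weights; a
  `weights = "inverse-variance"` switch turns the same model into a
  meta-regression for sensitivity analysis.

## Three-level meta-analysis, I², and Egger's test

`fit_three_level()` fits $y_{ij} = \mu + u_j + w_{ij} + e_{ij}$ by REML
(through `metafor::rma.mv`), with a between-study component $u_j$, a
within-study component $w_{ij}$ for multiple effects per study, and known
sampling variances $\mathrm{Var}(e_{ij}) = v_{ij}$ from the delta-method
formulas above.  Heterogeneity beyond sampling error is summarised by
$Q$ (the weighted residual sum of squares about the fixed-effect pooled
mean, $df = k - 1$) and by the multilevel $I^2$, which partitions total
variability using the typical sampling variance
$\tilde v = (k-1)\sum w_i / \big[(\sum w_i)^2 - \sum w_i^2\big]$,
$w_i = 1/v_i$:

$$I^2_{level} = 100\cdot\frac{\tau^2_{level}}
{\tau^2_{between} + \tau^2_{within} + \tilde v}.$$

Egger's test for funnel asymmetry is implemented in its multilevel form —
the sampling standard error enters the three-level model as a moderator and
its coefficient is tested — so the test respects the same hierarchical
structure as the pooled model.  The classical two-level weighted regression
is available (`method = "classical"`) for cross-checking.  Rows without a
positive sampling variance (e.g. richness arms reported without SDs) are
excluded from this stage only, with a logged count.

## The synthetic-data generator

`generate_database()` emulates the statistical structure of a database of
small factorial freshwater experiments — not their ecology.  Per study it
draws a stressor richness (1–3), an organism-group/function pair from the
attribution table, stressor categories, a study intercept
$u_j \sim N(0, \tau^2_{study})$ and a lognormal function baseline; single-
stressor true effects come from configurable normal distributions, and
every joint arm's true LRR is the *sum of its single-stressor LRRs* (the
multiplicative null) plus `interaction_delta` and the stressor-number-
dependent BEF slope increment on the function response.  Replicate-level
data are then realised as binomial thinnings of a species pool (richness —
guaranteeing integer counts and the ≥ 4-taxa baseline) and lognormal draws
(function and Shannon, with coefficient of variation `control_cv`);
controls are drawn once per study and shared across arms, as in a real
factorial design.

Default conditions: 51 studies; stressor-richness probabilities
(0.3, 0.4, 0.3); 4 replicates per arm; a 12-taxon species pool with control
persistence 0.9; `control_cv = 0.3`; $\tau^2_{study} = 0.1$; single-stressor
effects $N(-0.3, 0.4^2)$ for richness and $N(-0.2, 0.8^2)$ for function
(which span roughly 0.2–3-fold and 0.1–10-fold changes relative to control,
the ranges such experiments report); BEF slope 0.5 at one stressor with
increment 0.3 per added stressor; `interaction_delta = 0`.  Replicate
counts per arm are not reported consistently by real studies, so
`n_replicates` is a free parameter rather than an empirical calibration.

Three design consequences are worth knowing:

* **`control_cv = 0` is a deterministic mode**: arm summaries equal their
  exact expectations with zero SD, and richness expectations are left
  uncapped, so noise-free data reproduce the multiplicative null exactly —
  this is what makes oracle tests of the MDR chain possible.  With
  `control_cv > 0` the binomial survival probability is capped at 1, which
  slightly attenuates large positive richness effects.
* **The sum rule couples arms within a study**: a joint arm's truth
  contains its singles' realised deviations, so joint-arm residuals are
  correlated with single-arm residuals and their variance grows with the
  number of stressors.  A homoscedastic random-intercept LMM is therefore
  mildly misspecified on generator data — deliberately so, since real
  factorial experiments share controls and substrates the same way.  This
  is why the null-behaviour check of backward selection simulates the
  response from the homoscedastic null model on the generator's design,
  while slope-recovery checks accept slightly sub-nominal Wald coverage.
* **No mechanistic ecology**: no co-tolerance structure, no species
  interactions, no temporal dynamics.  Passing tests demonstrate that the
  statistical machinery recovers known structure under the model's own
  assumptions; they say nothing about whether those assumptions hold in any
  particular experiment.

`spike_interactions()` overwrites the function-response truth of chosen
fractions of two-stressor joint arms with a known MDR of
$e^{\pm\text{magnitude}}$ (the shift direction defined under the same
sign-flip rule the classifier uses), giving datasets whose expected
classification proportions are known exactly — the ground truth for
recovery tests.

## Worked example

```{r example, message = FALSE, warning = FALSE}
cfg <- sim_config(n_studies = 25, seed = 42)
report <- run_bef_pipeline(cfg, run_loso = FALSE)
report
```

```{r tables}
tidy(report$fit)
report$null_model$proportions
```

```{r plots, warning = FALSE}
plot_bef_slopes(report$marginal_effects)
plot_mdr(report$null_model$results)
```

## Numerical choices and degenerate inputs

* Classification boundaries 0.5 and 2 are strict inequalities; the
  boundary values classify as additive.
* Single-level moderators are dropped from the design with a warning;
  degenerate contingency tables make Cramér's V `NA` with a warning;
  fewer than 3 matched pairs make the MDR correlation `NA`.
* Arms with fewer than two replicates cannot carry the small-sample
  correction and fall back to the raw LRR with a warning.
* REML non-convergence in the three-level model falls back to a different
  optimiser; singular random-effect fits are flagged but retained.
* All randomness flows from the configuration seed; identical
  configurations give byte-identical databases and reports.

## Problem sizes used in the test suite

The simulation-based checks run at sizes chosen to make Monte-Carlo error
small relative to the assertions: $10^5$ replicates for the bias-correction
comparison, ~500 and ~1000 stressor pairs for null-recovery and
spiked-proportion recovery (tolerance three binomial standard errors), 200
replicates for mixed-model coverage and three-level variance-component
recovery, and 150 replicates for Egger calibration.

## Known limitations

* The MDR sign-flip convention, while necessary for shared declines, makes
  opposite-sign pairs hard to interpret; the noise filter removes only the
  small-effect subset of them.
* Between-study moderators (organism group, function type) are partially
  confounded with the random study intercept; their tests are exact only
  under the fitted model, and backward selection inherits the usual
  multiple-looks inflation of stepwise procedures.
* The generator's richness model cannot produce treatment richness above
  the species pool, so strong positive richness effects are attenuated
  unless the pool is enlarged.
```
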