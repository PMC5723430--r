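---
title: "Methods: scoring ultra-processed food intake and modelling its outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring ultra-processed food intake and modelling its outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upfdiet)
```

This vignette is the package's account of its own methods: the models it
fits, the conventions it adopts where several were defensible, the
numerical choices that matter, and what its synthetic data can and cannot
tell you about real cohorts.

## 1. From categorical answers to grams per day

A month-recall food frequency questionnaire (FFQ) of the DHQ-II family
records, per line item, a categorical frequency (8 ordered options for
foods, a longer list ending in "6 or more times per day" for beverages), a
categorical portion (3 options), and — for condiments — one of 5 options
for the fraction of the time the condiment accompanies its main food.

The instrument file maps options to numbers. The packaged defaults follow
the usual convention for semi-quantitative instruments: **"never" is 0**,
**bounded ranges take the arithmetic mean of their endpoints** (e.g. "3–4
times per week" becomes 3.5 × 30.4/7 times per month), and **open-ended
top categories are coded at their stated bound** ("2 or more times per
day" as 2/day). Top-coding at the bound is the conservative completion of
the averaging rule; if you prefer a different convention, edit the YAML —
nothing in the code assumes these values. Months are converted to days
with `days_per_month = 30.4` (365.25/12).

Grams per day for a food or beverage are

```
g/day = times_per_month(freq option) × grams_per_serving(amount option) / 30.4
```

and a condiment contributes `fraction × times_per_month(main item's
frequency) × grams_per_serving / 30.4` — it has no frequency of its own,
so a missing frequency on the main item is a hard error, not a zero.

## 2. Energy recomputation and the ultra-processed energy share

Energy is never read from a composition table; it is always recomputed
from macronutrients,

$$E\,[\mathrm{MJ}] = 0.017\,(g_{\text{carb}} + g_{\text{protein}}) + 0.037\,g_{\text{fat}},$$

because tabulated energy values are frequently inconsistent with the
tabulated macronutrients they accompany. The formula is linear, so the
identity "total energy equals the formula applied to total carbohydrate,
protein and fat" holds *exactly* by construction, and the test suite
asserts it to 10⁻⁹ together with the other conservation laws (group sums
equal subject totals; the 33 NOVA subgroups sum to their 4 parent groups;
per-subject energy shares across groups sum to 100).

Each subject's **PEI-UPF** is their own group-4 share of recomputed
energy. For the cohort-level nutrient table there are two defensible
percent conventions and the package exposes both:

* `cohort_sum` (default): share of the *cohort-wide sum* — an exact
  additive decomposition whose group entries always total 100;
* `subject_mean`: the mean of per-subject shares — for energy this equals
  the mean PEI-UPF by definition.

The two differ whenever intake level correlates with diet composition;
reports should state which convention they use.

## 3. Iterative random-forest imputation

Missing categorical answers are imputed on the option-index scale with
the iterative scheme popularised by missForest: initialise missing cells
with the column mode; visit variables in order of increasing missingness;
for each variable fit a random forest (100 trees, `ranger`) of that
variable on all others, using only rows where it is observed, and predict
its missing rows; repeat, and stop when the proportion of imputed cells
that changed *increases* between sweeps, returning the previous sweep
(cap: 10 sweeps). Determinism under a seed is guaranteed by seeding each
forest from `(seed, sweep, variable)` and breaking prediction ties toward
the lowest option index. Observed cells are never modified, and imputed
values always come from the variable's observed category set.

Structural blanks (a condiment's own frequency) are not variables at all,
so "missing" always means genuinely unanswered. The package also ships
`impute_mode()` as the reference baseline; on masked-at-random synthetic
responses the forest imputer's error is materially below mode imputation's
(about 0.54 vs 0.72 at 10% masking in the acceptance benchmark), which is
the behaviour that justifies the extra machinery.

## 4. Outcome models

The modelling stage is ordinary least squares dressed for the study
design: outcome on the focal dietary index plus adjustment covariates
(maternal age, race coded Caucasian vs African-American/other, clinic
low- vs high-income, weight status lean vs obese, daily energy and fat
intake, percent of time in moderate physical activity; neonatal outcomes
additionally adjust for gestational age at measurement). Two interaction
rules mirror the design:

* the **focal × weight-status** interaction is *forced* into every model,
  giving the lean and obese groups separate slopes and intercepts;
* every other focal interaction is *screened*: each candidate is added,
  alone, to the same base design and retained iff its extra
  sum-of-squares test has p < 0.05 (two-sided). Screening one-at-a-time
  against a fixed base makes the result independent of candidate order.

Coefficients are reported with t-based Wald intervals (n = 45 is small
enough that normal intervals would be noticeably anticonservative).
Predictors enter **uncentered** by default — with an uncentered
focal × age interaction, the large positive age main effect and the
negative interaction coefficient are two faces of the same fit — and
`center = TRUE` is available when a marginal-effect parametrisation is
wanted. No multiple-testing correction is applied across the four
outcomes; treat the per-outcome p-values accordingly.

Index comparison uses adjusted R² of each index's fully adjusted model
plus the extra sum-of-squares F-test for adding the second index's main
term to the first index's model,
$$F = \frac{(RSS_{\text{red}} - RSS_{\text{full}})/\Delta df}{RSS_{\text{full}}/df_{\text{full}}},$$
with the degenerate case (the added index already spanned by the reduced
model) reported as F = 0, p = 1 rather than an error. The
PEI-UPF–HEI-2010 association is a Pearson correlation with a Fisher-z
interval. Diagnostics are Shapiro–Wilk on residuals, the slope of squared
residuals on fitted values, the quadratic coefficient of residuals on
fitted values and their square, and a two-sided Durbin–Watson test; all
four hold their ~5% type-I rate at n = 45 in the null simulations run by
the acceptance suite, and a numerically perfect fit reports every
component as "not computable" instead of flagging.

## 5. What the synthetic generator emulates

`generate_cohort()` draws the dietary indices through a Gaussian copula
with **moment-matched truncated-normal margins** on [0, 100]: the
underlying (μ, σ) are solved so the *truncated* distribution has exactly
the target mean and SD (PEI-UPF 54.4/13.2, HEI-2010 62.2/13.0), rather
than ignoring the truncation bias; a beta margin could also honour the
bounds but cannot honour two printed moments as directly. The copula
correlation is set to the target (−0.74); the additional attenuation from
truncation is below 0.005 and is ignored. Group sizes are allocated
exactly (16 lean, 29 obese at n = 45), matching a fixed two-group design
rather than Bernoulli sampling. Outcomes are linear predictors — focal
effects 1.33 kg gestational weight gain, 0.22 mm thigh skinfold, 0.14 mm
subscapular skinfold, 0.62 percentage points neonatal body fat per
PEI-UPF point, a negative focal × age interaction, a small
focal × obesity interaction, and covariate effects on the scale of the
study's adjusted models — plus normal noise. The intercept of each model
is solved so the expected outcome at the covariate means equals the
target outcome mean (12.0 kg, 6.6 mm, 4.4 mm, 11.5%).

**Residual SDs are calibrated, not reported values.** The study prints
coefficients and intervals but not residual variances, so each outcome's
residual SD was solved once so that the expected standard error of the
focal coefficient at n = 45 matches the half-width of that outcome's
printed interval (targets 0.517, 0.097, 0.069, 0.285; solved SDs 6.26,
1.16, 0.82, 3.40). The resulting marginal outcome SDs land close to the
published ones (e.g. ≈7 vs 7.2 kg for weight gain), which is a
consistency check, not an input. These SDs are conditions of the
simulation, fixed once; they are not tuned against test results.

`generate_responses()` then manufactures FFQ answers that *realise* each
subject's assigned PEI-UPF: portion and condiment options are driven by
latent per-subject tendencies (an appetite propensity shared across
items, a condiment-use habit), frequency options start from a
diet-pattern-shifted baseline (group-4 items higher for high-target
subjects, group-1 items lower), and a greedy pass then steps single
frequency options toward the target until the implied group-4 energy
share is within 0.25 points or no step improves it. The share is computed
with exactly the scoring engine's arithmetic, so scoring the unmasked
table reproduces the achieved share to machine precision; across a
default cohort the mean achieved-vs-assigned gap is under 0.1 points.
Finally, answers are masked completely at random at 5% (configurable).
The latent-tendency structure is what makes imputation a meaningful
problem: real FFQ columns are strongly cross-correlated through diet
patterns, and a generator without that structure would make *any*
model-based imputer look no better than the column mode.

What the generator does **not** emulate: the real DHQ II item inventory
(the packaged food list is a 32-item synthetic miniature), food
co-consumption beyond condiment attachment, differential or
non-ignorable missingness, under-reporting of intake, and any direct
HEI-2010 → outcome pathway (HEI-2010 influences outcomes only through its
correlation with PEI-UPF). Passing tests therefore demonstrate the
*machinery* — conservation, recovery, error rates — under a favourable,
known truth; they do not validate the epidemiology.

## 6. Measurement error and what "recovery" means

Two recovery checks run at different points of the chain, and they answer
different questions.

* **Cohort-stage recovery** (500 replicates, one OLS fit each): fitting
  the generating design on generated cohorts recovers each focal effect
  with |bias| < 5% and 93–97% interval coverage. This validates the
  modelling machinery at the study's n under the calibrated noise.
* **Full-chain recovery** (generate responses → impute → score → fit):
  the re-scored index differs from the assigned one because ~5% of
  categorical answers were masked and imputed; the resulting measurement
  error (SD ≈ 5 points, heavy-tailed — one wrong frequency bin on a
  high-energy item moves the share a lot) attenuates the focal slope.
  Attenuation bites hard here because PEI-UPF is nearly collinear with
  its own forced interactions, leaving little independent variation: the
  observed attenuation is roughly 10–20% at default missingness. The
  package reports this arm honestly (it is one of the quantities the
  acceptance script writes) instead of pretending the full chain is
  error-free; with `missing_rate = 0` the chain closes exactly.

This is the classical errors-in-variables phenomenon, and it applies to
the real instrument too: categorical frequency bins are a coarse
measurement of intake, so fully-adjusted slopes estimated from FFQ-derived
indices should be read as attenuated lower bounds.

## 7. Problem sizes and numerical conventions

Simulation sizes used by the test and acceptance suites are the package's
own choices, balancing Monte-Carlo error against runtime on a single CPU:
1,000 randomized profiles for the conservation invariants; 500 replicates
for cohort-stage recovery, interaction-screening type-I and diagnostic
type-I rates; 20 seeds for the imputation-vs-mode benchmark at 10%
masking; 8–40 seeds for full-chain characterisation. Other conventions:
all internal arithmetic is double precision with rounding only at report
time (one decimal for magnitudes ≥ 0.1, scientific notation below, with
full-precision companion files always written); conservation tolerances
are 10⁻⁹ absolute; OLS-vs-normal-equations agreement is asserted at 10⁻⁸
relative on well-conditioned fixtures; rank-deficient designs abort with
the collinear terms named rather than silently dropping them; and every
stochastic component (generator, masking, forests) is seeded explicitly.

## 8. Known limitations

HEI-2010 is consumed as a provided column, never computed from food
pattern equivalents. Single imputation only — imputation uncertainty is
not propagated into the model standard errors. The instrument schema
fixes three portion options and five condiment options; instruments with
other shapes need only a changed validator, but are not accepted today.
The greedy response constructor targets the energy share alone; other
nutrient shares are emergent, not controlled. And the modelling stage is
deliberately plain OLS: no mixed effects, no robust standard errors, no
Bayesian variants.
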