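# upfdiet

Scoring ultra-processed food intake from food frequency questionnaires, and
modelling its association with maternal and neonatal outcomes.

## The problem

Diet quality during pregnancy is usually summarised by *quantity*-based
measures (total energy, total fat) or by composite scores such as the
Healthy Eating Index 2010 (HEI-2010). An alternative is to classify every
food by the NOVA scheme — (1) unprocessed/minimally processed foods,
(2) processed culinary ingredients, (3) processed foods, (4) ultra-processed
foods — and summarise a diet by the **percent of energy intake from
ultra-processed foods (PEI-UPF)**:

```
PEI-UPF_i = 100 × E_i(group 4) / E_i(total)
```

`upfdiet` implements the full chain needed to compute and use that index
in a small observational cohort (pregnant women in the lean and obese BMI
ranges, and their newborns):

1. **Instrument model** — a DHQ-II-style month-recall FFQ: categorical
   frequency options (8 for foods, "never" … "6 or more times per day" for
   beverages), three portion options per item, five condiment-fraction
   options. Midpoints live in an editable YAML file.
2. **Intake scoring** — grams/day per item
   (`times_per_month × grams_per_serving / 30.4`; condiments ride on the
   frequency of the food they are added to), nutrient totals by NOVA group
   and 33 nested subgroups, and energy recomputed from macronutrients:
   `E [MJ] = 0.017·(g_carb + g_protein) + 0.037·g_fat`.
3. **Imputation** — missing categorical answers filled by iterative
   random-forest imputation (missForest-style: mode initialisation, visit
   order by increasing missingness, stop when the change metric rises),
   deterministic under a seed.
4. **Cohort models** — ANCOVA-style OLS of gestational weight gain and
   neonatal body-composition outcomes on PEI-UPF, adjusting for age, race,
   clinic, weight status, energy/fat intake and physical activity (plus
   gestational age at measurement for neonatal outcomes); the
   PEI-UPF × weight-status interaction is forced into every model, other
   PEI-UPF interactions are screened at α = 0.05. Indices are compared by
   adjusted R² and extra sum-of-squares F-tests; Pearson correlation with
   a Fisher-z interval links PEI-UPF and HEI-2010; residual diagnostics
   cover normality, homoscedasticity, linearity and independence.
5. **Synthetic cohort generator** — produces cohort tables and FFQ
   response tables with the statistical structure the models assume
   (PEI-UPF mean 54.4, SD 13.2; correlation −0.74 with HEI-2010 via a
   Gaussian copula; 16/29 lean/obese split; configurable linear outcome
   models), so the entire pipeline is testable without any external data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` for residual panels and intake
distributions.

## Worked example

```r
library(upfdiet)
instrument <- default_instrument()
foods      <- default_food_table()

# simulate a 45-subject cohort and its FFQ responses, 5% answers missing
cfg <- cohort_config(seed = 42)
gen <- generate_responses(cfg, instrument, foods)

imp      <- impute_responses(gen$responses, foods, seed = 42)
profiles <- score_intake(imp$responses, foods, instrument)
profiles
#> <intake_profiles: 45 subjects, 32 items>
#>   mean energy 4.17 MJ/day, mean PEI-UPF 55.8%

cohort <- assemble_cohort(gen$cohort, profiles)
fit <- fit_ancova(
  cohort, outcome = "gwg_kg", focal = "pei_upf",
  covariates = maternal_covariates(),
  forced     = "pei_upf:weight_status",
  candidates = "pei_upf:age")
fit
#> <ancova_fit: gwg_kg ~ pei_upf + 7 covariate(s)>
#>   forced interactions:   pei_upf:weight_status
#>   retained from screen:  pei_upf:age
#>   n = 45, adj. R^2 = 0.200
#>   pei_upf: 0.957 (0.263, 1.65), p = 0.0083
```

Reading: in this simulated replicate each additional percentage point of
energy from ultra-processed foods is associated with a 0.96 kg higher
gestational weight gain (95% CI 0.26–1.65) after adjustment; the
PEI-UPF × age interaction was screened and retained. The point estimate
scatters around the generator's true effect (1.33 kg per point) from
replicate to replicate, and is additionally attenuated a little because the
index is re-scored from imputed categorical answers rather than taken as
generated — see the methods vignette. `tidy(fit)` returns the full
coefficient table, `glance(fit)` the fit summary, `diagnose_fit(fit)` the
assumption checks:

```r
diagnose_fit(fit)
#>                          test statistic p_value computable  flag
#> 1           normality_shapiro    0.9889   0.940       TRUE FALSE
#> 2 heteroscedasticity_sq_resid    0.0628   0.950       TRUE FALSE
#> 3         linearity_quadratic    0.6504   0.519       TRUE FALSE
#> 4  independence_durbin_watson    2.3927   0.166       TRUE FALSE
```

`run_pipeline()` drives the same chain from files on disk and writes CSV
reports plus a JSON run summary; `inst/scripts/ffq-pipeline.R` wraps it for
the shell (`simulate` and `run` subcommands).

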