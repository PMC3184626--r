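# cfsmecosts

Employment discontinuation and productivity costs in adults with chronic
fatigue syndrome / myalgic encephalopathy (CFS/ME).

Adults with CFS/ME are often ill for years before assessment by a specialist
NHS service, and roughly half report having stopped work because of
fatigue-related symptoms by then. For health economists and epidemiologists
working with such assessment cohorts, this package provides the full
analysis pipeline:

* **Questionnaire scoring** — Chalder Fatigue Scale (0–33), SF-36 physical
  function subscale (0–100), HADS anxiety/depression (0–21 each) and a
  visual-analogue pain rating, with the standard missing-item rule (more
  than one unanswered item ⇒ missing; exactly one ⇒ pro-rated adjusted
  total) and linear rescaling to a common 0–10 range for regression.
* **Factors associated with discontinuation** — median/IQR group summaries,
  chi-squared / pooled-t / Cochran–Armitage tests, and partially and fully
  adjusted logistic regression fitted by an IRLS routine with Wald
  confidence intervals and explicit separation and collinearity
  diagnostics.
* **Human-capital cost estimation** — for each sex-and-age stratum the loss
  is `N × d × (m/12) × f × y`: patients, fraction discontinued, median
  illness duration (months), the per-sex unemployment fraction `f` (duration
  unemployed / duration ill, estimated from an external sample), and mean
  annual income. Per-person losses are reported on pooled age groups (18–21
  pooled into 22–29).
* **Nationwide extrapolation** — annual service-access rates per 100,000
  catchment population, multiplied by UK population estimates and per-person
  losses; plus one-way sensitivity analyses at the 95% CI bounds of the
  unemployment fractions and of the per-stratum discontinued proportions.
* **A synthetic cohort generator** — `simulate_cohort()` /
  `simulate_external_sample()` with known truth parameters, used by the test
  suite for parameter-recovery and coverage studies.

## Worked example

The packaged reference inputs (per-stratum cohort summaries, 2009 incomes,
catchment and UK populations, and the per-sex unemployment fractions 0.52
for men and 0.47 for women) reproduce the full analysis:

```r
library(cfsmecosts)

summaries <- reference_stratum_summary()
economics <- reference_economics()
fractions <- reference_unemployment_fractions()

ct <- compute_cost_table(summaries, economics, fractions)
ct$total
#> # A tibble: 1 × 3
#>       n total_loss per_patient
#>   <dbl>      <dbl>       <dbl>
#> 1  2170  49223672.      22684.
```

The 2,170 patients had accrued a total productivity loss of about £49.2
million before assessment — £22,684 per patient (£44,515 per man, £16,130
per woman; men's losses are larger because of higher incomes and a higher
discontinuation fraction).

```r
np <- national_projection(ct, economics, years = 4)
np$total
#> # A tibble: 1 × 5
#>       n catchment  rate projected_patients projected_cost
#>   <dbl>     <dbl> <dbl>              <dbl>          <dbl>
#> 1  2170   4701710  11.5              4424.     102215180.
```

The cohort corresponds to an access rate of 11.54 assessed patients per
100,000 catchment population per year; scaled to the UK population that is
about 4,424 adults assessed annually, carrying roughly £102.2 million of
accrued productivity losses per year.

```r
sensitivity_one_way(summaries, economics, fractions, "unemployment_fraction")
#> One-way sensitivity on unemployment_fraction:
#>   base 102,215,180, range 75,481,784 - 128,948,577
```

Moving the unemployment fractions to their 95% CI bounds spans roughly
£75.5–£128.9 million per year.

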