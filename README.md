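# sccspipe

A tidyverse-native R package for **self-controlled case series (SCCS)**
analysis of medication safety from routinely collected prescription and
diagnosis records, built around the question: *does the rate of a rare
acute event (e.g. an incident psychotic event) rise while a patient is on
stimulant treatment, or in the weeks just before treatment starts?*

The SCCS design analyses only cases — patients who experienced the event —
and compares event rates across exposure periods *within* each patient's
own observation time, so all fixed between-person confounding cancels
exactly. The package covers the full pipeline:

* **records** — schema-checked CSV readers/writers; prescription-to-episode
  construction with duration imputation (recorded span → quantity/dose →
  dataset median) and overlap/abutment merging.
* **windows** — per-patient observation windows bounded by study dates,
  6th/20th birthdays, death, and censoring drugs; incident-event selection
  with prior-event exclusion.
* **segmentation** — person-time classified as exposed / pre-exposure /
  excluded-washout / baseline, then cut at birthdays and calendar quarters
  into model-ready intervals; first-day event tie rules.
* **sccs_fit** — the conditional Poisson (multinomial) likelihood fitted by
  Newton–Raphson with analytic derivatives; Wald intervals, contrasts,
  broom-style `tidy()`/`glance()`, `autoplot()`.
* **scenarios** — a declarative battery of 24 built-in analyses (primary,
  pre-exposure 30/60/90 d, washouts 7–21 d, exposure extensions 1–10 w,
  6-month age bands, censoring/exclusion variants, late entry) rendered as
  deterministic text/CSV/JSON reports.
* **samplesize** — the binomial-approximation SCCS sample-size and power
  formulas, plus a Monte-Carlo check.
* **synthetic_data** — a seeded piecewise-constant-hazard simulator whose
  defaults reproduce the motivating study's scale (70-day median
  prescriptions, ~2.2 exposed years and ~10 observed years per case, rare
  events at ~6/10,000 patient-years, true pre-exposure IRR 4.64).
* **cli** — `inst/cli/sccs.R` with `run`, `simulate`, `samplesize`,
  `fixture` subcommands and meaningful exit codes (0 ok / 1 usage / 2
  data-or-estimation error).

## Worked example

```r
library(sccspipe)

# a synthetic 150-case cohort at the study's defaults (deterministic seed)
cfg <- simulation_config(n_cases_target = 150L)
cohort <- simulate_sccs_cohort(cfg, seed = 2014)

# run the primary analysis with the 90-day pre-exposure window
report <- run_scenario(cohort, sccs_scenarios()$pre90)
print(report)
```

```
pre90 (n=150)
  90 days before first treatment          3.27 | 1.70–6.32 | <0.01
  Period with treatment                   1.28 | 0.86–1.90 | 0.22
```

The simulated truth here is a pre-exposure IRR of 4.64 and an on-treatment
IRR of 1.0: the fitted intervals cover both. Tidy access:

```r
tidy(report)
```

```
# A tibble: 2 × 8
  scenario n_cases status term           irr ci_low ci_high  p_value
  <chr>      <int> <chr>  <chr>        <dbl>  <dbl>   <dbl>    <dbl>
1 pre90        150 ok     pre_exposure  3.27  1.70     6.32 0.000408
2 pre90        150 ok     exposed       1.28  0.862    1.90 0.222
```

The study's published sample-size calculation is reproduced exactly from
its person-time split (223.0 exposed vs 823.6 unexposed patient-years,
target IRR 2, 80% power, two-sided 5% significance):

```r
sccs_sample_size(r = 223.0 / (223.0 + 823.6), irr = 2)
#> [1] 76
```

End-to-end from CSV files (writes `report.txt/csv/json`, `intervals.csv`,
and a `run.log` attrition funnel):

```r
write_cohort(cohort, "demo_in")
sccs_run("demo_in", "demo_out")            # full 24-scenario battery
```

or from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","sccs.R",package="sccspipe"))')" \
  run --input demo_in --out demo_out
```

## Installation and reproduction

```sh
R CMD INSTALL --no-docs --no-html --no-help .
```

Run the test suite against the installed package (unit, property, and
acceptance tests; the two Monte-Carlo acceptance blocks take a few minutes
each):

```r
testthat::test_dir("tests/testthat", package = "sccspipe",
                   load_package = "installed")
```

Compute the self-contained acceptance target:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
# -> {"t1":{"value":76,"n":103}}
```

One acceptance block is expected to fail by design: the analytic power
formula at (r = 0.2, IRR = 2, n = 76) is 0.789 while the exact
Monte-Carlo rejection probability is 0.752 — the published approximation
is more than 2 percentage points optimistic at that design point. The
formula is implemented as published; the test documents the approximation
error rather than hiding it (see the methods vignette,
`vignettes/sccs-methodology.Rmd`).

## Notes

* All randomness is seed-controlled; reports and simulator output are
  byte-reproducible.
* The `other_psychotic` outcome group is empty by default; supply a YAML
  code map (`read_code_map()`) to extend the outcome definition.
* Estimates from the motivating study's confidential records are not
  reproducible at desk scale; the package reproduces the methods, the
  printed sample-size figure, and simulation-verified statistical
  properties (unbiasedness, CI coverage, test size).
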