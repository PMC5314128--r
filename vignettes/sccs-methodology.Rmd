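---
title: "Self-controlled case series methodology in sccspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-controlled case series methodology in sccspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccspipe)
```

## The scientific problem

Stimulant medication safety questions — does starting or being on
methylphenidate-like treatment raise the rate of rare acute events such as
psychotic episodes? — are hard to answer with between-person comparisons,
because treated and untreated children differ in unmeasured ways.  The
self-controlled case series (SCCS) design sidesteps this by analysing only
*cases* (patients who experienced the event) and comparing event rates
across periods *within* each patient's own observation time.  All fixed
person-level confounders (genetics, severity, socioeconomic status) cancel
exactly.

`sccspipe` implements the complete pipeline: raw prescription and diagnosis
records in, incidence-rate-ratio (IRR) tables with confidence intervals
out, together with a declarative battery of sensitivity analyses and a
calibrated synthetic-data simulator so that every stage is testable without
access to confidential source records.

## Model

Let patient $i$'s observation window be partitioned into intervals $j$ with
lengths $t_{ij}$ (days), covariates $x_{ij}$ (exposure category, age band,
season) and event counts $n_{ij}$.  Interval counts are modelled as Poisson
with rate $\exp(\phi_i + x_{ij}^\top\beta)$ per day.  Conditioning on the
patient's event total $N_i = \sum_j n_{ij}$ removes the nuisance intercepts
$\phi_i$ and yields a per-patient multinomial likelihood

$$
\ell(\beta) \;=\; \sum_i \sum_j n_{ij}
  \log \frac{t_{ij}\,e^{x_{ij}^\top\beta}}
            {\sum_k t_{ik}\,e^{x_{ik}^\top\beta}} .
$$

Here each case contributes exactly one event ($N_i = 1$: the incident,
first-ever event), so each patient's contribution is the log-probability
that their event fell in the interval where it was observed, under
length-and-rate-proportional placement.

### Exposure categories

Person-time is classified with the precedence
`exposed > excluded_washout > pre_exposure > baseline`:

* **exposed** — days covered by an on-medication episode.  Episodes are
  built by merging overlapping or abutting prescriptions; duration is the
  recorded start–end span, else quantity/dose, else an imputed dataset
  median (70 days by default).
* **pre_exposure** — a fixed window (90 days by default; 30/60-day
  variants) immediately before the *first-ever* episode.  Events cluster
  here when the event itself precipitates treatment (reverse causality);
  estimating this term separately protects the exposed-term contrast.
* **excluded_washout** — optional 7–21 days immediately before the first
  episode, removed from analysed person-time entirely, consuming the
  overlapping tail of the pre-exposure window.
* **baseline** — everything else; the reference category.

Intervals are further split at every birthday (or half-birthday for
6-month bands) and every calendar-quarter boundary, and the model adjusts
for age band and season with corner-point coding.  Age bands anchor at the
birthday, not the calendar year, because study entry is the sixth
birthday.

### Observation windows

A patient is observed from the later of the study start and their sixth
birthday, to the earliest of the study end, the day before their twentieth
birthday, the day before any atomoxetine switch, death, and (in one
scenario) the day before a first antidepressant/antipsychotic
prescription.  Only the first-ever qualifying event counts, and patients
with a qualifying event before their window are excluded rather than
re-windowed.  An event recorded on the first day of an episode and flagged
as occurring *before* that day's treatment is assigned to the interval
ending the previous day.

### Estimation

`sccs_fit()` maximises $\ell(\beta)$ by Newton–Raphson with analytic
gradient and Hessian, step-halving, a zero start, and convergence declared
at gradient max-norm below $10^{-8}$.  The covariance is the inverse
negative Hessian.  Patients with no event, or whose intervals all share a
single covariate pattern, contribute a constant to $\ell$ and are dropped
and counted.  Coefficients with $|\hat\beta| > 10$ trigger a separation
warning rather than silent reporting.  The implementation is
cross-checked, at machine precision, against `survival::coxph` with
stratification by patient and a log-length offset — an independent
formulation of the same conditional likelihood.

## Sample size and power

`sccs_sample_size()` implements the binomial approximation for the
single-exposure SCCS: with exposed fraction $r$ of observation time and
target IRR $\rho$, the event lands in exposed time with probability
$\pi_0 = r$ under the null and $\pi_1 = r\rho/(r\rho + 1 - r)$ under the
alternative, giving

$$
n \;=\; \Big\lceil
\big(z_{1-\alpha/2}\sqrt{\pi_0(1-\pi_0)} + z_{\text{power}}\sqrt{\pi_1(1-\pi_1)}\big)^2
\big/ (\pi_1 - \pi_0)^2 \Big\rceil .
$$

```{r}
sccs_sample_size(r = 223.0 / (223.0 + 823.6), irr = 2)
```

A caution established by this package's own acceptance testing: the
normal-approximation power implied by this formula can differ from the
exact power of any standard binomial test by more than two percentage
points at moderate $n$ (at $r = 0.2$, $\rho = 2$, $n = 76$ the formula
gives 0.789 while the exact rejection probability is 0.752).  The formula
is implemented as published; treat its output as an approximation.

## The simulator

`simulate_sccs_cohort()` draws case patients whose *first* event falls
inside their window, from a piecewise-constant daily hazard

$$
\lambda(d) = b \cdot e^{\gamma\,(\text{ageband}(d) - 6)} \cdot
  s_{\text{season}(d)} \cdot \rho_{\text{category}(d)},
$$

with defaults calibrated to the motivating study population: baseline rate
$b = 1.7\times10^{-6}$/day ($\approx 6$ per 10,000 patient-years), median
70-day prescriptions, about 2.2 exposed years and 10 years of observation
per case, 5% atomoxetine switching, and a true pre-exposure IRR of 4.64
with a true exposed IRR of 1.

Conditioning on being a case uses rejection sampling with bounded work: a
candidate's structure is accepted with probability
$p_{\text{case}}/p_{\text{cap}}$, where
$p_{\text{case}} = 1 - e^{-\Lambda}$ comes from the candidate's exact
cumulative hazard and $p_{\text{cap}}$ is an analytic upper bound; the
event day is then drawn from the exact conditional first-event law by
inverting the cumulative hazard at a truncated-exponential target.  This
is distributionally identical to simulating unconditionally and keeping
cases, but needs only a few candidates per accepted case.  Everything is
deterministic given the seed.

Realistic impurities are included deliberately — a small fraction of
prescriptions lack end dates (exercising the imputation path), events on
episode first days carry `before_treatment` flags, and patients carry
ADHD, substance-misuse, and post-event psychotropic records — so scenario
filters have something to bite on.

## Numerical choices

* All date arithmetic runs on integer day numbers with precomputed month
  tables (1900–2199); segmentation is fully vectorised over cohorts.
* The likelihood is evaluated with `rowsum()` aggregation per patient;
  no per-patient loops occur in the hot path.
* Report rendering is deterministic: fixed column layout, IRRs to two
  decimals, p-values below 0.01 printed as `<0.01`, en-dash confidence
  intervals; re-running a report yields byte-identical files.

## Scope and limitations

* One event per case (the incident event); recurrent-event SCCS is out of
  scope.
* The `other_psychotic` outcome group is empty by default and must be
  supplied via a user code map when a richer code list is available.
* The sample-size formula ignores age adjustment, as published.
* The simulator is a single-drug, single-outcome generator; it does not
  model co-prescribing or dose effects.
* Estimates from the motivating study's confidential records are not
  reproducible here; the package reproduces the *methods*, the printed
  sample-size result, and distributional properties verified by
  simulation.
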