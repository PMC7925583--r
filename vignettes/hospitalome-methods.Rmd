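---
title: "Models and methods behind hospitalome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hospitalome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hospitalome)
```

This vignette is the package's own account of its science: the data model,
the two estimators, the synthetic-data generator that makes them testable,
and the numerical and design choices behind each — including the ones that
were genuinely open and how we settled them.

## The data model

A cohort is a bundle of up to ten tables sharing `PatientID` / `SampleID`
keys on a **deidentified integer day axis**: every patient's events are
shifted by a secret per-patient reference date, so only day differences
carry meaning. The package never parses calendar dates. Convenience
columns (`DayRelativeToNearestHCT` and friends) re-anchor events to the
nearest transplant day; the loader recomputes them and reports
discrepancies. When a timepoint is exactly equidistant between two
transplants we anchor to the earlier one — an arbitrary but deterministic
convention, and flagged in the validation report because the deposited
column may have used the opposite one.

Drug courses are **closed intervals** `[StartTimepoint, StopTimepoint]`:
the stop day is a day of administration. Missing cells are nulls, never
zeros. Real-valued columns are serialized with a shortest round-trippable
decimal representation and parsed back with R's correctly rounded
`strtod`, so `load_cohort(write_cohort(c))` reproduces `c` bit for bit —
a property the test suite checks table by table.

Taxonomic confidence columns appear in deposits on either a 0–1 or a
0–100 scale; the loader auto-detects the scale and records it in the
cohort's provenance rather than rescaling silently.

## Antibiotic-impact inference

### Model

Let `N_k(t)` be the absolute abundance of taxon `k` (relative abundance
times the sample's total 16S load from qPCR, in copies per gram of
stool). We assume antibiotics act independently and additively on the
exponential growth rate:

$$\frac{d\,\log N_k(t)}{dt} = g_k + \sum_{j=1}^{M_a} \varepsilon_{k,j}\,u_j(t)$$

* `g_k` — growth rate off antibiotics (1/day). Typical gut commensals
  in this regime sit in the ±0.3/day range.
* `u_j(t)` — binary presence of drug group `j` on day `t`. No
  pharmacokinetics: a day on a drug is a day exposed, regardless of dose.
* `ε_{k,j}` — susceptibility (1/day); negative values suppress, positive
  values (competitor release) expand.

Integrating between two consecutive stool samples of a patient at days
`t_i < t_f` turns each pair into one regression row
`log N_k(t_f) − log N_k(t_i) = g_k Δt + Σ_j ε_{k,j} C_j`, with `C_j` the
number of exposed days in the window. Logs are **natural** throughout —
the integral form of the model forces that base.

### The exposure-day convention

Day-resolution data leave one genuine choice: does a drug active on the
pair's first sampled day count toward `C_j`? We count exposed days in the
**half-open window `(t_i, t_f]`**: the initial sample reflects abundance
before that day's subsequent doses, so day `t_i` does not contribute,
while the final day does. The synthetic generator uses the matching
discrete step — the Euler update into day `t` applies the exposure state
of day `t` — so the pair equation is exact on noiseless synthetic data.
This is the single convention in the package where simulator and
estimator must agree; both record it, and the forward/inverse acceptance
test would fail loudly if they ever drifted apart.

### Filters

* Pairs are **adjacent** samples of one patient in day-sorted order
  (never skipping over an intermediate sample), at most **3 days** apart
  — in dense inpatient series this is the smallest gap that still retains
  the majority of consecutive samples — and require qPCR at both ends.
* Rows where the taxon's absolute abundance is zero at either endpoint
  are discarded (log of zero; absence is not evidence about growth
  rates).
* Analysis is restricted to the top-`k` (default 20) taxa by **mean
  relative abundance over the pair samples**. The ranking statistic is
  configurable (`total_counts`, `prevalence`) because "most abundant" is
  ambiguous; mean relative abundance is the default as the least
  depth-confounded of the three.
* Drug selection: antibacterial classes only; atovaquone excluded;
  metronidazole and aztreonam promoted out of the miscellaneous class as
  their own single-drug groups; other miscellaneous drugs dropped;
  remaining drugs grouped by category.

### Ridge regression and cross-validation

Per taxon we solve the penalized least squares
`argmin ‖Y − DX‖² + λ‖X‖²` in closed form via the normal equations.
Two deliberate choices:

* **The intercept `g_k` is penalized by default**, because the objective
  we implement includes the full coefficient vector in the penalty.
  `penalize_intercept = FALSE` restores the conventional unpenalized
  intercept; on day-scaled covariates the difference is small at the
  cross-validated λ.
* **Columns are not standardized.** The solver operates on the raw
  `[Δt, C_1..C_Ma]` design exactly as the objective is written. This
  keeps the λ → 0 limit an exact interpolator of consistent systems
  (which the identifiability test exploits) and keeps coefficients in
  interpretable 1/day units end to end. The default grid — 25 points
  log-spaced over `[1e−4, 1e4]` — spans under- to over-shrinkage for
  day-scaled covariates, which all lie in `0..Δt ≤ 3`; standardizing
  would only relabel the grid.

λ is chosen to minimize held-out sum-of-squared error under 3-fold
cross-validation repeated over 10 random partitions (seeded,
reproducible). Partitions are over **rows (pairs)** by default, matching
the row-wise objective; `group_by_patient = TRUE` offers patient-level
splitting for users worried about within-patient leakage. With equal fold
sizes the argmin is invariant to summing versus averaging fold errors; we
sum.

### Routes

Oral and intravenous administrations of the same drug are distinct
covariates. The package's default fits **one joint design with a
(group, route) covariate pair per column** rather than two fully separate
per-route regressions: when both routes are active in the same windows, a
per-route regression omits the other route's exposures and inherits their
confounding. The per-route presentation (and the fully separate fit, via
`routes = "oral"` / `"intravenous"`) remains available; on the synthetic
benchmark, where each drug group has a single fixed route, the two
approaches coincide.

## Domination and bloodstream-infection risk

**Domination** is a genus-level relative abundance **strictly above** a
threshold (30% classically; the sweep also fits 10%, 1%, 0.1%). Strict
inequality follows the standard definition of exceeding the threshold;
at exactly 30.000% a sample is not dominated.

Follow-up runs from day −15 to day +35 around the transplant, in
counting-process form `(start, stop, covariate, event)`:

* The domination covariate starts at 0 and switches to 1 at the **end of
  the first dominated sample's day** — it is **absorbing** (never reverts
  if the abundance later drops), encoding "has ever been dominated".
* Events are **genus-matched** positive blood cultures: an Enterococcus
  BSI is not an event in the Escherichia analysis (that patient is simply
  censored at the window end).
* Patients whose matching infection precedes entry are excluded; patients
  without any stool sample in the window contribute covariate-0 follow-up
  (absence of evidence is treated as no domination) and are flagged.
* The tables carry no death or discharge record, so follow-up is censored
  at the window end; this is documented rather than imputed.
* Patients with multiple transplants contribute one observation per
  transplant window, with any window overlapping a previous one truncated
  so no patient-day is counted twice.

The hazard-ratio fit maximizes the Cox partial likelihood over these rows
with the **Efron tie correction** (many same-day events are expected on
an integer day axis; Breslow is available). Degenerate inputs are refused
with informative errors rather than divergent estimates: no events, a
constant covariate, or all events in one covariate stratum (monotone
likelihood). Threshold sweeps report per-threshold failures in a `note`
column and are **not multiplicity-adjusted** — the sweep is descriptive,
and the output says so.

## The synthetic cohort generator

`generate_cohort()` emits all tables of the data model, internally
consistent, from the forward model above, plus the ground truth that
produced them. What it emulates:

* one transplant per patient at relative day 0 (multi-HCT optional), with
  random per-patient deidentified anchors so nothing downstream can rely
  on absolute timepoints;
* stool sampling every 1–4 days over days −15..+35;
* negative-binomial sequencing depth (mean 5×10⁴, dispersion 10) with
  multinomial read sampling; a latent-abundance extinction floor (1 copy)
  below which a taxon is recorded as absent, exercising the zero-discard
  rule;
* qPCR total load with 0.1 log10 multiplicative noise, covering 85% of
  samples — qPCR panels rarely cover a whole deposit, and partial
  coverage keeps the qPCR pair filter honest while retaining enough pairs
  for the inference demo;
* Poisson drug courses (2 antibacterial courses per patient on average,
  geometric durations of mean 5 days) across 4 drug classes, each class
  administered by one fixed route, plus decoy courses (atovaquone, an
  antiviral, a non-anti-infective) that the selection rules must remove;
* daily process noise of 0.2 on the natural-log scale (multiplicative on
  abundance, consistent with the log-linear model);
* growth rates `g ~ N(0.1, 0.15)` per day; susceptibilities zero with
  probability one half, otherwise random sign and magnitude
  `U(0.25, 0.75)` per day — strong, clean effects in the range antibiotic
  perturbations produce;
* genus-matched BSI events via a daily discrete hazard
  `h₀ · exp(β·dominated)` with `β = log 4` and `h₀ = 0.002`/day, the
  domination indicator taken from the *observed* samples (absorbing, at
  the 30% threshold), vitals with fevers and a post-transplant neutrophil
  nadir, and vanA calls.

Setting `read_depth_mean = Inf` records latent abundances as exact
real-valued pseudo-counts — the infinite-depth observation mode used by
the exactness tests (deposited data always have integer counts; the
validator reports non-integer counts whenever this mode's output is
validated as if it were real data).

What it does **not** emulate: realistic taxon identities or marginal
abundance distributions beyond orders of magnitude, strain-level
structure, correlated antibiotic prescribing in response to the
microbiota (exposures are exogenous here, which is exactly why recovery
can be exact), loss to follow-up, or death as a competing risk. Passing
tests therefore demonstrate estimator correctness under the model's own
assumptions — not robustness to their violation in real hospital data.

## Problem sizes and what the checks show

The package's own acceptance analyses (also run by
`scripts/acceptance.R`) use: a 50-patient noiseless cohort for the exact
forward/inverse check (max absolute recovery error below 10⁻⁶ at
λ = 10⁻⁶); a 300-patient cohort at the default noise levels for noisy
recovery (elementwise correlation between inferred and true
susceptibilities above 0.8 and at least 80% sign agreement — in practice
both land near 0.99 and 100%); 100 replicate survival simulations of 300
patients at a true hazard ratio of 4 for Wald-CI coverage (≥ 90/100
expected at nominal 95%); and a 300-patient end-to-end domination
analysis at the 30% threshold. These sizes give stable Monte-Carlo
behaviour at interactive runtimes; all randomness flows from a single
seed argument.

## Known limitations

* The growth model is sensitive only to **transient** expansions: a taxon
  that expands and then plateaus while the drug continues averages to a
  near-zero estimated effect. Capturing sustained dominations needs
  carrying capacities and interactions — a deliberately excluded richer
  model class.
* Binary exposure ignores dose and pharmacokinetics.
* The Cox analysis fits a single binary covariate; no adjustment for
  immune status or other time-varying confounders, no competing risks,
  no frailty.
* Ridge shrinkage biases small effects toward zero; the cross-validated λ
  trades that bias for variance and is reported per taxon so users can
  judge.
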