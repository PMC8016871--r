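---
title: "Model structure, conventions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, conventions and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxcea)
```

`pgxcea` re-implements, as tested and scriptable code, a published
decision-analytic evaluation of CYP2C19 genotype-guided antiplatelet
therapy after acute minor stroke or high-risk TIA in China. This vignette
is the package's own account of the model: its structure and assumptions,
the parameters that matter, the conventions we had to fix where the source
analysis left them open, how the one unpublished input (the age-specific
mortality table) is reconstructed by calibration, and the points where the
re-implementation is known to disagree with the published numbers.

## Model structure

**90-day decision tree.** All patients enter with minor or no disability
(mRS 0–2). The tested arm is split into three genotype/risk subgroups —
loss-of-function-allele (LoFA) noncarriers (proportion 0.41, clopidogrel-
aspirin), carriers with ESRS ≥ 3 (0.22, clopidogrel-aspirin) and carriers
with ESRS < 3 (0.37, switched to dipyridamole-aspirin); the untested arm is
a single pooled group on clopidogrel-aspirin. The published 90-day outcome
distributions over the four mRS states are first-class inputs
(`p90_*` parameters); a secondary "derived" mode reconstructs them from
subgroup recurrence risks and a disability-rate adjustment, and is used
only as a cross-check (see *Derivations* below).

**Markov cohort model.** The 90-day distribution seeds 30 annual cycles
over four states: mRS 0–2, mRS 3–4, mRS 5, death (absorbing). Per cycle
and alive state, competing risks are composed as mutually exclusive
branches in a fixed order, each applied to the residual mass of the
previous: recurrent stroke → major extracranial hemorrhage (ECH) →
myocardial infarction (MI) → non-stroke death. The source figure's chance-
node layout implies exactly this branch-tree style; the order itself is
our choice and matters only at second order (branch products are small).
Recurrence survivors are reallocated equally among the disability states of
equal and greater severity (from mRS 0–2: thirds to mRS 0–2/3–4/5; from
mRS 3–4: halves to mRS 3–4/5; mRS 5 stays). Recurrence grows by the factor
1.017 per year from the annual base 0.1219; if the product ever exceeded
the available branch mass it would be capped with a warning (it never does
over 30 cycles at the published ranges).

## Key parameters

All values are 2019 CNY, annual probabilities, or utilities; every
parameter carries a `low`/`high` sensitivity range and a distribution tag
(`parameter_table(default_parameters())` prints the full table). The
consequential ones:

* **Costs.** One-time hospitalization per event by resulting mRS band
  (ischemic 12,499.91 / 18,700.45; ICH 14,086.15 / 18,700.45; ECH 9,125.97;
  MI 21,276.20); annual care 8,767.42 (mRS 0–2) and 13,850.50 (mRS 3–5);
  90-day drug prices 490.45 (clopidogrel-aspirin) and 504
  (dipyridamole-aspirin); genotyping assay 1,076.5. The published cost
  table prints two identical-looking ICH mRS 0–2 rows; we read the second
  (18,700.45) as the ICH mRS 3–6 band, by symmetry with the ischemic rows.
* **Utilities.** 0.75 / 0.39 / 0.20 / 0 by state; temporary episode
  utilities 0.80 (ECH, 2 weeks) and 0.84 (MI, 30 days).
* **Long-term probabilities.** Annual recurrence 0.1219 (growth 1.017/yr),
  case fatality 0.1933, ICH share 0.075; ECH 0.0038 (fatality 0.06); MI
  0.0085 (fatality 0.15); age-specific non-stroke death within
  0.0089–0.1654.
* **Discounting.** 3 %/yr for costs and outcomes; the one-way analysis
  varies the cost rate over 0.03–0.08 and the outcome rate ±20 %.

## Derivations in the 90-day tree

Three small closed forms are exposed as functions because the source
analysis derives its inputs with them:

* `proportion_within_90d(0.083, 0.103)` = 0.806 — the share of first-year
  recurrences that fall within 90 days on clopidogrel-aspirin.
* `apply_hazard_ratio(0.0932, 0.78)` = 0.0727 — hazard ratios are applied
  multiplicatively on the 90-day probability scale; the source's own
  arithmetic confirms that convention.
* `adjusted_disability_rate(A, B, C)` — the published formula
  `A*(B − C)/B*(1 − C)` is typographically ambiguous. The default
  left-to-right reading `(A·(B−C)/B)·(1−C)` is used; the alternative
  `A·((B−C)/B)/(1−C)` is selectable via `policy = "ratio"`. Neither
  reading reproduces the published tested-arm 90-day distribution from the
  published inputs, which is why derived mode is a secondary pathway and
  the printed distributions are primary.

## Conventions fixed by this implementation

* **Reward accrual.** Costs and QALYs accrue on *end-of-cycle* occupancy,
  discounted by `(1+r)^{-t}` for cycle `t = 1…30`; in the zero-event limit
  the discounted QALY total equals the annuity `Σ u·(1+r)^{-t}` exactly
  (tested to 1e-9). Half-cycle correction (mean of start and end occupancy)
  is available but off by default, matching the common practice of the
  modelling software family the source analysis used.
* **90-day accounting.** The 90-day block is booked at time zero
  undiscounted (it is shorter than one cycle); the Markov seed keeps the
  90-day dead mass in the absorbing state, so totals are per patient
  entering the pathway.
* **Recurrence costing.** The share of 90-day recurrences ending in
  mRS 3–6 is inferred from the arm's 90-day distribution
  (`(1 − p_minor)/recurrence`), since MI and ECH cannot change disability
  in this model; in the Markov phase, survivors redistributed to mRS 0–2
  are costed at the mRS 0–2 hospitalization price, all other recurrences
  (including fatal) at the mRS 3–6 price.
* **Temporary-state disutility** is multiplicative
  (`duration · u_state · (1 − u_episode)`): replacing the state utility by
  the episode utility outright would *raise* utility for mRS 0–2 patients
  (0.80 > 0.75), contradicting a disutility.
* **Annual care costs** apply to every alive patient by band from cycle 1.
  Restricting them to post-recurrence patients would roughly halve lifetime
  costs and is incompatible with the published per-arm totals
  (≈ CNY 123k).
* **Renormalization of the 90-day distribution.** When a minor/no-
  disability proportion `p90_minor_*` is overridden (one-way analysis) or
  sampled (PSA), the 90-day death proportion is held at its own parameter
  value and only the moderate/severe split is rescaled. Letting the
  override bleed into mortality makes the incremental QALY cross zero for
  small changes in a *disability* input and the ICER degenerate — an
  artifact, not a sensitivity. This is deliberately different from
  renormalizing all three residual states proportionally.
* **PSA distributions.** Triangular over `(low, base, high)` for every
  class of parameter (truncated to [0,1] where applicable): the published
  description of its distribution choices is garbled beyond recovery, and
  the triangular is the only distribution fully determined by the printed
  triples. Tags are per-parameter (`dist:` in the config) so alternatives
  can be explored. Discount rates are not sampled. Parameters are drawn
  independently; no correlation structure was published.
* **Subgroup split.** Only the 0.37 share of low-risk carriers is
  published; the remaining 0.63 is split 0.41/0.22
  (noncarrier/high-risk carrier), approximating the ~59 % carrier
  prevalence of the underlying trial population. Because the printed
  pooled 90-day distributions drive the base case, this split affects only
  the 90-day drug/event cost mix (weakly).
* **90-day risks without printed ranges** (the subgroup recurrence risks,
  ICH share, ECH and MI risks) get ±20 % triangular ranges — the source's
  own stated default for parameters lacking literature ranges. The
  untested arm's 90-day minor proportion, which likewise has no printed
  range, gets the same absolute half-width (±0.011) as the published
  tested-arm range 0.939–0.961.

## The mortality schedule: generation and calibration

Only the envelope of the age-specific non-stroke death rates is published
(0.0089 to 0.1654 per year); the underlying per-age table is not. The
generator (`generate_schedule()`) interpolates log-linearly between the
endpoints across the 30 cycles from start age 62 — adult all-cause
mortality grows approximately exponentially with age — with a linear shape
available for comparison. The start age (not published) is typical of the
underlying trial cohort and is exposed in the structural settings; the
acceptance-relevant results are not knife-edge in it.

The one remaining degree of freedom is pinned by `calibrate_schedule()`: a
scalar multiplier on the envelope schedule (rates clamped back into the
envelope) chosen by one-dimensional minimization of the summed squared
relative error of the model's per-arm discounted QALY totals against the
published per-arm totals (5.1450 / 5.1140). Costs are deliberately not
targeted — once occupancy is right they follow — but both residuals are
reported. At defaults the search converges to scale 2.309; the shipped
fixture `extdata/mortality_schedule.csv` is exactly this output (a
regression test recalibrates and compares). QALY residuals are ±0.013 %;
cost residuals +4.2/+4.3 % per arm. A self-consistency test generates
anchors from a known schedule and recovers its scale within 1 %.

That the calibrated scale is ≈2.3 (i.e., mortality well above the raw
envelope interpolation) says the published model reaches its QALY totals
through a heavier effective mortality than the envelope alone suggests;
with the envelope untouched (scale 1) the model yields ≈5.96 discounted
QALYs per arm.

## Validation oracle

`run_microsim()` pushes individuals through *identical* event logic —
same branch order, redistribution rule, rewards and discounting — so its
means must agree with the cohort engine up to Monte-Carlo error. The test
suite checks both arms at n = 200,000 within 3 standard errors for the
default parameters and for 20 randomized parameter sets, alongside
property tests: mass conservation each cycle (1e-9), monotone cumulative
death, discounting monotonicity, NMB/ICER equivalence on the QALY-gaining
half-plane, and the zero-event annuity limit. Problem sizes (30 cycles,
10,000 PSA iterations, 200,000 simulated individuals) are the package's
standard analysis sizes.

What passing these tests shows: the cohort algebra, reward bookkeeping and
sampling machinery are internally correct and mutually consistent. What
they do not show: that the synthetic mortality schedule, the independence
assumptions or the triangular ranges describe any real cohort — the
generator emulates the published study's *conditions*, not patient-level
reality.

## Known disagreements with the published numbers

The re-implementation reproduces the published incremental QALYs (0.0297
vs 0.031, well within ±0.01) and both per-arm totals to within ~4 % after
calibration, but not every published summary statistic:

* **Incremental cost / ICER.** We obtain ΔC ≈ CNY 588 (published 420.13)
  and ICER ≈ 19.8k (published 13.55k). The 90-day arm difference is pinned
  by printed prices (assay 1,076.5 + drug mix 5.0 − event-cost savings
  ≈ 162 ⇒ +920); reaching ΔC = 420 needs ≈ CNY 500 of long-term savings,
  while the published transition structure can generate only ≈ 330 — the
  tested arm's disability advantage erodes as its extra mRS 0–2 survivors
  feed recurrence-driven redistribution.
* **One-way excursions for the mRS 3–5 annual cost.** In any model of this
  class the ICER is *linear* in a cost parameter, with slope proportional
  to the between-arm difference in discounted disabled person-years. The
  three published values for this parameter (4,961.67 at the low bound,
  13,552.74 at base, 33,439.13 at the high bound) are not collinear — the
  implied slope below base is +0.88 per CNY and above base +4.72 — so no
  internally consistent model can reproduce all three. Both published
  slopes are moreover *positive*, implying the tested arm accrues more
  disabled person-years, whereas the published 90-day distributions force
  the opposite sign (≈ −0.068 discounted years here): our excursions run
  in the opposite direction (≈ 42k at the low bound, ≈ 10k at the high).
* **The 0.939 excursion** of the tested arm's 90-day minor proportion
  yields ≈ 355k here versus the published 109.5k, for the same underlying
  reason: the published incremental cost appears insensitive to the
  90-day seed gap in a way this structure cannot produce.
* **PSA fractions.** P(ΔQALY > 0) ≈ 97.5 % matches the published 96.94 %;
  P(cost-effective at 72,100) ≈ 88–89 % (published 95.71 %) and
  P(dominant) ≈ 5.7 % (published 2.59 %) inherit the ΔC offset and our
  wider sampled cost uncertainty.

These residuals are documented rather than tuned away: every input above
is a published value, the calibration targets only the per-arm QALY
anchors, and the acceptance script reports whatever the model computes.

## Limitations

No tunnel states beyond the two temporary events; no state-dependent
mortality multipliers; utilities and care costs constant over age;
parameters sampled independently; two strategies only; all monetary values
fixed at 2019 CNY with no currency or inflation handling. The genotyping
assay is treated as perfectly accurate: the tree has no misclassification
branch, consistent with the source model.
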