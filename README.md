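# pgxcea

Cost-effectiveness modelling of CYP2C19 genotype-guided antiplatelet therapy
after acute minor stroke or high-risk transient ischemic attack (TIA).

## The problem

Dual antiplatelet therapy (clopidogrel + aspirin) within 48 h of a minor
stroke or high-risk TIA reduces 90-day stroke recurrence, but clopidogrel is
a prodrug activated by CYP2C19. Carriers of loss-of-function alleles (LoFA)
with a low Essen Stroke Risk Score (ESRS < 3) gain nothing from clopidogrel
and face additional bleeding risk; for them, dipyridamole + aspirin is the
guideline alternative. Genotyping every patient costs money up front
(CNY 1,076.5 per test in the 2019 Chinese setting modelled here) and pays
off — if at all — through fewer recurrent strokes and less long-term
disability. `pgxcea` implements the full decision-analytic pipeline that
weighs this trade-off from a healthcare-payer perspective, for health
economists and methodologists who want a tested, scriptable, reproducible
version of this class of model.

## The model

A **90-day decision tree** assigns therapy by strategy arm:

* *genetic testing*: LoFA noncarriers (41%) and high-risk carriers (22%)
  receive clopidogrel-aspirin; low-risk carriers (37%) are switched to
  dipyridamole-aspirin;
* *no testing*: everyone receives clopidogrel-aspirin.

Each arm accrues the testing cost, 90-day drug costs, and expected
hospitalization costs for recurrent stroke (ischemic/ICH, by resulting
modified-Rankin band), major extracranial hemorrhage (ECH) and myocardial
infarction (MI), and emits a 90-day distribution over four mRS-based health
states: minor/no disability (mRS 0–2), moderate (mRS 3–4), severe (mRS 5),
death.

That distribution seeds a **30-cycle annual Markov cohort model**. Each
cycle, every alive state faces — as mutually exclusive branches, in order,
each on the residual mass of the previous — recurrent stroke (case fatality
0.1933; survivors reallocated equally among states of equal and greater
disability), major ECH, MI, and age-specific non-stroke death. The annual
recurrence probability grows by a factor 1.017 per year from 0.1219.
Survivors accrue state utilities (0.75 / 0.39 / 0.20 / 0) and annual care
costs by band; ECH and MI are temporary states with 2-week and 30-day
multiplicative disutilities. Costs and outcomes are discounted at 3 % per
year.

Strategies are compared by the incremental cost-effectiveness ratio

ICER = ΔC / ΔE = (C_testing − C_no-testing) / (E_testing − E_no-testing),

in CNY per quality-adjusted life-year (QALY), judged against the
willingness-to-pay thresholds CNY 72,100 (1× 2019 per-capita GDP) and
CNY 216,000 (≈3× GDP). Uncertainty is propagated by deterministic one-way
sensitivity analysis (tornado) and by probabilistic sensitivity analysis
(PSA; 10,000 Monte-Carlo draws, triangular distributions over every
published parameter range) summarised as a cost-effectiveness plane and
acceptability curve (CEAC).

Because the published age-specific non-stroke mortality table is not
available (only its envelope 0.0089–0.1654 per year), the package ships a
log-linear schedule calibrated by a one-dimensional scale search against the
published per-arm lifetime QALY totals (see `calibrate_schedule()` and the
methods vignette). An individual-level microsimulation (`run_microsim()`)
with identical event logic serves as an independent validation oracle for
the cohort engine.

## Worked example

```r
library(pgxcea)

ps    <- default_parameters()   # full published parameter set + ranges
sched <- default_schedule()     # shipped calibrated mortality schedule

run_base_case(ps, sched)
#> Incremental cost-effectiveness result
#>   genetic_testing    cost    129197.28 CNY     5.1444 QALYs
#>   no_testing         cost    128608.90 CNY     5.1146 QALYs
#>   incremental        cost       588.38 CNY     0.0297 QALYs
#>   ICER 19807.68 CNY/QALY (highly_cost_effective)
```

Genotype-guided therapy gains 0.0297 QALYs per patient for an extra
CNY 588.38 — about CNY 19,808 per QALY, far below the CNY 72,100 threshold,
so testing is classified highly cost-effective. One-way and probabilistic
sensitivity:

```r
ow <- run_owsa(ps, sched)       # tornado, every non-fixed parameter
head(as.data.frame(ow), 3)

psa <- run_psa(ps, n = 10000, seed = 1, schedule = sched)
psa
#> <psa_result> 10000 iterations (seed 1)
#>   P(QALY gain)                 0.9753
#>   P(cost-effective @ 72,100)   0.8841
#>   P(dominant)                  0.0567
ceac(psa)                       # acceptability curve over WTP 0–250k
```

Report writers (`write_base_case()`, `write_owsa()`, `write_psa()`) emit
CSV/JSON bundles with a run manifest; `inst/scripts/pgxcea` wraps them as
shell subcommands (`basecase | owsa | psa | microsim | calibrate`).

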