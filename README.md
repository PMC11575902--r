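# afburden

Change-from-baseline analysis of atrial fibrillation (AF) burden from
insertable cardiac monitors (ICMs), for biostatisticians and device
researchers studying near-term cardiovascular hospitalization (CVH) risk.

ICMs report one diagnostic summary per day — total AT/AF burden, longest
continuous episode, patient activity, day/night ventricular rate,
heart-rate variability. A fixed population-level burden cutoff ignores
that the amount of AF that signals danger depends on the patient's own
baseline. `afburden` scores every follow-up day against that baseline and
validates the resulting *trend states* as day-level risk markers.

## The model

For daily values `d_1, d_2, …` (day 1 = day after implant) the engine
tracks the cumulative moving average (the historical baseline)

    CMA(t) = (1/t) · Σ_{i=1..t} d_i

and simple moving averages over clinical windows p ∈ {1, 2, 3, 5, 8, 13,
21} days

    SMA_p(t) = (1/p) · Σ_{i=t-p+1..t} d_i.

From the index day (day 22, when every window is defined) each day is in
exactly one trend state:

| State | Definition | Reading |
|---|---|---|
| A | burden CMA < 1% of the day (14.4 min) | sinus baseline (reference) |
| B | SMA₂₁ < CMA | below-average burden |
| C | SMA₂₁ ≥ CMA | at/above-average burden |
| D | C, and burden CMA > 8.5 min/day, activity CMA < 87 min/day | above-average burden with declining activity |

Two prespecified clinical comparators are flagged per day: *duration*
(a continuous episode ≥ 1 h) and *quantity* (total AT/AF ≥ 72 min = 5% of
the day). Validation statistics include per-state incidence-rate ratios
versus trend A with log-Wald CIs, day-level AUROC (Hanley–McNeil CI),
pooled equal-proportion tests, Poisson rate comparison, and the Venn
event-yield of trend-exclusive detections.

Because the linked claims/device data behind this kind of study cannot be
shared, the package includes a synthetic cohort generator
(`simulate_cohort()`) with hazard-linked events — the per-day CVH hazard
is the baseline hazard times a per-state multiplier — plus ground truth
for parameter-recovery studies, and a discovery module
(`train_bootstrap_forest()`, `extract_rules()`, `match_to_comparators()`)
that re-derives the trend-D rule from bootstrapped classification trees.

## Worked example

```r
library(afburden)

cfg    <- simulation_config(n_patients = 400, seed = 2024)
sim    <- simulate_cohort(cfg)
inc    <- apply_inclusion(sim$cohort)   # cohort rules + 2-year truncation
cohort <- forward_fill(inc$cohort)      # impute follow-up gaps
report <- evaluate_holdout(cohort)      # states, RRs, AUROC, yield
print(report)
```

```
Holdout validation: 398 patients, 159920 classified days, 273 events
  trend A:  82755 days,   38 events, RR 1 (reference)
  trend B:  40860 days,   75 events, RR 4.00 [2.71-5.91]
  trend C:  19379 days,   76 events, RR 8.54 [5.79-12.61]
  trend D:  16926 days,   84 events, RR 10.81 [7.37-15.85]
  AUROC 0.540 -> 0.603 with trend criterion (+11.6% relative)
  trend-exclusive events: 27 (+19.0% over clinical criteria)
```

Two of the 400 simulated patients were excluded (no device-detected AF on
or after the index day). The rate ratios recover the generator's
multipliers (here the defaults 4.49 / 8.41 / 11.15) within their 95%
intervals; the risk ordering A < B < C < D, the AUROC gain from adding
the trend criterion, and the extra events captured only by the trend are
the quantities the method is about.

`run_pipeline()` chains the full analysis — simulate → preprocess →
trends → rule discovery on a 70% patient split → holdout validation —
writing delimited-text artifacts, a JSON report, and a manifest with the
seed and config hash. A thin command-line wrapper with the matching
subcommands ships in `inst/cli/afburden.R`.

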