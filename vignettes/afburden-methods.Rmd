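---
title: "Burden trends from daily ICM diagnostics: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burden trends from daily ICM diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afburden)
```

## The problem

Insertable cardiac monitors (ICMs) report one diagnostic summary per day:
total AT/AF burden, longest continuous AF episode, patient activity
minutes, day and night ventricular rates, and heart-rate variability.
Population-level rules of thumb — "more AF burden means more risk" — ignore
that the burden amount that signals danger differs between a patient whose
baseline is 2 minutes a day and one whose baseline is 6 hours. `afburden`
implements a change-from-baseline analysis of these series: every day is
scored against the patient's own history, and the resulting trend states
are validated as predictors of near-term cardiovascular hospitalization
(CVH).

## Moving averages and trend states

For a daily series $d_1, d_2, \dots$ (day 1 is the day after implant), the
engine computes the cumulative moving average

$$\mathrm{CMA}(t) = \frac{1}{t}\sum_{i=1}^{t} d_i,$$

the patient's historical baseline, and simple moving averages

$$\mathrm{SMA}_p(t) = \frac{1}{p}\sum_{i=t-p+1}^{t} d_i$$

over clinical windows $p \in \{1, 2, 3, 5, 8, 13, 21\}$ days. The index
day — the first day eligible for classification — is day 22, the day after
the 21-day initialization window; from then on every window is defined.
"21 days after implantation" does not by itself say whether day 21 is
inside or outside the window; we take eligibility to start the day after
day 21 and state that choice here once.

Each classified day lands in exactly one trend state:

* **A** — sinus: burden CMA below 1% of the day (14.4 min/day by default;
  the percentage is what is specified, so the minute value is
  configurable);
* **B** — below-average burden: $\mathrm{SMA}_{21}$ strictly below the CMA;
* **C** — at-or-above-average burden: $\mathrm{SMA}_{21} \ge$ CMA (ties are
  read as "at or above", so a saturated persistent series is C, not B);
* **D** — the high-risk refinement of C: burden CMA above 8.5 min/day and
  activity CMA below 87 min/day (above-average burden with declining
  patient activity).

Because state A already requires the burden CMA to be below 14.4 min/day,
the 8.5 min/day floor in D can never be the binding condition under the
default thresholds. Both numbers are kept explicit and configurable rather
than simplified away, since either can be changed independently.

Two prespecified clinical comparators are evaluated per day: the
*duration* threshold (longest continuous episode at least 60 minutes,
regardless of when the episode started — an episode spanning midnight
flags both days) and the *quantity* threshold (total daily AF at least 72
minutes, i.e. 5% of the day).

A note on a perturbation property the test-suite checks: raising the
classified day's *own* burden can only move that day's state away from A
(toward C), because the day contributes $\delta/21$ to
$\mathrm{SMA}_{21}$ but only $\delta/t \le \delta/21$ to the CMA. The same
is not true of raising a day that has already left the 21-day window —
that inflates the CMA alone and can legitimately flip a later day from C
to B. The property test therefore perturbs the classified day itself.

## The synthetic cohort generator

The real linked claims/device data behind this style of analysis is not
shareable, so the package ships a generator whose outputs play the role of
a study cohort, with known ground truth for parameter recovery. Its
defaults are the package's study conditions; they were calibrated once
against the descriptive statistics such cohorts report and are not tuned
per analysis.

* **Phenotypes.** 6% of patients are *persistent*: after an onset day,
  every day carries at least 23.5 h of AF, so the series always contains
  the 7-consecutive-day run that defines the device-based persistent
  phenotype. The rest are *paroxysmal*.
* **Paroxysmal burden.** A day has an episode with probability
  $\mathrm{logit}^{-1}(b_0 + z_t)$, where $b_0$ is a patient-level
  intercept (SD 1.5 around $\mathrm{logit}(0.3)$ — most days are sinus for
  most patients, a heavy right skew) and $z_t$ is an AR(1) process
  ($\rho = 0.95$, stationary SD 1) whose weeks-long excursions are what
  make SMA/CMA crossovers informative. Episode-day amounts are log-normal
  (median 40 min, log-SD 0.9), floored at the 2-minute device detection
  limit; on a fragmented day (probability 0.5) the longest continuous
  episode is a uniform 45–90% fraction of the total. An optional
  patient-level amount-scale SD (`amount_scale_log_sd`) reproduces the
  order-of-magnitude overdispersion of real cohorts; it defaults to 0,
  which keeps planted trend-state signals cleanly attributable in
  discovery studies.
* **Activity.** Gaussian daily activity (mean 95 min/day, SD 30, clipped
  to the physical range), with a 55% subcohort declining linearly at 0.8
  min/day/day — the substrate for trend D.
* **Events.** Every classified day $t$ carries a CVH probability
  $h \cdot m_{s(t)}$, where $h$ is the baseline (state-A) hazard and
  $m_s$ the per-state multiplier ($m_A \equiv 1$; defaults are the
  published trend-state rate ratios 4.49/8.41/11.15). The draw on day $t$
  produces the event on day $t+1$ and follow-up ends with day $t$: the
  state of the last record day is the state that carried the hazard. This
  timing makes day-level estimation — attribute each event to its last
  record day, divide per-state events by per-state days — exactly match
  the generating mechanism, which is what the recovery studies require.
  A consequence worth stating: with a hazard of 1, every patient's event
  lands on the first at-risk day after the index, not on day 1.
* **Truncation and gaps.** Follow-up is capped at 730 days; an event drawn
  beyond the cap is censoring. Gaps start with per-day probability
  3×10⁻⁴ and last $1 + \mathrm{Poisson}(6.4)$ days (mean 7.4).

At the defaults, 1000-patient cohorts land near the descriptives such
studies print: roughly three quarters of patients have a CVH within two
years, mean daily burden is a few tens of minutes with an SD several times
larger, trend A dominates the day count, and trend-D days are slightly
more prevalent than quantity-threshold days. What the generator does *not*
emulate: comorbidity structure, administrative censoring (censored
patients run to day 730), seasonal or circadian structure, inappropriate
device detections, and any dependence of the hazard on anything but the
trend state. Passing recovery tests therefore show the estimators are
consistent for this mechanism — not that real CVH risk follows it.

## Preprocessing

Inclusion mirrors the cohort definition: at least one observed day with
burden above zero on or after the index day; exclusion for any gap in
daily follow-up of 30 days or more (measured on the raw records, before
imputation); follow-up truncated at two years; records of event patients
truncated to the day before the event; only the first CVH counts. Events
after day 730 are recorded as censoring and flagged
(`post_truncation_event`) rather than dropped silently. Gaps inside the
retained span are forward-filled with the last known value per channel;
imputed days keep `observed = FALSE` and never count as device-detected
AF. Each excluded patient is logged with exactly one primary reason,
checked in the order no-AF-day, then gap.

## Rule discovery

The discovery module reproduces how the high-risk trend is derived:

1. label the 5 days preceding each CVH as positive;
2. split patients 70/30 into training and holdout;
3. per parameter, build the day-level feature row — CMA, the seven SMAs,
   and all 28 pairwise "shorter window at or above longer" indicators;
4. fit bootstrapped CART trees (default 200 replicates of a random 70%
   patient partition each); positives are weighted inversely to
   prevalence, since pre-event days are well under 1% of rows;
5. turn every positive-majority leaf into a conjunction of threshold
   conditions; merge conjunctions across trees; score each rule's
   log incidence-rate ratio against trend-A days and its prevalence;
6. match against the clinical comparators: walk rules by selection
   frequency and return the first whose log RR and prevalence strictly
   exceed the quantity threshold's values on the same training days;
7. freeze the matched rule's CMA bounds into the trend configuration
   before touching the holdout.

Three design choices here deserve their rationale:

* **Structural rule merging.** CART split points on continuous columns
  drift by several percent between bootstrap replicates, so merging rules
  at a tight numeric tolerance leaves almost every rule unique and makes
  "selection frequency" a lottery. Rules are instead identified by their
  *structure* — which columns they bound and in which direction — and the
  thresholds of merged instances are summarized by their median. This is
  also how such rules are reported clinically: one structural rule, one
  set of representative thresholds.
* **Relative-feature preference.** The premise of the method is
  change-from-baseline risk, and a rule built from within-patient
  comparisons transfers across patients whose absolute burden scales
  differ by orders of magnitude. Tree induction therefore applies a split
  cost of 2 to raw value columns relative to the binary trend indicators:
  an absolute-level split must improve the fit twice as much as a
  relative comparison to be chosen. Set `value_split_cost = 1` to
  disable. Without the preference, splits on absolute levels that
  approximate "almost crossed" days — which the 5-day labeling window
  rewards — displace the crossover condition from the matched rule in a
  substantial fraction of planted-signal replicates.
* **Prevalence statistic for matching.** The comparator floors pair a log
  RR with a prevalence. The day-share reading (fraction of classified
  days selected) is the one under which a selected trend can sit below a
  comparator's patient percentage while still being a coherent match, so
  matching uses day shares by default; patient shares are computed and
  reported alongside, and `prevalence = "patients"` switches the floor.

Tree depth (4), minimum leaf size (50 days), and the complexity parameter
(0.005) keep the rules at the granularity of a clinical table — two to
four conditions.

## Validation statistics

* **Rate ratios.** Day-level exposure accounting: each classified day
  contributes one day at risk to its state; an event counts on its last
  record day. CIs are log-Wald, $\exp(\log\mathrm{RR} \pm 1.96
  \sqrt{1/a + 1/c})$; the CI method is a package choice, as is the
  window-attributed tally reported alongside (an event credited to every
  criterion met during its 5-day pre-event window), which is the
  attribution used for incidence rates, event yield, and AUROC labels.
* **AUROC.** The day score is the number of criteria met (0–2 for
  duration+quantity, 0–3 adding the trend criterion); the AUROC is the
  rank statistic with ties at one half, and its CI uses the Hanley–McNeil
  variance — deterministic, unlike a bootstrap, which matters for
  reproducible reports.
* **Equal proportions.** A plain pooled two-sided z-test (its square is
  the uncorrected chi-square statistic). With degenerate pooled
  proportions the test reports $p = 1$.
* **Event yield.** Each captured event is assigned to the subset of
  criteria met in its pre-event window; the Venn regions partition the
  captured events, and the headline figure is the percent increase that
  trend-exclusive events add over events captured by the clinical
  criteria.
* **Poisson rate comparison.** A log-linear rate model with criterion
  indicators and a log person-days offset, fitted by IRLS (`glm`), with
  Wald tests of pairwise coefficient equality; for a saturated
  single-factor model the coefficients and variances have the familiar
  closed forms, which the tests exploit as oracles.

## Numerical and degenerate-input conventions

Moving averages are plain means (no FFT), matching brute-force sums to
well under 10⁻⁹ on bounded daily series. Classification refuses days
whose largest window is undefined rather than guessing. Zero exposed
events yield a rate ratio of 0 with a flagged one-sided interval; zero
reference events are an error, not an infinity. Cohorts with no events
produce a holdout report flagged `degenerate` instead of NaNs. All
randomness flows from a single integer seed; the pipeline derives
per-stage seeds by hashing the stage name so stages can be re-run
independently, and every artifact records the seed and a hash of the full
configuration.

## Problem sizes used by the shipped studies

The packaged studies run at desk scale, chosen so the full suite and the
acceptance script re-run comfortably on one CPU: parameter-recovery
studies use 50 cohorts of 2000 patients; planted-signal discovery uses 50
cohorts of 600 patients over 365 days with 12-tree forests on the burden
and activity channels; pipeline smoke runs use 120–150 patients. The
pooled rate-ratio recovery reported by `scripts/acceptance.R` uses eight
2000-patient cohorts.

## Known limitations

The generator's hazard is driven by the true trend state, so recovery
studies validate estimation, not the clinical claim; censoring is
administrative only at two years; the discovery module's holdout is drawn
from the same simulated population as its training set, mirroring the
validation design it reproduces rather than an external validation; and
the matched rule's thresholds inherit whatever granularity the trees
chose — they are medians over bootstrap instances, not fitted parameters
with standard errors.
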