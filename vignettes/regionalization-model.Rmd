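---
title: "A cohort decision model for regionalizing pancreatic cancer surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cohort decision model for regionalizing pancreatic cancer surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancreg)
```

## The model

Pancreatic resection has a pronounced volume–outcome relationship: centers
performing at least 20 resections per year ("high-volume centers", HVCs)
report lower 30-day mortality and complication rates than low-volume centers
(LVCs). `pancreg` implements a cohort decision model that asks what a policy
of *regionalization* — moving resections from LVCs to HVCs — would buy at the
population level, in 30-day deaths, 30-day complications, and the cost of
managing those complications.

The structure is a single 30-day decision cycle with absorbing outcomes:

1. **Cohort funnel.** An annual incident cohort $N$ is reduced to the
   surgical cohort: $N_\text{resectable} = N \cdot p_\text{resectable}$
   (localized or regional disease), then
   $N_\text{resected} = N_\text{resectable} \cdot p_\text{resection}$.
2. **Allocation.** A fraction $A$ of resections happens at HVCs and
   $B = 1 - A$ at LVCs. $B$ is never stored; it is always derived, so
   $A + B = 1$ holds by construction.
3. **Outcomes.** Each center class contributes expected marginal counts
   $n \cdot p_\text{death}$ and $n \cdot p_\text{complication}$, and a
   complication-management cost equal to the complication count times a unit
   cost. Deaths and complications are independent marginals — no joint
   distribution or overlap between the two is modelled, matching how the
   source estimates are reported.
4. **Comparison.** A policy state is the model evaluated at one allocation
   fraction. The *differential* (current state minus a more regionalized
   future state) is the model's headline output: positive values are deaths,
   complications, and dollars saved per year.

Models of this kind are often presented in Markov terms, but only
one 30-day cycle with absorbing states is ever exercised here; there are no
multi-cycle transitions, discounting, or half-cycle correction, and no
survival or quality-adjusted life-year machinery. The model is closed-form
arithmetic, which is why the whole analysis runs in well under a second.

## Baseline inputs

`default_parameters()` carries the published baseline for California:

| Parameter | Value | Unit |
|---|---|---|
| annual incidence | 5958 | cases/year (2021 projection) |
| resectable fraction | 0.41 | of incident cases |
| resection fraction | 0.40 | of resectable patients |
| HVC share of surgeries | 0.466 | of resections (observed) |
| 30-day mortality | 0.018 HVC / 0.052 LVC | per operation |
| 30-day complications | 0.343 HVC / 0.398 LVC | per operation |
| cost per complication | \$16,815 | USD, either center class |

Proportions are always fractions in $[0,1]$, never percentages — percent
strings are rejected even in config files, which removes a whole class of
unit bugs. Unit costs are stored separately per center class (equal at
baseline) so the cost-differential scenario needs no structural change.

`parameter_ranges()` records the spread of the underlying literature: e.g.
HVC mortality 0.017–0.021, LVC mortality 0.045–0.061, resection rate
0.21–0.41, cost per complication \$9,101–\$17,947. Parameters with a single
published source get a degenerate range. One documented inconsistency in the
source material is carried as-is: the tabulated resection-rate range is
21–41% while the accompanying narrative says 27–41%. We use the tabulated
21–41% for ranges and do not attempt to reconcile the two.

## Rounding policy

Counts are people, and the published outputs are integers. The package
rounds expected counts to whole patients with **round-half-away-from-zero**
(`round_half_up()`) at each stage — funnel, allocation, per-center outcomes.
This convention reproduces every published output cell exactly
(e.g. $977 \times 0.466 = 455.282 \to 455$;
$977 \times 0.343 = 335.111 \to 335$; $455 \times 0.018 = 8.19 \to 8$).
Two structural choices matter:

* **Conservation.** The HVC count is rounded and the LVC count obtained by
  subtraction. Rounding both classes independently could create or destroy a
  patient.
* **Cost exactness.** The complication cost is the exact product
  `count × unit cost` with no further rounding, so baseline costs are exact
  integer dollars.

```{r}
p <- default_parameters()
run_state(p, label = "current")
run_state(p, 1, label = "future")
regionalization_differential(p)
```

Every function also accepts `rounding = "off"`, which carries fractional
expected counts through (costs then computed on fractional complications).
Whole-patient rounding makes small differentials move in unit steps, which
both hides monotone structure and, for small scenario deltas, can differ
from the fractional answer by a patient or two. The fractional mode is the
right lens for sweeps, threshold solving, and diagnosing published figures;
the rounded mode is the right lens for reporting people.

## Scenarios

`run_suite()` packages four named scenarios, each reported under *both*
rounding conventions side by side:

```{r}
as.data.frame(run_suite())
```

* **Baseline** — observed allocation (46.6% HVC) vs. complete
  regionalization: 17 deaths, 29 complications, \$487,635 saved per year.
* **Partial regionalization** — future state moves only 75% of operations to
  HVCs: 9 lives saved.
* **Differential complication costs** — managing a complication assumed
  cheaper at HVCs (\$11,098) than LVCs (\$22,364). The two printed dollar
  values are taken literally even though they are not an exact 2:1 ratio
  ($2 \times 11{,}098 = 22{,}196$): printed values outrank the word
  "double".
* **Widened complication gap** — complication rates set to 31.5% (HVC) and
  43% (LVC). We read "widening the gap between center classes" as
  redefining the rates globally, i.e. in **both** the current and future
  states; the alternative (current state keeps baseline rates) contradicts
  the between-classes framing. Mortality inputs are untouched, so the death
  differential stays at its baseline 17.

### Known discrepancies in the published sensitivity figures

Three figures printed in the source's sensitivity narrative do not follow
from its stated inputs under any rounding convention, and the package
deliberately does **not** reproduce them. Its recomputed values:

| Scenario | Published | Recomputed (half-up) | Recomputed (fractional) |
|---|---|---|---|
| partial 75%, complications | 15 | 16 | 15.26 |
| partial 75%, cost saved | \$256,870 | \$269,040 | \$256,639 |
| widened gap, complications | 58 | 59 | 60.00 |
| widened gap, cost saved | \$974,295 | \$992,085 | \$1,008,975 |
| differential cost, saved | \$2,659,211 | \$2,665,170 | \$2,658,071 |

Note the published 15 complications match the *fractional* convention while
the published table matches the *half-up* convention, and the published
dollar figures match neither ($15 \times 16{,}815 = 252{,}225$, not
256,870; $58 \times 16{,}815 = 975{,}270$, not 974,295). These
inconsistencies are asserted in the test suite as negative checks — the
package treats them as documentation, not as targets.

## Deterministic sensitivity analysis

`one_way_sweep()` re-evaluates the baseline-vs-complete-regionalization
differential over `n_points` evenly spaced values of one parameter across
its literature range. Sweeps run in fractional mode so the curves are
smooth functions rather than patient-count staircases:

```{r}
one_way_sweep("lvc_mortality_30d", n_points = 5)
```

`threshold_fraction()` inverts the dose–response: the smallest future-state
HVC fraction achieving a target saving, found by bisection to a $10^{-6}$
fraction tolerance. In fractional mode the differential is continuous and
monotone non-decreasing in the fraction whenever HVC rates are no worse
than LVC rates, so bisection is exact:

```{r}
threshold_fraction(p, "deaths", target = 10)
```

## Probabilistic sensitivity analysis

The source gives literature *ranges*, not distributions. The least
assumptive reading is uniform over each range, independently across
parameters, and that is the default for `run_psa()`:

```{r}
run_psa(n_draws = 1000, seed = 1)
```

Design choices, made once:

* **Uniform by default.** A beta/gamma option exists (`dist = "beta-gamma"`)
  for users who prefer standard health-economics shapes: each beta (gamma
  for costs) is matched by mean to the baseline value with its central 95%
  interval as wide as the literature range, solved in the unimodal regime;
  draws are then clipped to the range so every sampled set respects its
  literature bounds. The clipping puts small point masses at the bounds —
  acceptable for a bounded literature range, and it keeps the "all draws
  in range" invariant true for every distribution kind.
* **Independence.** No correlation structure is imposed across parameters
  (none is published). This overstates joint uncertainty in tails and is a
  documented limitation.
* **Fractional counts internally.** PSA evaluates differentials in
  fractional mode to avoid staircase artifacts; rounded baselines remain
  available for cross-checking.
* **Substreamed seeding.** Each parameter draws from its own RNG substream
  derived deterministically from the root seed, so restricting or extending
  the sampled parameter set never perturbs the other parameters' draws, and
  fixtures stay stable across versions. The sampler saves and restores the
  caller's RNG state.

## Synthetic parameter sets as fixtures

`sampling_spec()` + `sample_parameters()` generate seeded, validated
parameter sets within the literature ranges — this is what the PSA layer and
the property tests feed on, with no external data. What the generator
emulates is exactly *parameter heterogeneity across the published
literature*; it does not emulate patient-level variation, within-center
correlation, or secular trends, so passing tests say nothing about those
features of real data. `write_fixture()` emits the sets as a plain CSV plus
a sidecar config sufficient to regenerate the file byte-for-byte
(`regenerate_fixture()`).

## Numerical and degenerate-input choices

* Ties in rounding go away from zero; counts are non-negative so this is
  "half up".
* A center class with zero surgeries is reported as a zeros row (never
  omitted), keeping report shapes stable; totals are unaffected.
* Degenerate literature ranges (`low == high`) collapse any sampling
  distribution to a point mass; a degenerate sweep range repeats its single
  value.
* `compare_states()` refuses to difference states with different total
  surgery counts (differentials are only meaningful on a common cohort);
  in fractional mode the equality check uses a $10^{-9}$ tolerance.
* Config parsing is strict: unknown keys, duplicate keys, missing keys, and
  percent strings are all hard errors with the offending line or field
  named.

## Problem sizes

Everything is closed-form, so the defaults are generous and still fast: the
test suite's brute-force oracle sweeps all cohort sizes 0–200 on a grid of
rates in both rounding modes; distributional tests use 2,000–5,000 draws;
the shipped analysis script uses 2,000 PSA draws. All of it, end to end,
runs in seconds on one CPU.

## Limitations

* One 30-day cycle; no 90-day outcomes, readmissions, survival, or QALYs,
  so no cost-effectiveness ratio is (or can be) computed — there is no
  effectiveness denominator.
* Deaths and complications are marginal counts; a patient may implicitly be
  counted in both.
* The provenance of the \$16,815 unit cost (cost-to-charge ratios, wage
  indices, inflation adjustment) is upstream of this model; the value is
  taken as a given input.
* Parameter uncertainty is sampled independently and (by default) uniformly;
  the literature provides no joint information to do better.
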