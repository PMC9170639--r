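---
title: "Estimating unbiased post-error slowing in interference tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating unbiased post-error slowing in interference tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pesbias)
library(dplyr)
```

## The estimation problem

Post-error slowing (PES) is the increase in reaction time on correct
trials immediately following an error, relative to a baseline of other
correct trials. Two baselines are in common use: *post-correct* trials
(correct trials following a correct trial; the traditional estimator) and
*pre-error* trials (correct trials following a correct trial and preceding
an error; the robust estimator, which matches baseline and post-error
trials in time and so resists slow drifts in speed or accuracy).

In interference tasks a second, less obvious confound arises. Congruent
trials are faster and more accurate than incongruent trials, and error
rates are higher after congruent trials (conflict adaptation). The trial
sets entering each average are therefore *differently* imbalanced mixtures
of a fast and a slow RT distribution:

- pre-error trials lean congruent because errors preferentially follow
  congruent trials;
- post-correct trials lean congruent because incongruent trials are more
  often errors and drop out of the "correct after correct" set;
- post-error trials lean congruent because only *correct* post-error
  trials count, and incongruent post-error trials fail more often.

Pooling congruency conditions before averaging computes the central
tendency of a weighted mixture. For the mean, the cell-level bias is

$$\mathrm{bias} = -(\overline{RT}_{incon} - \overline{RT}_{con})
  \times (p_{con} - 0.5),$$

linear in the interference effect and the imbalance and independent of
the component SDs; a 100-ms interference with a 70/30 split biases the
cell mean by 20 ms. PES inherits the *difference* of the post-error and
baseline cell biases, so it is biased whenever the two trial sets are
differently imbalanced. The remedy implemented here as the "corrected"
estimators: average congruent and incongruent RTs separately, then take
the unweighted mean of the two condition means.

All four estimators are computed per participant and per
response-stimulus-interval (RSI) stratum, where the relevant RSI is
always the one that *preceded* the trial, and baseline and post-error
cells are always matched on it. PES depends strongly on RSI, so mixing
strata would itself be a confound.

## Trial classification and its edge rules

Roles are a pure function of the accuracy sequence. For a correct trial
$t$: post-correct iff $t-1$ is correct; pre-error iff additionally $t+1$
is an error; post-error iff $t-1$ is an error and $t+1$ is correct. A
single correct trial between two errors is both pre-error and post-error
and is excluded as ambiguous — the rule applies to the exact
error–correct–error triple only; longer correct runs classify normally.

Two edge rules required decisions the estimator definitions leave open:

- **No-response neighbours.** A trial adjacent to a no-response trial
  receives no role that depends on that neighbour (its own RT may still
  enter other roles). Fabricating adjacency across an unscored response
  would create neighbour pairs the participant never experienced.
- **First/last trials.** A role is assigned only when the neighbours it
  quantifies over exist: the session's last correct-after-error trial is
  *not* post-error, because the confirming next trial is missing. The
  first trial also has no preceding RSI and is never
  measurement-eligible.

Filtering (post-break removal, the 100–1500 ms RT window, MAD outlier
rejection with scale 1.4826 and threshold 2.5) never recomputes roles: a
filtered trial keeps its accuracy status for its neighbours' roles and
only loses its own RT from averages. Recomputing adjacency over gaps
would again create pseudo-neighbours. Post-break and RT-window screening
run first; MAD statistics are then computed on the surviving correct RTs,
by default within participant × congruency × preceding-RSI cells
(within-condition screening, the standard recommendation for RT data;
the grouping is configurable because conventions differ). A cell whose
raw MAD is zero flags nothing — with low-variance integer-valued RTs a
zero MAD can occur even with non-identical values, and dividing by zero
would flag every deviating trial regardless of magnitude.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `rt_min_ms`, `rt_max_ms` | 100, 1500 | absolute RT window (ms) |
| `mad_scale`, `mad_threshold` | 1.4826, 2.5 | MAD consistency scale and cut |
| `min_cell_trials` | 5 | minimum eligible pre-error/post-error trials per congruency × RSI cell (inclusive) |
| accuracy minima | 80% / 60% | congruent / incongruent percent correct (inclusive) |
| `n_iter`, `level` | 1000, 0.95 | bootstrap replicates and coverage |

Screening accuracies are computed over close trials after post-break and
RT-window removal but *before* MAD removal: the MAD screen targets
correct-RT distributions, not accuracy. Only pre-error and post-error
cells face the ≥5-trial rule; post-correct cells are plentiful by
construction and are only required to be non-empty. Median cells use
midpoint interpolation for even counts. The percent inflation statistic
uses the corrected estimate as its denominator, and the paired effect
size is $d_Z = \bar{b}/SD(b)$, reported as `NA` when the SD is zero
rather than as an infinity.

## The mixture-bias model

`mixture_central()` treats a cell as a two-component normal mixture with
common SD. The mean variant is closed-form. The median variant solves
$w\,\Phi((m-\mu_{con})/\sigma) + (1-w)\,\Phi((m-\mu_{incon})/\sigma) =
0.5$ by bracketed root search on $[\min\mu - 10\sigma, \max\mu +
10\sigma]$ — the mixture CDF is strictly increasing, so the bracket
always contains the unique root; the numerical tolerance (1e-8 ms) is far
below the 0.01-ms documentation contract. At $\sigma = 0$ the step-CDF
median is the majority component's mean (midpoint at $w = 0.5$), which
is the worst case: in the worked example a 15/5 imbalance drags the
pooled pre-error median to 1000 ms and overstates PES by 200 ms.

Sign convention: every bias is reported as (weighted central) −
(unweighted midpoint), so a congruent surplus yields a *negative*
cell-level bias, and the PES-level bias combines the post-error and
baseline cell biases with opposite signs. The per-participant
uncorrected-minus-corrected bias equals the analytic prediction applied
cell-wise exactly (this identity is tested). `bias_grid()` sweeps
interference 0–200 ms (5-ms steps by default — the grid step is a
package choice), imbalance 55–70%, SDs 50 and 100 ms; the mean rows are
SD-invariant and the median bias is at least as strong as the mean bias
at every point.

## The synthetic flanker task

The generator emulates the design the estimators assume: 1088 trials
with a self-paced break every 200 (the following trial is flagged and
dropped by default), 50% congruent with the four congruency transition
types counterbalanced to within one occurrence (via a seeded run-length
construction), preceding RSIs of 250/700 ms balanced within congruency,
and per-condition normal RTs (defaults: congruent 400/360 ms at
short/long RSI, incongruent 450/410 ms, SD 80 ms — a 50-ms interference
effect with short-RSI trials slower, the ordering seen in speeded
flanker data). Error probabilities default to 5.0% (congruent) and 29.9%
(incongruent); conflict adaptation adds ±`adaptation_delta`/2 = ±0.0185
to the error probability depending on the previous trial's congruency,
reproducing an after-congruent vs. after-incongruent gap of ≈3.7
percentage points (≈18.6% vs. 14.9% around the pooled base rate).
Injected post-error slowing (default 50 ms) is added to every response
following an error. Drifts enter additively on the RT mean and on the
error log-odds: `drift_linear_fatigue()` (slower, sloppier late) and
`drift_caution_phase()` (an initial slow-and-accurate phase). An
ex-Gaussian RT family is available to make the median-vs-mean bias
differences visible; adaptation acts on error rates only by default
(an RT-level congruency-sequence effect is available but off), because
the imbalance mechanism runs through error rates. Post-error accuracy
improvement is not modeled: the post-error congruency imbalance already
arises from selecting *correct* post-error trials.

What the generator deliberately does not emulate: RT–accuracy
dependence within a trial (no diffusion-style speed–accuracy trade-off),
sequential RT autocorrelation beyond the modeled adaptation and drifts,
and far-distance flanker conditions (the data model carries the field;
all simulated trials are close). Passing recovery tests therefore shows
the estimators are unbiased under the stated mixture mechanism, not that
every property of empirical flanker data is reproduced.

A note on outlier screening and recovery: with the MAD screen on, the
recovery of an injected Δ is a few ms low *by construction* — the screen
pools all correct trials of a cell and so asymmetrically trims the upper
tail of the genuinely shifted post-error distribution. This is a
property of pooled outlier rejection, not of the estimators. The
recovery analyses in the test suite therefore run the median-style
filter set (post-break + RT window, MAD off), the same choice the
median pipeline makes; applied analyses that keep the MAD screen should
expect that small attenuation.

## Problem sizes and numerical checks

The test suite verifies classification against an independent
brute-force triple-scan enumerator on 1000 random sequences; mixture
medians against 10^6-draw Monte-Carlo medians at 20 random
specifications (within 1 ms); injected-slowing recovery on 200 simulated
participants (group corrected robust PES within ±3 ms of the injected
50 ms, uncorrected exceeding corrected in the direction the measured
pre-error imbalance predicts); and the confound directions on 120
participants per drift preset — sizes chosen to make Monte-Carlo error
small relative to the tested effects. Two-level bootstrap coverage is
checked at 12 participants × 15 observations over 200 repetitions with a
generous band: percentile intervals under-cover slightly at small
participant counts, which is a known property of the method, not a
defect of the implementation.

## Interfaces

The tidy trial tibble (one row per trial, `participant` column) is the
package's only data container; `read_trial_log()`/`write_trial_log()`
round-trip it through CSV/TSV with a documented column contract and an
optional header mapping, and a numeric RSI column is binned at a
user-supplied threshold (default 475 ms, the midpoint of the 250/700-ms
design). All result tables are tidy (one observation per row). The
command-line wrapper (`pes_cli()`; `inst/cli/pesbias`) exposes
`simulate`, `classify`, `estimate` and `bias-grid`; the reporting the
specification sketches as a separate command is covered by `estimate`'s
output set (per-participant estimates, imbalance table, inclusion
report, bias summary, group summary with bootstrap CIs). Exit codes: 0
success, 1 usage error, 2 data error — including the case where no
participant survives screening, which still writes all tables.

## Known limitations

- The empirical magnitudes of the imbalances and PES biases in any real
  dataset depend on that dataset; the package reproduces mechanisms and
  worked examples, and its simulation defaults are realistic rather than
  fitted.
- The multilevel bootstrap returns percentile intervals only (no BCa).
- Breaks are encoded by a `first_after_break` flag; raw logs that encode
  breaks differently must be mapped during import.
```{r example}
trials <- worked_example_trials("imbalanced")
labels <- classify_trials(trials)
cells <- cell_statistics(trials, labels, central = "mean")
pes_estimate(cells, "robust", "uncorrected", rsi = "short")$pes_ms
pes_estimate(cells, "robust", "corrected", rsi = "short")$pes_ms
```
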