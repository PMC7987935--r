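---
title: "Methods: actigraphy-based identification of weekday sleep debt factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actigraphy-based identification of weekday sleep debt factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiwsd)
```

## The problem

Weekday sleep debt (WSD) is the chronic weekday sleep restriction that
day-working adults compensate with longer weekend sleep. `actiwsd`
implements a complete analysis pipeline for one-week wrist-actigraphy
protocols built around that construct: a subject wears a wrist actigraph
from Monday around 17:00 to the next Monday around 08:00, the device
records activity counts and illuminance in 1-minute epochs, and the
analysis asks which circadian and sleep-habit characteristics distinguish
subjects with WSD from those without.

The pipeline has five stages, each exposed as ordinary R functions:

1. **Ingestion and screening** (`read_epochs()`, `trim_to_protocol()`,
   `apply_exclusion()`): recordings are clipped to the fixed protocol
   window (6 days 15 h = 9,540 one-minute epochs) and subjects with any
   non-wear run longer than 30 minutes are excluded. The first, partial
   Monday is kept only for wake-up/sleep-onset estimation; day-complete
   statistics use Tuesday–Sunday.
2. **Sleep/wake scoring** (`cole_kripke()`, `sleep_wake_function()`,
   `nightly_times()`, `summarize_days()`).
3. **The 40-feature circadian battery** (`build_feature_vector()`).
4. **Factor identification** (`run_experiment()`): a Gaussian-kernel SVM
   with repeated under-sampled splits and permutation feature importance.
5. **Group statistics** (`ttest_bonferroni()`, `chi2_2xk()`,
   `bland_altman()`).

A seeded synthetic generator (`generate_subject()`, `generate_cohort()`)
stands in for restricted cohort data and provides ground truth for every
stage.

## Sleep/wake scoring and nightly times

Each epoch is scored with the Cole–Kripke weighted-window rule for
1-minute counts: epoch $i$ is sleep iff

$$D_i = P\,(W_{-4}A_{i-4} + \dots + W_{0}A_i + \dots + W_{+2}A_{i+2}) < 1,$$

with the published coefficient set $P = 0.001$,
$W = (404, 598, 326, 441, 1408, 508, 350)$ (exposed via
`cole_kripke_weights()`; no rescoring rules are applied). Boundaries are
zero-padded.

Scored states $x_i \in \{+1 \text{ (sleep)}, -1 \text{ (wake)}\}$ are
accumulated into $r(i) = \sum_{j \le i} x_j$, which rises during sleep and
falls during wake. Wake-up time (WU) of a day is the latest local maximum
of $r$ in the morning window 00:00–12:00; sleep-onset time (SO) of a day
is the latest local minimum in the evening window 12:00–06:00 (next day),
reported on the onset day's minutes-after-midnight scale so post-midnight
onsets exceed 1,440. Two numerical conventions matter:

* the extremum of $r$ sits on the last epoch *before* the state change, so
  the reported time is the boundary one epoch later (sleep scored through
  the 05:59 epoch gives WU = 360);
* a tied extremal plateau contributes its last epoch (this extends the
  "latest extremum" rule; with $\pm 1$ steps $r$ itself never plateaus, so
  the case only arises for degenerate inputs).

The search windows are a package choice — the printed group means they
must be compatible with put onsets around 23:30–00:06 and wake-ups around
05:30–06:00, which both windows cover with wide margins. Raw $r$ is used
without smoothing; an isolated misscored epoch can therefore displace a
nightly time, which is visible in noisy regimes but not under the bundled
generator's count model (see below).

Per-night summaries use the overnight conventions

$$\mathrm{SD} = \mathrm{WU} + 1440 - \mathrm{SO}, \qquad
  \mathrm{MS} = \left(\frac{\mathrm{SO} + \mathrm{WU} + 1440}{2}\right)
  \bmod 1440 .$$

The naive "midpoint of SO and WU" formula is not used: it is inconsistent
with printed reference values whenever SO is on the evening scale (e.g.
SO = 1,434 and WU = 338 must give MS = 166, not 886). The overnight form
reproduces the reference identities exactly, which the acceptance tests
assert.

## The 40-feature battery

`build_feature_vector()` computes, per subject (names via
`feature_names()`):

* **Sleep habits** — WU for Tuesday–Friday mornings, SO/MS/SD for
  Monday–Thursday nights, plus mean and sample (n−1) standard deviation
  of each. Friday-night sleep belongs to the weekend, so weekday blocks
  end with Thursday night.
* **Rest–activity windows** — M10 and L5 (mean activity of the most
  active contiguous 10-h and least active 5-h windows), per calendar day
  Tuesday–Friday, windows constrained within the day.
* **Sleep rhythm** — the sleep regularity index
  $\mathrm{SRI} = -100 + \frac{200}{p(N-1)} \sum_{j,k}
  \delta(s_{k,j}, s_{k+1,j})$ over the six complete days, and the sleep
  timing index STI, the circular-mean clock time of all sleep epochs.
* **Activity rhythm** — interdaily stability and intradaily variability
  for both activity and illuminance,
  $$\mathrm{IS} = \frac{M \sum_j (\bar A_j - \bar A)^2}
                       {p \sum_i (A_i - \bar A)^2}, \qquad
    \mathrm{IV} = \frac{M \sum_{i \ge 2} (A_i - A_{i-1})^2}
                       {(M-1) \sum_i (A_i - \bar A)^2},$$
  computed on raw 1-minute epochs by default. An hourly-bin mode
  (`bin_minutes = 60`) is available; binning is a genuine scale choice —
  white-noise epochs give IS $\approx 1/N$ and IV $\approx 2$ at any bin
  width (a calibration the tests verify), while structured profiles gain
  IS under binning.
* **Biological clock** — weekend (Friday + Saturday night) means SOF/WUF,
  mid-sleep on free days $\mathrm{MSF} = \mathrm{MS}(\mathrm{SOF},
  \mathrm{WUF})$, weekday mean mid-sleep MSW, social jetlag
  $\mathrm{SJL} = \mathrm{MSF} - \mathrm{MSW}$.

The weekday-sleep-debt label derives from the weekend sleep rebound
$\mathrm{SRW} = \mathrm{SDF} - \mathrm{SDW}$ (mean weekend minus mean
weekday sleep duration): a subject has WSD when $\mathrm{SRW} \ge 120$
minutes. Chronotype classes use the MSF thresholds 03:00/04:00.

## Factor identification

`run_experiment()` repeats, 100 times by default under one master seed:

1. random under-sampling of the majority class to balance WSD/non-WSD;
2. a stratified 7:3 train/test split;
3. z-score standardization fitted on the training split (required for a
   Gaussian kernel across minutes-vs-counts scales);
4. kernel width $\gamma$ tuned by stratified 10-fold cross-validated
   accuracy over the grid $10^{-3} \dots 10^{2}$, smallest $\gamma$ on
   ties; cost fixed at $C = 1$;
5. an SVM fit and one permutation per feature on the test split:
   $\mathrm{Pimp}(x_j) = E - E_j$ with $E$ the intact test accuracy and
   $E_j$ the accuracy after shuffling column $j$ once.

Mean importances over the repeats are ranked, and `select_top()` returns
the smallest prefix whose cumulative importance reaches 20% of the summed
*positive* importances (negative importances — shuffles that accidentally
help — are excluded from the denominator but can never be selected
anyway). Tuning $\gamma$ inside every repeat, re-under-sampling inside
every repeat, and using accuracy as the performance metric are package
choices where the procedure admits variants; all are configurable through
`experiment_config()`.

A caution from our own synthetic experiments: permutation importance
divides credit among correlated features, and the cumulative-20% rule
returns very few features when importance concentrates. With strong,
partially redundant effects the selected set typically has one or two
members — the rule's set size is itself an indicator of how diffuse the
signal is, not a fixed count of "the important factors". Findings should
be read from the full ranking (`report$importance`), with the top set as
a shortlist.

## Group statistics

`ttest_bonferroni()` runs Student's pooled-variance two-sample tests (the
Welch variant via `var_equal = FALSE`) with the family-wise threshold
$\alpha/m$: $m = 40$ for the battery ($0.05/40 = 0.00125$) and $m = 13$
for the questionnaire totals. `chi2_2xk()` is Pearson's test without
continuity correction (df $= k - 1$ for a $2 \times k$ table).
`bland_altman()` reports the mean actigraphy-minus-diary sleep-duration
difference with $\pm 1.96\,\mathrm{sd}$ limits of agreement. Tests are
two-sided throughout.

## The synthetic generator: what it emulates and what it does not

`generate_subject()` reproduces the protocol's observable structure: a
Monday-17:00 to Monday-08:00 1-minute grid; one consolidated nocturnal
sleep bout per night with night-level onset jitter; weekday wake fixed by
a work alarm; Friday/Saturday sleeps extended to hit a target rebound (so
the true SRW is known exactly); wake counts as rounded Gamma draws around
a diurnal sinusoid; sleep counts from a small-mean Gamma regime that
rounds to zero essentially always; day/night illuminance with log-normal
noise; explicit non-wear gaps; a diary equal to truth plus truncated
Gaussian errors applied independently to onset and wake (so diary
*duration* errors have sd $\sqrt 2 \sigma$); and questionnaire totals
uniform in each instrument's printed range, with the MEQ total optionally
tied to chronotype.

Cohort-level spreads were fixed from the reference study's printed group
standard deviations before any acceptance measurement: within-subject
onset jitter 45 min, between-subject chronotype sd 55 min, wake-time sd
40 min (clamped to the recordable morning), rebound sd 45 min per class
(means 180/45 min, truncated 10 min clear of the 120-min threshold so
class labels are unambiguous), a 45-min evening-chronotype shift and a
60-min Thursday onset shift for the WSD class, and between-subject
heterogeneity in activity level, diurnal amplitude and daytime lux.

Not emulated: naps (available via an option only in schedule form),
nocturnal awakenings, within-sleep movement bursts, device-specific count
transfer functions, daylight-saving arithmetic, or any physiological
circadian model. Consequently, passing the recovery tests shows the
pipeline's algebra and conventions are right and that effects survive
realistic *timing* noise; it does not certify scorer performance against
polysomnography or against real wrist-count distributions.

## Problem sizes and numerical choices

The test suite uses desk-scale runs chosen to exercise every code path:
Monte-Carlo calibrations with 500–1,000 replicates; zero-noise recovery
on a 100-subject cohort; and the factor-recovery experiment on one
200-subject cohort with 20 experiment seeds of 100 repeats each. Constant
features pass through standardization unscaled and shuffle to themselves
(importance exactly 0); degenerate inputs (constant series for IS/IV,
circularly uniform sleep for STI, empty classes, all-negative importance)
raise or warn explicitly rather than returning silent NAs. Gamma-grid
ties and tied extremal plateaus break deterministically (smallest
$\gamma$; last epoch), keeping the whole pipeline reproducible
byte-for-byte under a fixed master seed.

## Known limitations

* The latest-local-extremum rule on unsmoothed $r(i)$ is sensitive to
  isolated misscored epochs; real recordings with fragmented sleep may
  need the search windows narrowed or a rescoring pass before this rule
  is trustworthy.
* Permutation importance under correlated features (SD and SO of the same
  night are near-affine; MSF and SJL share construction) spreads or
  hides credit; the cumulative-20% shortlist should not be read as an
  exhaustive factor list.
* The generator's questionnaire totals are distributional placeholders,
  not item-level simulations; only their ranges and one optional
  chronotype tie are meaningful.
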