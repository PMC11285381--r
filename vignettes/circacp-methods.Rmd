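---
title: "Circadian-guided change-point detection of sleep-wake cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian-guided change-point detection of sleep-wake cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(circacp)
library(dplyr)
```

## The problem

Wrist- and hip-worn actigraphs record movement intensity ("activity
counts") in 30 s or 60 s epochs for days to weeks. Many sleep metrics —
sleep onset time (SOT), wake onset time (WOT), sleep duration, night-to-
night variability — derive from locating the transitions between the wake
and sleep regimes in this one-dimensional series. Supervised detectors
need labelled training data and inherit the scale conventions of whatever
device produced them; activity counts have no common unit across sensors,
so tuned cutoffs transfer poorly. This package implements an unsupervised
alternative that leans only on two near-universal features of human
actigraphy: a roughly 24 h rest-activity rhythm, and a drastic
distributional shift in activity at sleep and wake onsets.

## The two-stage model

**Stage 1 — where, roughly, are the cycles?** The circadian rhythm is
summarised by a cosinor regression

$$r(t) = \mathit{mes} + \mathit{amp}\cdot\cos\!\big((t-\phi)\,2\pi/T\big),$$

with period fixed at $T = 1440$ min, fitted by least squares. Because $T$
is fixed, the model is linear in $(\mathit{mes},\,
\mathit{amp}\cos(2\pi\phi/T),\, \mathit{amp}\sin(2\pi\phi/T))$: the
default solver regresses on the cosine/sine basis and recovers amplitude
and acrophase analytically, which is the exact global optimum. An
iterative Levenberg–Marquardt solver (multi-started over the acrophase,
since the nonlinear objective has local minima in $\phi$) is retained and
agrees with the linear path to well below 1e-8 on clean data; a Huber
option guards against extreme activity bursts but is off by default
because plain least squares is the reference behaviour. The fitted curve
is then dichotomized: epochs in the lower 18% of its range are nocturnal.
The 18% default reflects the roughly one-fifth of the day spent asleep in
ageing adults; on a pure cosine it marks
$1-\arccos(2\cdot 0.18-1)/\pi \approx 27.9\%$ of each cycle as nocturnal.
The dichotomized state changes give one rough wake-to-sleep and
sleep-to-wake transition per cycle — too rigid to capture day-to-day
variation in onset times, which is exactly what stage 2 supplies.

**Stage 2 — where, exactly, is each onset?** Within a cycle the series is
treated as independent draws $y_k \sim \Gamma(\theta_k, \xi)$ with a
common shape $\xi$ and a scale $\theta_k$ that switches once, at the
onset. Gamma scales fit activity intensities well: both regimes are
long-tailed and non-negative, and sleep epochs have far smaller scale
with much more mass at zero. For a window $y_1,\dots,y_n$ the profile
MLEs under a change after $k$ are $\hat\theta_1 = S_1/(k\xi)$ and
$\hat\theta_2 = S_2/((n-k)\xi)$ with $S_1, S_2$ the two partial sums, and
the location is chosen by minimising a modified information criterion

$$\mathrm{MIC}(k) = -2\log L_1(\hat\theta_1,\hat\theta_2) + 2\log n
  + \lambda\,(2k/n-1)^2 \log n ,$$

whose quadratic term penalises change points near the window edges,
where one segment's MLE rests on few observations. Dropping every
$k$-free term gives the reduced objective the code evaluates in $O(n)$
via cumulative sums:

$$2k\xi\log S_1 + 2(n-k)\xi\log S_2 - 2k\xi\log(k\xi)
  - 2(n-k)\xi\log((n-k)\xi) + \lambda(2k/n-1)^2\log n .$$

The test suite proves this reduction exact (up to a $k$-free constant)
against a brute-force evaluation of the full Gamma log-densities, and
proves the selected $\hat k$ identical to the exhaustive
penalized-likelihood argmin over hundreds of random windows.

## Orchestration

1. **Screening.** Recordings shorter than 5760 min (4 days) are
   excluded; continuous wearing periods are stretches with no zero run
   exceeding 120 min (a run of exactly 120 min does not split), and the
   longest such period must also reach 5760 min. Detection then runs on
   that longest period only. 30 s recordings are aggregated to 60 s by
   pairwise sums, conserving total counts.
2. **Windows.** Each rough transition anchors a search window reaching
   to the midpoints between neighbouring transitions (series ends for
   the outermost). Under monophasic sleep each window then straddles
   exactly one true onset, which is the premise of the single-change-
   point search; windows shorter than 240 epochs are dropped.
3. **Detection and refinement.** `detect_cp()` runs per window with
   zeros floored at 0.1 count and the shape estimated once per window
   under the homogeneous model. A second round rebuilds windows from
   midpoints between the *first-round* change points — the cosinor
   anchors can sit tens of minutes off, skewing window edges — and
   re-searches each window once, re-estimating the shape in the new
   window. One pass only: iterating to convergence is not part of the
   procedure and empirically is not needed (on clean input refinement is
   a fixed point).
4. **Events.** The change point $\hat k$ indexes the last epoch of the
   old regime; the onset event is stamped at the start of epoch
   $\hat k + 1$, the first epoch of the new regime. Wake-to-sleep
   windows yield SOTs, sleep-to-wake windows WOTs.

## Error detection

With no labels, errors are flagged internally: the Calinski–Harabasz
variance-ratio criterion with $k=2$ clusters is computed for the
epoch-level sleep/wake labelling implied by the rough cosinor dichotomy
(`ch_cos`) and by the detected events (`ch_pro`), over the same raw
counts. A refined segmentation that truly tracks the regime switches
separates the two activity clusters far better; when
`ch_pro - ch_cos < 100` the subject is flagged as likely containing
detection errors. Flagged subjects remain in the output with the flag
set, and are meant to be excluded from downstream agreement analyses.

## Validation against event markers

Self-reported button presses are noisy — forgotten, repeated, or pressed
at arbitrary times — so estimated onsets are paired to markers by
proximity: candidates lie within 180 min (inclusive; timestamps are
truncated to whole minutes first), the **latest** candidate is kept for
an SOT and the **earliest** for a WOT, and each marker pairs with at most
one event, assigned greedily in chronological order. Sequence-alignment
approaches (Needleman–Wunsch, dynamic time warping) are deliberately not
used: long marker gaps break them, while valid markers always sit close
to true onsets. Times are converted to minutes since midnight, with
1440 added to SOTs falling between midnight and noon so one night's
bedtimes stay on a contiguous scale (noon is the natural changeover and
is configurable). Agreement is summarised by Bland–Altman bias and 95%
limits of agreement plus median absolute error, per kind, with match
rates computed over all estimated events.

## What the simulator emulates — and what it does not

`simulate_subject()` draws a monophasic night sleeper: zero-inflated
Gamma activity with wake scale 200, sleep scale 10, shape 0.8, zero
probability 0.1 awake versus 0.6 asleep; onset times jitter day to day
with SD 20 min around subject means (23:00 / 07:00 by default, varied
between subjects with SD 45 min in cohorts); recordings start at a
midnight and end at 06:00 after the final night so every onset has data
on both sides. A 30 min sedentary wind-down at scale 45 (the geometric
mean of the two regimes — quiet reading in bed, not yet asleep) precedes
each true sleep onset; this reproduces the known asymmetry that
actigraphy places SOTs earlier than self-report (the device cannot
distinguish lying still from sleeping), and our end-to-end tests assert
that WOT errors are indeed stochastically smaller than SOT errors.
Markers are true onsets plus N(0, 10 min) noise, each forgotten with
probability 0.2.

The simulator does **not** emulate naps or polyphasic sleep, shift-work
schedule changes mid-recording, non-wear gaps, sensor saturation, or
marker presses at arbitrary non-bed times. Passing tests on this
generator therefore demonstrate correctness of the machinery under the
model's own assumptions, not performance on pathological real-world
recordings; on real data the CH flag is the guard rail.

## Numerical choices and degenerate inputs

* Zeros are floored at `eps = 0.1` count before any Gamma likelihood
  (the log-likelihood needs positivity; the floor preserves ordering and
  is configurable).
* The Gamma shape is solved from
  $\log\xi - \psi(\xi) = \log\bar y - \overline{\log y}$ by Newton with
  the standard closed-form initialiser, falling back to the moment
  estimator on failure; a constant window raises a degenerate-input
  error.
* `min_seg = 30` epochs keeps at least 30 observations on each side of
  any candidate change point.
* MIC ties are broken toward the window midpoint, then the smaller
  index, making detection fully deterministic.
* A flat cosinor (constant series) raises a no-rhythm error rather than
  guessing; ties at the dichotomization threshold count as diurnal, so
  the labelling is invariant to adding a constant to the curve.
* Scale equivariance: multiplying all counts by $c>0$ leaves $\hat k$
  unchanged when the shape is held fixed (the reduced objective shifts
  by a $k$-free constant), so device scale conventions do not move
  detected onsets.

## Design decisions that were genuinely open

* **Window construction** is not part of the published procedure beyond
  "within each circadian cycle"; midpoint edges were chosen because they
  guarantee one true transition per window under monophasic sleep. A
  fixed ±T/4 window around each anchor is a simple alternative but
  over- or under-covers when cycles drift.
* **Indexing** is 1-based throughout (R convention), with half-open
  `[lo, hi)` windows.
* The printed form of the reduced objective in the source literature
  carries two typographical slips (a dropped shape factor and
  $\log(n\xi)$ for $\log(k\xi)$); the implementation derives the
  objective from the profile likelihood and the oracle tests certify it.
* The cosinor's default iterative initialiser `(500, 550, 227)` is kept
  as an opaque optimizer seed; the linear solver makes it immaterial in
  practice.
* The aggregation operator for 30 s → 60 s is a **sum**, not a mean:
  counts are additive intensities per epoch.
* A single change point is always returned per window — there is no
  "no-change accepted" path, because the pipeline's premise is one
  transition per window; the `delta_bic` diagnostic (criterion at the
  optimum minus the no-change BIC) is exposed for QC instead.

## Problem sizes used in the tests

The bundled tests and the acceptance script run entirely on simulated
data: cohorts of 20 subjects × 7 days at 60 s epochs (≈ 10 440 epochs
per subject) for end-to-end recovery, 200 random windows of up to 200
epochs for the change-point oracle, and 200 replicates for recovery-rate
estimates. These sizes give Monte-Carlo error comfortably inside the
asserted tolerances while keeping a full run to a few seconds.

## Known limitations

* Subjects whose habitual sleep onset falls *after* midnight can start
  the recording mid-sleep with a partial first cycle; the rough cosinor
  phase then occasionally misassigns the first window and shifts the
  SOT/WOT labelling for that subject. The CH error detection flags these
  (that is its purpose), mirroring the small exclusion fraction expected
  in real cohorts.
* Onset events are behavioural (time-to-bed, time-out-of-bed), not
  physiological sleep; the wind-down asymmetry is inherent to actigraphy.
* Severely irregular rhythms (no discernible 24 h cycle) produce a
  degenerate or misleading cosinor; such subjects fail loudly (no-rhythm
  error) or are flagged.
* Naps and split sleep are outside the model: each circadian cycle
  contributes exactly one SOT and one WOT.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(n_subjects = 5, seed = 11)
events <- detect_sw(sim$activity)
attr(events, "qc")

matches <- match_markers(events, sim$markers)
summarize_agreement(matches)
plot_bland_altman(matches)
```
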