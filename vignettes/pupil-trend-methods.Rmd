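---
title: "Pupil trends: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pupil trends: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupiltrend)
```

## The problem

Pupil diameter fluctuates on several timescales at once. Fast changes —
the light reflex to a bright target, the phasic dilation accompanying a
response — ride on much slower drifts that track the observer's tonic
alertness over tens of seconds. Because the fast components are dominated
by stimulus luminance, raw peri-event pupil size is a poor index of
alertness in tasks with visual targets. **pupiltrend** quantifies the slow
component only: the *pupil trend*, a signed diameter change across a
window centered on a task event, computed from representations of the
signal that suppress everything faster than the window.

Three estimators are provided, all linear in the input and all invariant
to constant offsets:

- **Smoothed trend.** The series is averaged over a centered boxcar of
  $w \in \{5, 10, 15\}$ s; the trend at event time $t_0$ is the smoothed
  value at $t_0 + w/2$ minus at $t_0 - w/2$, identically the mean over
  $[t_0, t_0 + w]$ minus the mean over $[t_0 - w, t_0]$. Positive values
  mean dilation across the event.
- **Conservative trend.** Means over $[t_0 + 2, t_0 + 12]$ s minus
  $[t_0 - 12, t_0 - 2]$ s (a 14 s span with a 10 s window per side). Any
  signal confined to within 2 s of the event — in particular the phasic
  response and the luminance reflex — contributes exactly zero, by
  construction rather than by attenuation.
- **Decomposed trend.** The series is decomposed additively into
  components at dyadic timescales with a Symlet-4 wavelet filter pair; the
  trend at scale $s \in \{4096, 8192, 16384, 32768\}$ ms is the scale-$s$
  component at $t_0 + s/2$ minus at $t_0 - s/2$. This asks, per
  timescale, whether the slow fluctuation was rising or falling through
  the event.

## Preprocessing

Blink cores are runs of samples that are invalid, missing, or
non-positive. Eyelid closure contaminates neighbouring samples before the
tracker loses the pupil, so each core is grown outward while the
sample-to-sample difference exceeds `noise_k` (default 5) times the MAD of
first differences over the whole trace (cores masked out of the MAD). A
margin of 200 ms (configurable) is then added on each side, overlapping
segments are merged, and the segments are filled by linear interpolation
between the nearest retained samples; gaps touching a recording edge take
the nearest retained value. Samples outside the segments pass through
bitwise unchanged, and a per-sample mask records what was filled.

Interpolation keeps the series continuous for the window averages, but a
trial whose flanking window is mostly interpolated measures the
interpolant, not the pupil. A per-trial quality gate therefore rejects a
trend when more than `max_interp_frac` (default 0.5) of either flanking
window is interpolated. Windows that extend past the recording are flagged
*incomplete* rather than partially averaged.

## The wavelet decomposition

A decimated discrete wavelet transform is not shift-invariant: moving an
event by one sample can change a per-event two-point readout
substantially. The decomposition here is therefore a maximal-overlap
(stationary) transform with the Symlet-4 filters, whose per-level
reconstructions are exactly zero-phase (each detail operator is an
analysis stage followed by its transpose). Level $j$ carries fluctuations
at scale $2^j$ sample periods; at 1,000 Hz the details run from 2 ms up to
32,768 ms with a coarse approximation at 65,536 ms held at absolute
diameter level. The approximation plus all details reconstructs the input
to machine precision (the test suite requires $10^{-6}$ relative error).

Numerical choices: boundaries are mirror-padded by one coarsest
scale-length before the circular transform and cropped afterwards; event
readouts whose points fall within one scale-length of a recording edge are
flagged incomplete. At sample rates other than 1,000 Hz, scales are $2^j$
sample periods and reported in ms — rates whose period divides the target
scales dyadically (e.g. 125 Hz, period 8 ms) keep the conventional
4,096–32,768 ms labels exact.

One property worth knowing: a sinusoid whose period is exactly $2^j$
sample periods sits on the boundary between bands $j-1$ and $j$ and its
energy splits roughly evenly between them. Mid-band periods concentrate
their energy in a single component. Band-edge behaviour is a property of
any dyadic filter bank, not an artefact of this implementation.

## Trial bookkeeping and comparisons

Exclusions are flags, never deletions: misses, responses at or below
150 ms (anticipations and false alarms), incorrect responses where
correctness exists, and the first 5% of each participant's trials
(round-half-up of $0.05 N$; 116 trials give 6, 158 give 8). Keeping
excluded rows lets the accuracy contrast re-admit incorrect trials. For
the cued-flanker session of 96 trials the same rule gives 5 startup
trials; the fraction is left configurable for designs that used a
different startup count.

RT splits are computed per participant: the mean split sends RTs strictly
below the participant mean to *short* (ties to *long*, since "below
average" is strict); the quartile split takes RTs strictly below the 25th
and strictly above the 75th percentile, middle half unassigned, with
percentiles by linear interpolation (`stats::quantile` type 7 — group
membership near the quartiles depends on this, so it is fixed and
documented). Condition contrasts for the cued flanker compare center vs
no cue (alerting; double and spatial cues unassigned to avoid the cue
luminance confound) and congruent vs incongruent targets (executive;
neutral unassigned).

The unit of analysis is the participant: trends are averaged per
participant × group, compared with a paired one-tailed $t$ (alternative:
first group below second), with paired Cohen's $d$ = mean / sd of the
differences (so $|d| = |t|/\sqrt{n}$; the pooled-sd variant is reported
alongside). Benjamini–Hochberg FDR adjustment is applied across the
family of smoothing windows within one contrast — these are strongly
correlated readouts of the same signal — while conservative and
decomposed p-values are reported uncorrected. Zero-variance differences
are flagged degenerate with limit p-values rather than an error.

## The synthetic generator

No recordings ship with the package; the generator produces sessions with
exactly the statistical structure the analysis assumes, which makes
parameter recovery — not numerical agreement with any particular dataset
— the validation surface.

The latent "suboptimality" state $s(t)$ is an Ornstein–Uhlenbeck process
(mean 0, stationary sd `state_sd` = 1, mean-reversion `theta` = 0.05/s,
i.e. a 20 s autocorrelation time so that 10 s windows sit within one
state excursion). The tonic pupil component integrates the state:
baseline + $\alpha \int s\,dt$ with $\alpha$ = 2 px/s per unit state —
integration is the simplest coupling under which a window-differenced
trend tracks the state itself. On top of this: a gamma-shaped
event-locked constriction (peak −40 px, shape 2, scale 250 ms, truncated
at 2 s so the conservative trend is provably immune), white measurement
noise (6 px), a constant per-eye offset (sd 20 px), and blinks (15/min,
100–400 ms, zeroed with validity cleared). Reaction times are
$\mathrm{rt} = \mathrm{rt}_0 + \beta s(t_i) + \varepsilon$, floored at
180 ms, so suboptimal states are slow states — the direction the analysis
is designed to detect. Session designs mirror the three studied tasks:
vigilance (29 latency periods of 1,000–8,000 ms in 250 ms steps, 4 trials
each), two-back (158 trials at a 3.5 s pitch), and cued flanker (96
trials, four cue types at 25%, three target types, with the published RT
orderings as condition main effects).

The coupling $\beta$ is the one calibrated constant: with the other
defaults fixed a priori, $\beta$ = 8 ms per unit state makes the default
17-participant vigilance cohort yield a paired $d \approx -0.8$ on the
10 s smoothed short-vs-long contrast — the generator's stated design
target, a moderate-to-large effect at which an $n = 17$ one-tailed test
has high but not saturated power. Seeds fully determine output; the same
config reproduces a cohort byte-for-byte.

What the generator does *not* emulate: pupil foreshortening and gaze
dependence, luminance-driven baseline shifts, non-stationary fatigue
drifts across a session, asymmetric or partial blinks, and any
physiologically detailed impulse response. Passing recovery therefore
shows the pipeline detects the modelled slow-state coupling at realistic
noise levels — not that real recordings satisfy the model.

## Problem sizes

Recovery experiments and the bundled demo run at 125 Hz rather than
1,000 Hz. The sample period of 8 ms keeps every analysed dyadic scale
(2^9–2^12 samples = 4,096–32,768 ms) exactly aligned with its
millisecond label while making replicate cohorts cheap: the package's
validation uses 100 coupled and 200 null cohorts of 17 participants ×
116 trials. All trend indices are window averages or band-limited
readouts far below 62.5 Hz, so the reduced rate does not change what is
being measured; the generator's default remains 1,000 Hz for
sessions meant to resemble the original recordings.

## Known limitations

- The blink detector's flank rule is a stand-in for noise-robust
  onset/offset capture in general; trackers with different noise
  signatures may need `noise_k` retuned.
- Pixel units are tracker-specific; the mm conversion is a single-point
  linear calibration (3,300 px = 4.5 mm by default) and should be treated
  as indicative, not metric.
- Binocular averaging happens at the index level (one trend per eye, then
  averaged), with a monocular fallback when one eye fails the quality
  gate.
- BH-adjusted p-values are monotone and capped but not idempotent under
  re-adjustment; adjusted values should not be fed back through the
  correction.

## A minimal run

```{r demo, eval = FALSE}
demo <- system.file("extdata", "demo_config.yaml", package = "pupiltrend")
res <- cmd_run_all(demo, out_dir = tempfile())
res$results[, c("method", "scale_ms", "t_stat", "p_one_tailed", "p_fdr",
                "cohens_d")]
```
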