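---
title: "Detecting chirps, rises and jamming interactions in pulse-type electric fish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chirps, rises and jamming interactions in pulse-type electric fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirpjar)
```

## The measurement problem

Pulse-type gymnotiforms discharge their electric organ at a very regular
rate; the discharge (EOD) itself lasts only 1–3 ms, so most of each cycle is
silent. When two fish of similar frequency are near each other, their
relative pulse timing precesses slowly through the beat cycle, and
interference is concentrated in a narrow phase band: a conspecific pulse
arriving within roughly 60° *before* a fish's own EOD falls in its most
sensitive (and most jammable) epoch, while pulses shortly *after* the EOD
are nearly harmless. Electromotor behaviors that reshape this phase
relationship — rate shifts, chirps, interruptions — are therefore at once
communication signals and jamming maneuvers.

`chirpjar` turns a single-channel playback recording (subject S1 plus a
synthetic conspecific S2 delivered at a fixed period) into event tables and
phase-interaction summaries. This vignette documents the models and rules
each stage implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
conventions adopted where the underlying definitions leave freedom.

## Interval statistics and the chirp rules

All rate analysis runs on the inter-pulse-interval (IPI) series. For
interval $i$, the instantaneous frequency is $1/\mathrm{IPI}_i$ and the
**rIPI** is the percent shortening relative to the preceding interval,

$$\mathrm{rIPI}_i = 100\,\frac{\mathrm{IPI}_{i-1}-\mathrm{IPI}_i}
{\mathrm{IPI}_{i-1}},$$

positive when the interval shortens. Resting trains have rIPI standard
deviations of a few tenths of a percent, so the chirp statistic is nearly
noise-free.

**Chirp start.** Any interval with rIPI above the detection threshold that
is not already inside a previously delimited chirp starts a chirp. The
threshold defaults to 10%; `trial_config("brachy")` raises it to 25% for
dischargers whose ordinary behaviors already reach 5–10% rIPI.

**Chirp extent and end.** The chirp body is the maximal run of intervals
shorter than $(1-\theta/100)$ times the local pre-chirp IPI (mean of the
three preceding intervals; the three following intervals when the chirp
falls within the first five intervals of a trial). The chirp ends when the
frequency returns to within 10% of the *post-chirp steady-state rate*,
measured as the mean frequency over five intervals beginning at least 50 ms
after the chirp body. Referencing the end to the post-chirp rate matters
for species that follow a chirp with a sustained plateau above the
pre-chirp baseline: the chirp ends at the plateau rather than running on
until the plateau decays. If the trial ends first, the chirp is kept and
flagged truncated.

**Metrics.** Against the 3-EOD local baseline the package reports the
maximum IPI reduction, peak frequency (inverse of the shortest chirp
interval), maximum EOD amplitude reduction and the times to both maxima;
plus duration in EODs, seconds and S2 cycles (duration divided by the S2
period — the receiver-centric unit that allows cross-species comparison),
the S2 phase of the first chirp EOD, and latency from the first S2 pulse.
Chirps starting strictly less than 100 ms after the first S2 are flagged
short-latency (startle-like). Ties between equal rIPI maxima resolve to the
first occurrence.

**Burst episodes.** Chirp-like intervals separated by at most
`burst_max_normal_gap = 2` normal intervals ("fewer than three") merge into
burst episodes of at least two chirp-like intervals. Episodes are reported
independently of chirps and rises: a multi-interval chirp necessarily
contains adjacent chirp-like intervals and thus also registers as a minimal
episode. The rules are deliberately not made exclusive, because the
behaviors form a continuum from isolated chirps through burst-like chirping
to tumultuous rises.

## Tumultuous rises and interruptions

A **tumultuous rise** is a sustained epoch that combines a large baseline
frequency increase with dense chirp-like intervals. Two block statistics
are computed: the coefficient of variation (CV) of instantaneous frequency
in 200 ms blocks with 50% overlap, and a running baseline as a 20-interval
centered moving average. A rise is any maximal span where CV > 5 *and* the
running baseline exceeds 1.25× the pretest mean, lasting longer than
500 ms. The CV is read as a percentage (CV of frequency × 100): a raw CV
above 5 would require interval variability far beyond anything a pacemaker
produces, so the percent reading is the only physically sensible one. CV is
computed on instantaneous frequency rather than IPI; at these jitter levels
the two differ negligibly, but one convention is required. No smoothing is
applied across blocks.

The rise end is extended to where the running baseline returns to within 5
pretest standard deviations of the pretest mean. The same band rule is
applied symmetrically at the start: the detected core necessarily begins
where the running baseline crosses 1.25× pretest — partway up the ramp —
so walking the start back to the 5 SD band recovers the true onset. With
this convention, injected rises are recovered with both boundaries inside
one 200 ms CV block of ground truth. `mean_rise` is the running baseline at
the temporal midpoint minus the pretest mean; `peak_rise` the maximum
running baseline during the rise minus the pretest mean. Note that the
interspersed chirp-like intervals pull the moving average above the
injected ramp height by several percent; the reported `mean_rise` reflects
the discharge actually produced, not the generator's ramp parameter.

**Interruptions** are abrupt silences of tens of milliseconds that begin
with a deformed, strongly reduced EOD and a burst of high-frequency
desynchronized "hash". Detection is rate-based: any inter-pulse gap larger
than `gap_factor = 2.5` times the local median IPI (rolling 21-interval
median) is an interruption. The factor separates the observed silence
durations (≈ 40–90 ms) from ordinary IPIs (≈ 13–25 ms) with a wide margin
on synthetic data. When the recording is available, the hash end is the
last time inside the gap where the 2 ms-window RMS exceeds three times the
silent-period noise floor (estimated from the final quarter of the gap); a
3 ms guard band at each gap edge keeps the bracketing EODs out of both
estimates.

## Phases and the jamming index

Every S1 pulse after the first S2 receives a phase
$360\,(t-t_{\mathrm{prev\,S2}})/T_{S2}$ degrees, wrapped to $[0,360)$; an
S1 exactly at an S2 time is 0°. Within the 120° critical window around
coincidence, with $n_\mathrm{prior}$ phases in $[300°,360°)$ and
$n_\mathrm{after}$ in $[0°,60°)$ (half-open on both ends),

$$\mathrm{JI} = \frac{n_\mathrm{prior}-n_\mathrm{after}}
{n_\mathrm{prior}+n_\mathrm{after}} \in [-1,1],$$

undefined (and flagged) when no phase falls in the window. +1 means every
critical-window S1 lands just before the S2 — S1 jams the stimulus; −1 the
reverse.

The trial is tiled with 400 ms windows at 50% overlap anchored at the trial
start; a final partial window is reported flagged rather than dropped. Each
window's JI is z-scored against the standard deviation of 10 000 uniform
phase shuffles with the same number of S1 pulses; shuffles with an empty
critical window are redrawn, matching the pulse count entering the
statistic. Windows with $|z| > 1.96$ are significant, two-sided, with the
sign giving the jamming direction — both directions are behaviorally
meaningful, so a one-sided reading would discard half the phenomenon. The
null SD depends only on the pulse count, so profiles simulate one null per
distinct count rather than per window; `jamming_null_z()` performs the
single-window computation.

Because the index is a ratio of small counts, its null distribution is
discrete, and the z-test's realized size is not exactly 5%: over windows of
5–30 pulses the empirical flag rate on uniform phases is ≈ 4–5% (measured
in the test suite), with very small windows unable to reach significance at
all ($|JI|\le 1$) and mid-size windows slightly anti-conservative. The
1.96 criterion is retained as the operative definition.

**Circular statistics.** Chirp start phases are summarized by the mean
vector direction, resultant length $r$, circular SD $\sqrt{-2\ln r}$ (in
degrees) and the Rayleigh uniformity test with the standard approximation
$p = \exp\!\big(\sqrt{1+4n+4(n^2-R^2)}-(1+2n)\big)$, $R = nr$. Per-trial
summaries use chirp *start* phases (not every EOD within a chirp) — the
start is the timed event; trials with fewer than two chirps are excluded
from within-trial dispersion statistics but still pool into per-subject
summaries, which equal the circular summary of the concatenated angles.

## The synthetic-trial generator

`synth_trial()` emulates the statistical structure of a playback trial and
carries full ground truth, so every detector is validated by
injection-recovery rather than against unavailable animal recordings. Its
defaults are the study conditions: baselines in the 20–90 Hz range
(default 55 Hz), frequency offsets dF within ±16 Hz, S2 amplitude 80–100%
of the subject's peak (default 0.9), trials of 10 or 15 s, and the
acquisition rate 48 828.125 Hz.

* **Baseline trains** draw independent Gaussian IPIs with a given CV,
  truncated at 0.2× the mean. Baseline rIPI SD relates to the IPI CV as
  $\sigma_{\mathrm{rIPI}} \approx 100\sqrt{2}\,c$ for independent jitter;
  a CV of ≈ 0.0019 reproduces the ≈ 0.27% resting rIPI SD typical of a
  highly regular discharger, and the generator default (0.002) sits there.
* **Chirps** shorten $n-1$ consecutive intervals by stated percentages of
  the pre-chirp IPI and scale the $n$ EOD amplitudes; later pulses shift
  earlier by the time removed. `chirp_profile()` provides presets:
  single-interval (the modal chirp), a ramp, and a long chirp with deep
  constant IPI reduction and a mid-chirp amplitude minimum.
* **Rises** rebuild the train inside the window from an instantaneous
  frequency that follows a piecewise-linear up/plateau/down ramp (edges
  15% of the duration each) with chirp-like intervals interspersed at a
  fixed rate (default 15.61 s⁻¹, reduction 35%). The ramp shape is a
  modeling choice; recordings show smooth rises without fixing a form.
* **Interruptions** remove all pulses in the silence; the last preceding
  EOD is re-timed to the silence onset with its amplitude reduced to 0.3
  (the deformed EOD that begins real interruptions) and the resuming train
  is shifted so discharge restarts exactly at the end of the silence. The
  first half (configurable) of the silence is marked as hash and rendered
  as high-pass-filtered Gaussian noise peak-scaled to 10% of the EOD peak.
* **Rendering** sums template-shaped S1 pulses (the biphasic template is
  given a head-positive asymmetry so its largest-magnitude extremum — the
  fiducial point for both rendering and detection — is unambiguous), S2
  pulses at the calibrated amplitude, hash spans, and Gaussian sensor
  noise. The template peak aligns to the scheduled pulse time, so detected
  times match ground truth to within one sample.

What the generator does **not** emulate: electrode geometry and water
conductivity (amplitudes are abstract), motion of a free-swimming fish
(real recordings show motion-induced amplitude modulation), within-chirp
IPI microstructure beyond the preset profiles, and any closed-loop
dependence of the fish's behavior on the stimulus — events are injected at
configured times. Passing injection-recovery therefore demonstrates the
detectors' correctness under the stated noise model, not robustness to
every artifact of real recordings.

## Artifact subtraction and pulse detection

The S2 artifact is removed using the programmed stimulus timings and the
known template. Each pulse's amplitude is fitted by least squares over the
template support; because the playback amplitude is constant within a
trial, the default subtracts the *median* fitted scale at every pulse. The
median makes the subtraction immune to the minority of S2 pulses that
coincide with a subject EOD: their individual fits are contaminated by the
EOD, and subtracting a contaminated scale would deform the EOD and shift
its apparent time by up to a millisecond — enough to masquerade as
chirp-scale rIPI noise. A `per_pulse` mode retains the raw fits (useful
when the artifact amplitude genuinely drifts). Subtraction is idempotent;
amplitudes (not times) of S1 EODs coincident with an S2 remain unreliable
and downstream amplitude metrics should be read accordingly.

Pulse detection thresholds at 0.3× the recording's maximum absolute
amplitude and merges threshold crossings closer than the refractory period
(default 1 ms, half a typical EOD) before taking the largest-magnitude
extremum as the pulse time; the event amplitude is peak-to-peak within
±2 ms. The pulse time is defined as the largest extremum because the
original acquisition does not fix a fiducial point; any consistent choice
works for interval analysis.

## Numerical conventions and degenerate inputs

* Sample rate is a parameter throughout (default 48 828.125 Hz); the
  duration-in-samples of a rendering is `round(duration × rate)`.
* Half-open conventions: S2 schedules cover $[0, T)$; phase 0° at
  coincidence; jamming windows $[300°,360°)$ and $[0°,60°)$; short-latency
  strictly `< 100 ms`.
* An all-zero recording detects as an empty train (not an error); a trial
  with fewer than two pulses yields an empty report with a warning.
* `baseline_stats()` requires at least 10 intervals per window; rIPI of the
  first interval is `NA` by construction.
* All stochastic operations accept a seed; `run_trial()` derives the
  permutation-null seeds from `trial_config(seed=)`, and identical inputs
  plus seed give byte-identical reports.
* Problem sizes in the test suite were chosen to exercise each claim at
  meaningful power while keeping the default run fast: 100 fifteen-second
  trials for chirp injection-recovery (300 chirps), a 5 × 3 grid of rise
  heights (25–100%) and durations (1.5–10 s), 1000 s of stationary train
  for the false-positive checks, and 10 000 simulated windows for the null
  calibration.

## Known limitations

* The chirp-body rule assumes chirp intervals stay at least the threshold
  fraction shorter than the local baseline; a chirp ramping *into* a
  plateau more than ~33% above baseline (with the 25% threshold) could
  absorb plateau intervals into the body.
* Rise boundaries inherit the smoothing of the 20-interval moving average;
  at very slow ramps the 5 SD crossing lags the true onset by a fraction
  of the ramp.
* The jamming z-test's size is approximate at small pulse counts (see
  above); interpret isolated significant windows with few pulses
  cautiously.
* Interruption detection is purely rate-based and will flag any long gap,
  whatever its cause; the hash measurement, not the gap rule,
  distinguishes a true hushing silence.
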