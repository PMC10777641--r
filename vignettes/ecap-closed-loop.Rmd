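---
title: "ECAP analysis and closed-loop stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECAP analysis and closed-loop stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecapscs)
```

## The problem this package addresses

Spinal cord stimulation (SCS) doses in preclinical work are usually set
relative to the motor threshold (MT), a coarse behavioural landmark. The
evoked compound action potential (ECAP) — the summed response of the
dorsal-column fibres recruited by each stimulation pulse, recorded
epidurally as a triphasic P1/N1/P2 waveform — offers an objective,
per-pulse readout of fibre activation. Closed-loop (CL) SCS measures the
ECAP after every pulse and adjusts the next pulse's current to hold the
ECAP amplitude at a target, compensating for the changes in
electrode-to-fibre coupling that posture shifts cause in a freely behaving
animal; open-loop (OL) SCS holds the current fixed and lets the amplitude
fluctuate.

`ecapscs` implements the full analysis chain for such experiments —
triphasic feature extraction, input–output (IO) recruitment fitting with
threshold extrapolation, conduction-velocity (CV) estimation, pulse-on-pulse
closed-loop simulation, and the behavioural statistics (von Frey, acetone)
— together with a synthetic-data generator so that every stage can be
exercised and validated without access to recordings.

## The synthetic plant

The generator is a *stated world*: its defaults encode the experimental
conditions of the six-contact rat preparation (contacts every 4 mm,
stimulation over T13, 30 kHz sampling) and published cohort-level
parameters, and the analysis code is validated against the generator's
bookkeeping.

**Recruitment.** Above the ECAP threshold current $I_{\mathrm{ECAPT}}$ the
N1–P2 amplitude at the closest recording contact grows linearly:
$$A(I) = g \, s \, \max(I - I_{\mathrm{ECAPT}}, 0),$$
with slope $s$ (mV/mA) and a multiplicative posture gain $g$. Sham
defaults are $s = 20.53$ mV/mA, $I_{\mathrm{ECAPT}} = 0.038$ mA,
$I_{\mathrm{MT}} = 0.082$ mA, CV 20 m/s; the nerve-injured (SNI) preset
uses lower thresholds (0.026 / 0.065 mA), slope 23.56 mV/mA and slower
conduction (15 m/s), matching the direction of the reported group
differences.

**Distance attenuation.** Amplitude falls off with distance $d$ from the
stimulation contact as a single exponential anchored at the closest
contact, $A(d) = A_{4\,\mathrm{mm}} e^{-(d-4)/\lambda}$. No functional
form is established for this fall-off; the single exponential is the
simplest monotone law, and $\lambda \approx 3.9$ mm is calibrated once by
least squares to the reference profile (0.63, 0.20, 0.09, 0.08) mV at
(4, 8, 12, 16) mm (`calibrate_decay_length()`).

**Waveform.** Each ECAP is a sum of three Gaussian lobes (positive P1,
negative N1, positive P2; lobe SD 0.12 ms, separation 0.35 ms), numerically
re-centred so the N1 minimum sits exactly at the nominal latency and
rescaled so the N1-to-P2 excursion is exactly the recruitment amplitude.
The N1 latency at distance $d$ is $t_0 + d/\mathrm{CV}$, where $t_0$
(default 1.2 ms) is a fixed utilisation delay: because of it a
single-channel latency over-estimates the travel time, and CV must be
estimated from latency *differences* across contacts — exactly as in the
real analysis. With the sham defaults the 4-mm N1 lands at 1.40 ms, inside
the reported 1.373–1.433 ms band. A sharp decaying transient (time
constant 0.06 ms) models the stimulation artifact; it is dominant on the
stimulation channel and essentially extinguished after 0.5 ms elsewhere.

**Posture gain.** The log gain follows a discretised mean-reverting
(Ornstein–Uhlenbeck) process with stationary SD `gain_volatility`
(default 0.2) and correlation time `gain_tau_s` (default 5 s), exponentiated
with a $-\sigma^2/2$ correction so the stationary mean is exactly 1. The
defaults state a world where posture shifts modulate coupling by ±20%
over seconds — enough to make the OL/CL contrast meaningful. Neither value
is published; they were chosen once on plausibility grounds.

**What the generator does not emulate.** Electromyographic or
post-synaptic ("slow") components superimposed on the ECAP, electrode
impedance drift, movement artifacts with spectral structure (noise is
white), heteroscedastic recording noise, or any biology linking the plant
to behaviour. A green test therefore establishes that the analysis
recovers the stated generative quantities under realistic noise — not that
it would be robust to every pathology of real recordings.

## Feature extraction

Within a search window (default 0.5–5 ms, after a 0.5 ms artifact
blanking; neither is stated in the source methods) the N1 peak is the most
negative sample, P1 the largest sample before it, P2 the largest after it;
plateau ties break to the earliest sample for determinism. The amplitude
is $|P2 - N1|$. The noise floor is the SD of the final 20% of the sweep.

**Detection.** A feature set is a detectable ECAP when its amplitude
exceeds $k$ times the noise floor (default $k = 3$) *and* the latencies
order P1 < N1 < P2. One subtlety is load-bearing: the peak-to-peak range
of pure noise over a ~4.5 ms window at 30 kHz is about 5 noise SDs
regardless of the noise level, so the 3-SD rule cannot work on a single
raw sweep. Detection decisions are therefore made on the across-pulse
*averaged* waveform compared against the *single-sweep* noise floor:
averaging $n$ sweeps leaves a genuine ECAP untouched while shrinking noise
extrema by $\sqrt{n}$, so a noise-only average falls below the floor from
roughly $n \ge 4$ while a true response near threshold does not. This
mirrors what visual detection on a streaming display achieves.

**Sub-sample latencies.** At 30 kHz one sample (33 µs) is ~9% of the
4-mm propagation delay at 20 m/s, so discrete peak times quantise CV
badly. `feature_table()` refines each landmark latency by the vertex of a
parabola through the peak sample and its neighbours (the standard
estimator for band-limited waveforms); `extract_features()` keeps the
literal most-negative-sample contract by default (`refine = "none"`).

## IO fitting and thresholds

`fit_io()` reproduces the offline pipeline: the raw (current, amplitude)
points from the first sustained observable ECAP to MT are interpolated
with a cubic smoothing spline, 200 evenly spaced points are sampled from
the spline, and an ordinary least-squares line is fit to the *interpolated*
points — statistically unusual, but preserved because that is how the
original analysis was run. The slope is the recruitment slope, the
x-intercept the extrapolated ECAPT, and R² comes from the linear stage.
Currents are additionally rescaled so 0 is the extrapolated ECAPT and 1 is
MT.

The smoothing parameter follows the MATLAB `csaps` convention the original
toolbox used: the spline minimises
$p \sum_i (y_i - f(x_i))^2 + (1 - p) \int f''^2$, so $p = 1$ interpolates
and $p \to 0$ tends to the least-squares line; 0.95 means strong fidelity
with mild smoothing. It is mapped onto `stats::smooth.spline` via
$\lambda = (1 - p)/p$. The exact basis of the original "assumption-free
spline" is unknown; for the near-linear IO data the choice is immaterial
(the roughness penalty vanishes on straight lines, so no smoothing level
can flatten a genuinely linear curve).

**Observed vs extrapolated threshold.** `observed_ecapt()` is the
surrogate for the visually observed threshold: the smallest current of an
ascending staircase from which detection *persists* to the top of the
staircase. The persistence requirement matters with finite averaging —
isolated noise flickers below threshold occasionally pass any fixed
SD-multiple rule, and a human observer would not call them a threshold;
recruitment is monotone above threshold, so a genuine ECAP never
un-detects. `sustained = FALSE` gives the literal first-detectable rule.

**IO staircases and the gain.** A 21-step staircase at 50 Hz lasts about
two seconds — far below the 5-s gain correlation time — and the CL target
is set from the same recording minutes later, so `synth_io_curve()` holds
the posture gain frozen at its calibration reference (1) and IO fixtures
carry additive recording noise only. This is also the only reading under
which the published IO quality (R² 0.98 ± 0.01 at 50 Hz) is reproducible;
`gain_process = TRUE` re-enables drift for sensitivity studies.

## Conduction velocity

`estimate_cv()` regresses per-channel N1 latency (averaged across pulses)
on contact distance over the three antidromic contacts closest to the
stimulation site and reports velocity as the reciprocal slope (mm/ms ≡
m/s). Any fixed onset delay cancels in the slope. The N1 peak is used as
the timing landmark (the source does not say which landmark was used; N1
is the most robust extremum). Non-increasing latency with distance is a
propagation-direction error, fewer than two detected contacts an
insufficient-data error.

## Closed-loop simulation

The commercial controller's law is unpublished; the package implements the
minimal law consistent with its described behaviour — an integral update
$$I_{n+1} = \mathrm{clip}\big(I_n + K_i (A^\ast - A_n),\; \pm\delta\big)
\quad \text{clamped to } [0, I_{\mathrm{cap}}],$$
with exactly one update per pulse (50 adjustments per second at 50 Hz).
Defaults: loop gain $K_i s = 0.4$ (geometric convergence holds for
$0 < K_i s g < 2$), step cap $\delta = 0.005$ mA, and
$I_{\mathrm{cap}} = I_{\mathrm{MT}}$, reflecting the ECAPT-to-MT
therapeutic window. The update rule is swappable
(`run_session(update_fn = )`). OL and CL sessions sharing a seed share the
identical gain and noise realisations, which is what makes paired
variance comparisons exact rather than statistical.

`summarize_session()` applies the 3-SD outlier rule as a *single pass*,
independently to amplitude and current, excluding a record that is an
outlier on either variable; the source does not state whether the rule was
iterated or joint, and the single-pass union is the most conservative
simple reading. Amplitude-error and current-minus-ECAPT histograms are
computed on the included records, and the mean amplitude is reported as a
percentage of the amplitude at MT.

## Behavioural statistics

`withdrawal_threshold()` implements the 60% (3-of-5) rule over the
ascending von Frey series with the 26 g cutoff, and `log_transform()` the
×10,000 log10 scale. The omnibus test is a two-way repeated-measures
ANOVA (group between, timepoint within, animal as error stratum), whose
interaction carries the df structure (30, 186) reported for 37 animals.
Post-hoc group contrasts at planned timepoints are Welch t-tests —
inferred from the fractional post-hoc dfs in the source, which equal-variance
tests cannot produce — Bonferroni-corrected over the planned-contrast
family (`default_contrasts()`; the family is configurable because its size
is not stated). Windowed AUCs (0–30 and 30–60 min) use the trapezoidal
rule on raw endpoint values and a one-way ANOVA whose post-hocs use the
pooled residual variance, matching the integer dfs reported there.

The behavioural generator draws per-animal normal deviates around per-cell
means that state the design: shared healthy baseline at BS1, the reported
group means at BS2 (5.01/5.11/5.23 vs 3.13/3.48/3.76 log units), rescue of
SNI SCS-ON only during stimulation, washout after. Cell SDs (0.25 log
units; 2 s for injured, 0.1 s for sham acetone latencies) are on the order
of the SEM-implied cohort SDs. Thresholds are clamped at the cutoff and
latencies truncated at zero, so extreme cells are mildly non-normal — a
feature shared with the real bounded endpoints.

## Numerical choices and degenerate inputs

* Plateau ties in peak search break to the earliest sample; flat traces
  return amplitude 0 and are undetectable.
* Fewer than four unique currents fall back from the smoothing spline to a
  natural interpolating spline; fewer than three points refuse to fit.
* Non-positive IO slope is a degenerate-recruitment error; an x-intercept
  at or beyond MT warns of inconsistent thresholds.
* A conduction velocity too slow for the sweep window is rejected at
  synthesis time rather than silently truncating the N1.
* All generators take explicit seeds and are bit-reproducible; `gain_trace`
  with zero volatility returns exactly 1.

## Known limitations

The controller is a stand-in for an unpublished proprietary law; the
detection rule is a surrogate for human judgement; the synthetic plant is
deliberately simple (white noise, lognormal gain, exact linearity above
threshold). Cohort-level published values that depend on unreleased
recordings (e.g. group CV means) are used only to parameterise
presets, never asserted as recovered facts.
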