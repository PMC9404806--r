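---
title: "Methods: spike-train rates, whisker kinematics, and resonance readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train rates, whisker kinematics, and resonance readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskres)
```

`whiskres` analyses two coupled signals from awake head-fixed mice:
the simple-spike (SS) and complex-spike (CS) activity of cerebellar
Purkinje cells, and the mean whisker angle tracked at 1 kHz, under
rhythmic optogenetic stimulation of either the Purkinje cells themselves
(SS-type drive) or their climbing-fiber input (CF-type drive). The package
implements the full analysis chain — instantaneous firing rate, whisker
event detection, time-frequency spectra, stimulation protocol, evoked
amplitude and entrainment measures — together with a synthetic-data
generator so every stage can be exercised and validated without any
recording.

## Instantaneous simple-spike frequency

Spike times are binned into a logical 0/1 vector at 1 kHz (half-open 1 ms
bins; two spikes in a bin would still yield a single 1, but the 3 ms
refractory period enforced by quality control makes the logical and count
conventions identical). The rate estimate is the convolution of this
vector with a composite smoothing kernel: the elementwise mean of two
Gaussians $e^{-x^2/(2n^2)}$ with $n = 8$ and $n = 20$ samples, both on a
100-sample (0.1 s) support. The support is even, so the kernel is
evaluated on the half-sample-offset grid $x = -49.5, \dots, +49.5$, which
keeps it exactly symmetric with exactly 100 points. Each Gaussian is
normalized to unit sum before averaging and the convolution is scaled by
the sampling rate, the only convention under which a periodic train at
$r$ Hz reads $r$ Hz. The narrow component tracks fast rate transients,
the wide one stabilizes the estimate; a consequence worth knowing is that
for a perfectly periodic 50 Hz train the narrow component leaves a ripple
of about ±2.2 Hz around 50 in the interior of the trace (the tests pin
this down with a direct-summation oracle).

The rate trace is then band-passed at 3–25 Hz — the whisking band — with
a 4th-order Butterworth filter applied forward and backward
(`signal::filtfilt`), so there is no phase distortion and event timing
survives for stimulus alignment. The input is demeaned before filtering;
DC is deep in the stopband, and removing it first suppresses the
recursive filter's start-up transient. The first and last 50 ms
(half the kernel support) of any rate trace are flagged as
edge-contaminated.

Single-unit quality control follows the recording acceptance criteria:
minimum SS inter-spike interval 3 ms, an SS pause of at least 8 ms after
every CS, no run of more than three consecutive spikes whose waveform
amplitude or width deviates more than 3 SD from its mean, and at least
40 s of recording. All violated criteria are reported, not just the
first.

## Whisker kinematics

Angle traces are low-pass filtered at 30 Hz (4th-order zero-phase
Butterworth, filtered around the mean for the same transient reason as
above). Movement events are defined by the ±4° criterion: local extrema
of the filtered trace are found from sign changes of the first
difference (plateaus resolved to their midpoint, trace endpoints
included so a monotone ramp yields one event), sub-threshold wiggles are
pruned by repeatedly collapsing the smallest adjacent extremum pair
below 4°, and each remaining rising pair is a protraction, each falling
pair a retraction.

One refinement proved necessary: pruning alone connects the last whisk
of one bout to the first whisk of the next bout through the intervening
rest, producing a single "event" several seconds long whose amplitude
clears the threshold. Such swings are drift, not whisks — a whisker
half-cycle at the 3 Hz lower band edge lasts under 170 ms — so events
longer than `max_duration_ms` (default 400 ms) are discarded. With this
gate, movement periods recovered from synthetic whisking overlap the
generator's ground-truth bouts with a Jaccard index around 0.9; without
it the figure drops below 0.4. The price is that strictly global
alternation of event kinds can be broken across a discarded drift swing;
within any movement period events alternate.

Events separated by less than 250 ms (one inter-pulse interval at 4 Hz)
are merged into movement periods; the gap is a configuration parameter
because "period of movement" has no sharper operational definition.
Per-event kinematics are amplitude (endpoint angle difference), duration,
and maximum velocity from first differences — the 30 Hz low-pass already
suppresses frame noise, so no extra smoothing is applied. Whisk cycles
are counted as complete protraction–retraction pairs whose protraction
starts inside the query interval.

## Time-frequency spectra

Scalograms use the analytic Morlet wavelet with centre-frequency
parameter $\omega_0 = 6$ cycles, evaluated in the frequency domain (one
FFT of the signal, per-scale multiplication, inverse FFT) with the
standard $\sqrt{2\pi s/\delta t}$ per-scale normalization. The frequency
grid runs 1–30 Hz in 0.1 Hz steps — fine enough to express sub-integer
peaks. Samples inside the cone of influence (within the e-folding time
$\sqrt{2}s$ of either edge) are excluded from all time averages, so
boundary effects cannot inflate low-frequency power; on short windows a
low frequency can lose all its valid samples, in which case its power is
`NA` and it is ignored by peak extraction. Mean spectra can be
restricted to movement periods. Normalization divides by the maximum
(area normalization is available), peaks tie-break to the lower
frequency.

Two properties of this estimator matter for interpretation. First, it is
validated against an independent periodogram on stationary tones (same
argmax within one grid step of either estimator). Second, for a *damped*
transient the spectral line is broadened and slightly skewed, so the CWT
peak of a single free ring sits 0.2–0.3 Hz above the true damped
frequency; resonance-recovery checks therefore use a 0.5 Hz tolerance
rather than one grid step.

## Stimulation protocol

The paradigm uses 20 ms LED pulses at seven train frequencies. IPIs and
pulse counts are stored as a printed lookup table (0.5 Hz/2000 ms/10,
1 Hz/1000 ms/20, 2 Hz/500 ms/40, 4 Hz/250 ms/80, 8 Hz/125 ms/140,
14 Hz/77 ms/280, 28 Hz/35 ms/660) rather than derived from 20 s/IPI,
because the printed counts deviate from exact division at the higher
frequencies and fidelity to the protocol wins; a consistency warning
fires if a custom count strays more than 20% from the nominal 20 s
train. Sessions alternate ~20 s trains with ~10 s rests; the 0.5 and
14 Hz trains are given twice. The within-session order is not pinned
down by the paradigm, so the default (`0.5, 2, 14, 8, 28, 4, 1`, repeats
appended) is configurable.

## Stimulus-evoked responses and entrainment

Two amplitude definitions coexist deliberately. The *tuning curve* uses
the stimulus-averaged mean whisker trace per train: amplitude is max
minus min over one inter-stimulus interval (capped at 250 ms for trains
strictly below 4 Hz, so spontaneous whisks between widely spaced stimuli
do not contaminate the measure; at 4 Hz the IPI is 250 ms, making the
boundary inert). The *entrainment* analysis instead uses the raw
single-trial trace, stimulus by stimulus, for the first 15 stimuli (10
at 0.5 Hz — the total count at that frequency), because averaging would
erase the within-train growth it is trying to measure. The entrainment
slope is the OLS slope of amplitude against 1-based stimulus index; the
last epoch of a train extends one nominal IPI past its onset. Slopes are
compared between drive types with a two-sided paired t-test, paired by
stimulation frequency; the zero-variance degenerate case is reported
with an explicit flag rather than an error. Spectra 1 s before the last
stimulus onset and 1 s after the last pulse end test whether oscillation
outlives the train at the drive frequency.

## The synthetic plant and what it does (not) emulate

The whisker is modelled as a linear second-order underdamped oscillator
$\ddot{x} + 2\zeta\omega_n\dot{x} + \omega_n^2 x = \omega_n^2 u(t)$,
integrated with the exact zero-order-hold discretization (closed-form
matrix exponential per 1 ms step — stable at arbitrary durations, unlike
naive Euler). `resonance_freq_hz` parameterizes the *damped* ringing
frequency, $\omega_d = 2\pi f_{res}$, with
$\omega_n = \omega_d/\sqrt{1-\zeta^2}$, so free ringing genuinely occurs
at the named frequency (8 Hz by default, $\zeta = 0.25$).

Each LED pulse injects a rectangular 20 ms command (mirroring the pulse
width). SS-type drive adds one echo command 125 ms later at 0.7 relative
gain — a minimal stand-in for a premotor loop reverberating with a
~125 ms period; CF-type drive has no echo. The drive gain default of
7° steady-state deflection was chosen once so that a single pulse evokes
a ~5° protraction and cycle excursions fall in the 8–14° peak-to-peak
range typical of spontaneous whisks, while the third half-cycle of the
free decay stays below the 4° detection threshold — that is what makes
CF-type drive read out as exactly one cycle per pulse and SS-type as
two. Optional per-stimulus multiplicative gain growth
(`entrain_increment`, index from 0) produces a linear amplitude trend
for the entrainment analysis. Measurement noise (0.3° SD, Gaussian) is
added last.

Because the plant is linear, driving it near resonance rings it up over
the first few stimuli even with no entrainment gain: at 14 Hz drive the
first-15-stimuli slope is visibly negative (decaying beat transient),
at 8 Hz slightly positive. Entrainment properties are therefore tested
at 4 Hz, where each 250 ms epoch outlasts the ~77 ms decay time and
epochs decouple; there the residual startup trend is below 1% of the
mean amplitude per stimulus. Likewise, the moved-resonance recovery
control uses CF-type drive: with the echo loop on, the fixed 125 ms echo
itself pins the spectral readout to 8 Hz regardless of the plant — which
is precisely the resonance-vs-loop dissociation the analysis is built to
expose, but makes the SS variant useless as a parameter-recovery
control.

Spontaneous whisking alternates exponential rests (rate 0.3/s) with 1–2 s
bouts: a sinusoid at 8 Hz under a tapered-cosine envelope, flat over the
central 80% of the bout, peak amplitude 8°. The flat envelope keeps
nearly the whole bout above the ±4° criterion, which is what makes
bout-interval recovery a meaningful test. Synthetic spike trains draw SS
times from an inhomogeneous point process at
$r(t) = r_0(1 + m\sin 2\pi f t)$ (defaults $r_0 = 60$ Hz, $m = 0.5$,
$f = 7$ Hz — inside the observed 5–10 Hz band of SS-rate peaks), thinned
to a 3 ms refractory period, with 1 Hz Poisson CS and an 8 ms SS pause
after each — so every generated train passes quality control by
construction.

What the generator does *not* emulate: muscle and tissue nonlinearity,
inter-animal variability, whisker-tracking artifacts, slow postural
drifts, or any biophysics of the Purkinje-cell-to-premotor pathway. A
passing pipeline therefore demonstrates that the *procedures* recover
known ground truth under the assumed signal structure, not that real
recordings would yield any particular value.

## Problem sizes and numerical choices

Tests and the acceptance script run full printed trains (e.g. 80 pulses
at 4 Hz, 20 s) and whole nine-train sessions for the tuning curve;
spike-train recoveries use 40–60 s simulations. Scalograms of such
segments (≤ 65k samples × 291 frequencies) take a few seconds each in
the FFT formulation. Convolution uses FFT via `stats::convolve` and is
checked against an O(nm) double loop to 1e-9; the OLS slope is checked
against its closed form to 1e-12; the discretized plant propagator is
checked against an independent Padé matrix exponential. Ties in peak
extraction resolve to the lower frequency; degenerate inputs (empty
spike lists, flat traces, all-zero spectra, zero-variance slope
differences) are exercised explicitly in the test suite.
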