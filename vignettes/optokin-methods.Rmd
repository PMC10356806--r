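---
title: "Models and methods behind optokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

optokin analyzes two kinds of recordings from optogenetic experiments on the
cerebellar flocculus: 2-D video-tracked eye position during LED stimulation of
Purkinje-cell (PC) subpopulations (at rest and during vestibulo-ocular /
optokinetic stimulation), and PC spike trains recorded in vivo around the same
LED epochs or ex vivo during current-injection steps. Because such recordings
are rarely deposited, the package ships a synthetic-data module whose traces
have closed-form ground truth; every analysis stage is validated against that
truth rather than against intermediate outputs of the pipeline itself.

## The evoked-movement kernel

An optogenetically evoked eye movement is modeled on the magnitude axis
(the scalar displacement $\sqrt{h^2+v^2}$) as a pulse-step-like kernel. With
LED onset at $t=0$, duration $D$, and intensity fraction $s$:

* during the LED: $m(t) = s\,[A_d (1 - e^{-t/\tau_d}) + v_h t]$ — a fast
  saturating **drive** component plus a slow linear **hold** creep;
* after offset ($\Delta = t - D$):
  $m(t) = r\,e^{-\Delta/\tau_r} + (m(D) - r)\,e^{-\Delta/\tau_{rec}}$, where
  $r = \min(s A_r, m(D))$ — a fast **release** collapsing onto a slow
  **recovery** exponential that decays to zero.

This shape was chosen because it reproduces the characteristic velocity
signature of the recordings it emulates — a velocity peak just after LED onset
and another just after offset — while keeping every per-phase summary
available in closed form. The scalar kernel is projected onto a unit direction
vector (horizontal naso-temporal positive, vertical downward negative, default
$(2,-1)/\sqrt{5}$, i.e. a diagonal, mostly horizontal movement), and white
Gaussian measurement noise is added per axis.

Defaults: $A_d = 2.5$ deg, $\tau_d = 0.1$ s, $v_h = 0.5$ deg/s, $A_r = 2$ deg,
$\tau_r = 0.1$ s, $\tau_{rec} = 0.35$ s, noise SD $0.1$ deg. These give evoked
movements of ~3 deg with peak velocities of ~25 deg/s — the scale of the
recordings emulated — and deliberately keep the *slow-phase* peak velocity
below the 40 deg/s quick-phase threshold, so that threshold separates signal
classes rather than clipping the response. The stimulation protocol defaults
to 60 consecutive LEDs per duration from the set {50, 100, 200, 500, 1000} ms.

**Sampling rate.** The emulated video tracker's frame rate is not a property
we could anchor on, so the generator defaults to 1000 Hz (configurable);
analyses infer the rate from the time base.

**Quick phases.** Saccadic quick phases are modeled as minimum-jerk
*out-and-back* transients (default 3 deg, 20 ms, Poisson-timed at 0.5 Hz).
An out-and-back transient, rather than a persisting ballistic displacement,
is a deliberate choice: a persisting displacement at a random time would
permanently offset the post-saccade slow-phase position of that cycle, and no
sample-masking strategy could recover the saccade-free trace — the
quick-phase-removal stage would be unfalsifiable. The transient form keeps
the slow-phase ground truth intact while still producing strongly
supra-threshold velocities (~280 deg/s after filtering), so the removal stage
is genuinely exercised. Real quick phases in these reflex paradigms are
centripetal resets, which the out-and-back shape caricatures.

**Seeding.** One master seed; per-animal, per-cell and per-purpose streams
(noise vs. saccade placement) are derived deterministically
(`derive_seed()`), so any single trial is reproducible in isolation and
turning saccades off does not perturb the noise realization — which is what
makes "with vs. without saccades at the same seed" a clean paired comparison.

**Cohorts.** Genotype archetypes are parameter sets; per-animal kinematic
parameters are jittered multiplicatively (log-normal, SD 0.1 by default),
keeping them positive. A 10% coefficient of variation is a typical
between-animal spread for evoked-movement amplitudes; it is declared, not
estimated from data.

## Velocity profiles and quick-phase removal

Position is differentiated with central differences (one-sided at the ends)
and low-pass filtered with a zero-phase 2nd-order Butterworth filter, default
cutoff 50 Hz; the same is repeated for acceleration. With 0.1-deg white
position noise at 1 kHz this leaves ~5 deg/s RMS velocity noise — far enough
below the 40 deg/s threshold that spurious masking is negligible, while a
20-ms quick phase still peaks near 280 deg/s after filtering.

Because R's `signal::filtfilt()` starts from a zero filter state, a trace
with a non-zero baseline would acquire large start-up transients; `optokin`
therefore extends the signal by odd reflection at both ends and removes the
endpoint-to-endpoint line before filtering (constants and ramps pass a
zero-phase Butterworth unchanged), restoring it afterwards.

Samples whose 2-D eye speed exceeds 40 deg/s are *masked*, padded by 10 ms on
each side to remove saccade shoulders. Masked samples are excluded from all
averages, fits and integrals — never interpolated (interpolation is used only
to give the zero-phase filter a contiguous signal at all-masked time points
of a mean trace, and those points stay flagged). Masking is monotone in the
threshold by construction.

## Cycle quality control and averaging

A stimulation cycle is included when

1. the eye was steady in the 20 ms before LED onset — implemented as the SD
   of the magnitude position in that window not exceeding 0.25 deg (the
   steadiness criterion is stated in the emulated protocol without a formula;
   0.25 deg is 2.5x the default noise SD, configurable); and
2. the magnitude position crossed the movement threshold during stimulation:
   any unmasked in-stimulation sample above the pre-window mean plus twice
   the pre-window SD. The SD is floored at 0.01 deg so a noiseless flat trace
   cannot cross its own (zero-width) threshold.

Included cycles are averaged pointwise over unmasked samples (h and v axes
separately; the magnitude of the mean is then recomputed, which avoids the
upward noise bias of averaging magnitudes); animal means are averaged into
group means with pointwise SEM.

## Phase decomposition and metrics

For LEDs of at least 200 ms the mean movement is decomposed into four phases:
**drive** = first 100 ms after onset, **hold** = drive end to LED offset,
**release** = first 100 ms after offset, **recovery** = the following full
second. Shorter LEDs get a flagged drive + release decomposition.

Per phase, an ordinary least-squares line of magnitude *position* against
time over unmasked samples gives the phase mean velocity (slope) and the
starting position (fit evaluated at the phase start). Position-vs-time was
chosen as the fit variable because the pair "mean velocity and starting
position" is exactly the slope/intercept pair of that regression; fitting
velocity against time would yield an acceleration, not a velocity.

Net distance traveled is the trapezoidal area under the magnitude velocity
profile, bridging masked gaps between unmasked neighbors. A numerical
consistency choice worth stating: the magnitude velocity is defined as the
central difference of the *filtered* magnitude trace (differentiation and
LTI filtering commute, so this equals filtering the raw derivative). The
trapezoidal integral of a central-difference derivative telescopes, so the
per-phase AUC equals the endpoint displacement of the filtered magnitude to
discretization accuracy — independent of noise. Integrating a separately
smoothed velocity against raw-position endpoints would instead leak
displacement across phase boundaries through the filter's impulse response.

Trace-level summaries: **maximum amplitude** is the filtered magnitude at the
LED-offset sample (the nearest unmasked sample if that one is masked,
flagged) — the offset sample rather than the in-stimulation maximum, which is
equivalent for monotone responses and deterministic for all of them;
**initial peak velocity** is the largest unmasked magnitude velocity within
the drive window ("shortly after onset" bounded to the drive phase).

## Pointwise divergence map

Group divergence over time is the absolute t-score of an unpaired two-tailed
Student's t test at every time point on per-animal velocity traces, with
pooled variance and $df = n_A + n_B - 2$ (the pooled-variance form is what
yields the integer df conventions of published thresholds; a `df_override`
argument accommodates other conventions). No multiple-testing correction is
applied across time points — the map is a descriptive visualization, not a
confirmatory family of tests. Zero-pooled-variance points (possible under
mask holes) are reported as degenerate with $|t| = 0$ rather than errored.
The critical value is `qt(1 - alpha/2, df)`.

## Spike-train analyses

The generator draws spike trains from a **gamma renewal process via time
rescaling**: unit-mean gamma increments (shape $k$; $k = 1$ is Poisson, large
$k$ approaches clockwork) accumulate in rescaled time
$\Lambda(t) = \int r(s)\,ds$, with intensity `base_rate` outside stimulation
epochs and `stim_factor * base_rate` inside. Defaults (60 Hz, $k=4$) emulate
tonic PC simple-spike firing; factors 3 and 0.25 reproduce the excited
(~3-fold increase) and suppressed (75% decrease) response archetypes.

Epoch responses tile a 2-s window exactly: 0.5 s pre-stimulation, the
(50/100/200 ms) peri-stimulation window, and the remaining post time. The
modulation index is the mean peri rate normalized to the mean pre rate
(aggregated rates rather than per-epoch ratios, which are unstable at low pre
counts; per-epoch ratios are also reported). The PSTH is the mean spike
*count* per 5-ms bin across stimulations — counts, taken literally, rather
than rates; bin edges are built as integer multiples of the bin width so
boundary spikes cannot drift between bins through accumulated floating error.

CV2 is the Holt-style local variability index
$\mathrm{mean}_i\, 2|ISI_{i+1}-ISI_i| / (ISI_{i+1}+ISI_i)$: 0 for clockwork
trains, 1 in expectation for Poisson, insensitive to slow rate drift, and
scale-invariant. Response classification uses normalized-peri thresholds of
1.5 (excited) and 0.5 (suppressed); these are package conveniences sitting
far from both archetype values (3.0 and 0.25), not estimated cutoffs.

Current-step input-output curves count spikes in the 500-ms pulse and the
first-spike latency per step (+100 to +900 pA in the emulated protocol);
silent sweeps count toward the average with zero spikes and undefined
latency.

## Sensory paradigms

VOR/OKR/VVOR traces share one model: a horizontal sinusoid
$g A \sin(2\pi f t + \varphi)$ with $f \in [0.1, 1]$ Hz. Under an opto
condition, the evoked-movement kernel is added in every half-cycle where the
sensory drive moves the eye in the designated direction (naso-temporal =
positive horizontal velocity), LED onset at the half-cycle boundary (the
exact phase alignment is not pinned down by the emulated protocol; the
boundary is the natural deterministic choice). The release/recovery tail runs
on through the opposite half-cycle — truncated at the next LED onset so the
perturbation is exactly cycle-periodic — because the emulated responses do
show a drift persisting beyond the stimulated half; the tail has decayed to a
few percent of the peak by late in the opposite half-cycle.

Cycle folding assigns samples to 100 phase bins per cycle (binning is a free
choice; 100 bins resolve the kernel rise at all frequencies while keeping
>= 10 samples per bin per cycle at the default rates), excludes
quick-phase-masked samples, averages within cycle and then across cycles
(mean ± SEM). Condition subtraction is bin-wise `on - off` with SEM
propagated in quadrature; it is antisymmetric under swapping by construction.
Because the LED spans the designated half-cycle, its absolute duration grows
as the frequency falls, so the per-cycle difference magnitude is larger at
0.1 Hz than at 1.0 Hz — the fixed-kernel frequency ordering the package's
acceptance suite checks.

A fundamental-frequency sine fit (`reflex_gain_phase()`) summarizes reflex
gain and phase as a convenience; the paradigm analyses themselves operate on
traces, not gains.

## Calibration of raw tracker frames

`calibrate_position()` applies the standard angular conversion for a
corneal-reflection video tracker: `asin((pupil - CR - offset)/Rp)` per axis,
with `Rp` the radius of pupil rotation and the offset defaulting to the
session median (an explicit `offset` argument covers bench tests with a known
zero reference). Pupil-size-dependent corrections of `Rp` are out of scope;
frames whose displacement reaches `Rp` raise a calibration-range error naming
the frame.

## Problem sizes and what the tests do and do not show

The validation suites run at the emulated study's own scale where that is
what is being claimed (14-animal cohorts with 60 trials of 1000-ms LEDs;
60 stimulation epochs; 200 synthetic cells; 200-seed null calibration of the
divergence map; 10^5 interspike intervals for the Poisson CV2 check) and at
reduced scale for unit tests of mechanics. The default `run_pipeline()`
configuration is a deliberately small demonstration cohort (2 groups x 3
animals, 10 repeats); scale it through the config.

Passing tests show that the pipeline recovers the generator's ground truth
under the generator's assumptions: stationary kernels, additive white
Gaussian noise, out-and-back quick phases, renewal spiking. Real recordings
violate all of these in degree — drifting baselines, correlated tracker
noise, pupil-size artifacts, history-dependent firing, CS/SS interactions —
so the suites certify the *estimators*, not the biology. Known limitations:
no torsional eye position, no pupil detection from video, no
conductance-based spiking, no CS-triggered analyses (spike classes are
carried through the types for future use), and no ANOVA-family group
statistics (the divergence map is deliberately the only between-group
statistic).
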