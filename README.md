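# optokin

Kinematic and spike-train analysis for optogenetic experiments on the
cerebellar flocculus — and a synthetic-data generator that makes every stage
of the analysis testable against closed-form ground truth.

## The problem

Optogenetic stimulation of floccular Purkinje-cell (PC) subpopulations evokes
small, structured eye movements: a fast rise after LED onset, a slow creep
while the light is on, a fast release at offset, and a slow return to
baseline. Characterizing which PC subpopulation drives which component
requires a chain of careful signal processing — calibrated angular position,
filtered velocity, removal of saccadic quick phases, per-cycle quality
control, cycle and animal averaging — followed by a four-phase kinematic
decomposition and pointwise statistical comparison between genotypes. The
accompanying electrophysiology needs peri-stimulus rate modulation, spike
regularity (CV2) and current-step excitability summaries. Raw recordings for
such studies are typically available only on request, so `optokin` pairs the
full analysis chain with a generator that emulates the recordings with known
ground truth.

## The analyses

* **Kinematics** — position-to-velocity with a zero-phase Butterworth filter;
  quick-phase removal at the >40 °/s speed threshold with 10-ms padding;
  cycle inclusion requiring a steady 20-ms pre-window and a crossing of the
  pre-window mean + 2 SD; cycle and animal averages on unmasked samples.
* **Phase decomposition** — drive (first 100 ms of the LED), hold (to LED
  offset), release (first 100 ms after offset), recovery (the next full
  second). Per phase: mean velocity and starting position from an OLS fit of
  magnitude position √(h² + v²) vs. time, and distance traveled as the area
  under the velocity curve. Trace-level: maximum amplitude at LED offset and
  initial peak velocity in the drive window.
* **Divergence map** — pointwise unpaired two-tailed Student's *t* on
  per-animal velocity traces (pooled variance, df = nA + nB − 2), |t| against
  the critical value `qt(1 − α/2, df)`.
* **Spike trains** — per-epoch pre/peri/post rates on the 0.5 s + peri +
  remainder-of-2 s window layout, peri rate normalized to pre, 5-ms-bin PSTH,
  CV2 = mean 2|ISIᵢ₊₁ − ISIᵢ|/(ISIᵢ₊₁ + ISIᵢ), excited/suppressed
  classification, and current-step input–output curves (spike count and
  first-spike latency per 500-ms pulse).
* **Sensory paradigms** — VOR/OKR/VVOR sinusoids (0.1–1.0 Hz) with optional
  opto co-stimulation in designated half-cycles; phase-binned cycle folding
  and on − off condition subtraction with propagated SEM.
* **Synthetic data** — an exponential pulse-step kernel with per-phase
  closed-form ground truth, out-and-back minimum-jerk quick phases,
  log-normal per-animal parameter jitter, and gamma-renewal spike trains via
  time rescaling (3× excitation / 75 % suppression archetypes).

## A worked example

```r
library(optokin)

# one synthetic animal: 20 repeats of a 1000-ms LED, 0.1 deg noise,
# 0.5 Hz quick phases
p <- opto_eye_params(led_durations = 1000, n_repeats_per_duration = 20,
                     seed = 42)
sim <- gen_opto_eye_trace(p)

# velocity -> quick-phase removal -> cycle QC -> mean response
resp <- animal_mean_response(sim, duration_ms = 1000)
#> <animal_response> 1000-ms LED, 20/20 cycles included

seg <- segment_phases(onset_s = 0, offset_s = 1,
                      trace_end_s = max(resp$mean$rel_time_s))
fit <- phase_metrics(resp$mean, seg)
tidy(fit)
#> # A tibble: 4 x 8
#>   phase    start_s end_s     n mean_velocity_dps start_position_deg ...
#> 1 drive        0     0.1   101            16.0                0.143
#> 2 hold         0.1   1     901             1.03               2.21
#> 3 release      1     1.1   101           -14.8                2.88
#> 4 recovery     1.1   2.1  1001            -0.978              0.812
glance(fit)$max_amplitude_deg
#> [1] 2.98
```

The drive phase moves the eye at ~16 °/s (the slope of magnitude position
over the first 100 ms), the hold phase creeps at ~1 °/s up to a ~3°
amplitude at LED offset, and release/recovery mirror the rise; the generator's
closed-form values for this parameter set are 16.1, 1.03, −14.9 and −0.98 °/s
(`opto_kernel_truth(p, 1.0)`), so the pipeline recovers each phase to a few
percent despite noise and quick phases.

The divergence threshold used to mark significant velocity differences
between two 16-animal-scale groups:

```r
critical_t(df = 30, alpha = 0.05)
#> [1] 2.042272
```

A stimulated cell with a 3-fold rate increase:

```r
onsets <- 1 + (0:19) * 2
st <- gen_spike_train(spike_gen_params(
  base_rate = 60, stim_factor = 3, gamma_shape = 4,
  epoch_schedule = tibble::tibble(onset_s = onsets, duration_ms = 200),
  total_duration = 42, seed = 1
))
epoch_response(st$spikes, onsets, peri_s = 0.2)
#> <epoch_response> 20 epochs: pre 59.9 Hz, peri 185.0 Hz (normalized 3.09),
#>   post 61.0 Hz
```

The normalized peri rate (3.09) recovers the generator's stimulation factor
(3), and `classify_response()` labels the cell `excited`. An end-to-end run
over a small cohort — simulation, kinematics, phases, divergence, spikes,
sensory subtraction — is `run_pipeline(default_config(seed = 1), out_dir =
"out")`; a thin command-line wrapper lives at `inst/scripts/optokin.R`.

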