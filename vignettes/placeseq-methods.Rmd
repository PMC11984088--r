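---
title: "Methods and design notes for the placeseq pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the placeseq pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures the package implements,
the conventions adopted where the underlying methods admit more than one
reading, the numerical choices that matter, and what the synthetic
generator does and does not emulate. Nothing here reports an empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The recording model

A session-day consists of four 10 min unidirectional run sessions on a 1 m
diameter circular track (circumference 100π ≈ 314.2 cm), interleaved with
five rest sessions in a flowerpot beside the track. Position is tracked at
29.97 Hz as an angle in [0°, 360°); LFP channels are sampled at 2,000 Hz;
single units are sorted spike-time lists. Units with whole-day mean rates
above 5 Hz are flagged putative interneurons and excluded from place-cell
analyses (they are never deleted from the session object).

All angular arithmetic is circular: distances are shortest-arc unless an
operation is explicitly signed, and the angle increases in the running
direction. One degree of track is 100π/360 ≈ 0.873 cm.

## Behavior

Running speed is the central difference of the unwrapped angle, converted
to cm/s, then boxcar-smoothed over 5 samples (~167 ms). The smoothing
choice is a convention of this package (the tracker-speed estimator is
otherwise unspecified in the methods this pipeline follows): without
smoothing, frame-to-frame tracker jitter near the 5 cm/s gate makes the
gated sample set unstable. Laps are counted each time the unwrapped angle
advances a further full 360° in the running direction — also a convention,
invariant to the angular origin. Mean run speed uses only samples faster
than 5 cm/s.

## Rate maps, place fields, information

Maps use 90 bins of 4°. Occupancy is the speed-gated time per bin; spikes
at gated times are excluded; the raw rate is spikes/occupancy with
zero-occupancy bins set to 0 Hz *before* smoothing (on a circular track
with many laps such bins are rare; zeroing avoids NaN propagating through
the kernel — occupancy-weighted smoothing would be the alternative).
Smoothing is a wrap-around Gaussian, σ = 8° (2 bins), truncated at 4σ and
renormalized; it preserves the map's sum, so a constant map stays constant
and a single spike becomes a wrapped Gaussian.

The day-averaged map pools spike counts and occupancy across the four run
sessions and re-applies the rate definition — it is not the mean of the
session maps (pooling equals the rate definition applied to the whole day;
the two differ whenever occupancy differs across sessions). Units are
included as active place cells when the day map's peak reaches 1 Hz.

Place fields are detected on the smoothed map: rates are z-scored across
the 90 bins with the unweighted mean and SD (a stated convention —
occupancy weighting would be defensible too), bins with z ≥ 2 seed fields,
fields extend circularly to where z < 0.5, touching regions merge, and
fields must reach 1 Hz at the peak and span at least 18°. Spatial
information is the Skaggs formula in bits/spike over bins with positive
rate; stability metrics are the Pearson correlation of two maps' rate
vectors and the ratio of mean rates with the larger as denominator.

## Theta phase and precession

Theta phase comes from a 4th-order Butterworth bandpass (6–10 Hz) applied
forward–backward (zero phase) followed by the analytic-signal (Hilbert)
phase. Two numerical points matter:

- At 2,000 Hz the normalized theta band is so narrow that the filter's
  transfer-function coefficients are ill-conditioned, producing
  degree-scale phase ripple even on a pure tone. The channel is therefore
  decimated (anti-aliased) to about 20× the band's upper edge before
  filtering and the phase is interpolated back onto the original grid;
  this reduces the pure-tone peak-phase error to under 0.2°.
- `filtfilt` as implemented in the `signal` package does not match initial
  conditions, so boundary steps (e.g. a DC offset) ring into the series;
  the package pads every zero-phase filter call with an odd reflection of
  the signal and crops afterwards.

The phase convention is 0° at the peak of the filtered waveform, 180° at
the trough (the methods being followed do not state their zero; only
quantities that are invariant to the choice — precession correlation,
sequence fits — are compared across implementations). Phase at spike times
is linear interpolation on the unwrapped phase.

Precession is quantified per unit on its highest-peak day field: each
speed-passing in-field spike contributes (normalized position d ∈ [0, 1],
phase φ); the slope maximizes the mean resultant length of φ − a·d over a
bounded range (±1,080°/field, i.e. up to three theta cycles of advance;
coarse grid of 241 points then local refinement), and r is the standard
circular–linear correlation built from the Pearson correlations of d with
cos φ and sin φ. Units with fewer than 50 in-field spikes are excluded
with a reason, not an error. The p-value uses the χ²(2) approximation of
n·r²; it is reported but not used for inclusion.

## Bayesian decoding and the accuracy gate

The decoder assumes independent Poisson spiking given position with
expected rates from the day-averaged tuning of included place cells and a
flat position prior; per window of length τ the log-likelihood is
Σⱼ [nⱼ log(τ λⱼ(x)) − τ λⱼ(x)] with rates floored at 0.01 Hz inside the
logarithm, and the posterior is normalized per window. Windows with zero
spikes are decoded (valid under the model — the posterior concentrates
where total tuning mass is lowest) but flagged; downstream modules apply
their own activity gates.

The decoding-accuracy gate decodes all run windows (500 ms, 100 ms steps)
whose mean speed clears 5 cm/s, takes the maximum-posterior bin as the
decoded position, and requires the cumulative error distribution to reach
50% below 20° — implemented as the median shortest-arc error being below
20°, which is the same statement. The confusion matrix row for an actual
position bin is the mean posterior over all windows spent there (rows then
sum to 1 by construction). Tuning is estimated on the same day that is
decoded, replicating the analysis this pipeline follows; no
cross-validation is attempted.

## Theta sequences

Theta cycles are cut at the phase with the fewest place-cell spikes
(histogram of spike phases in 18 bins of 20° — the bin width is a package
convention; ties resolve to the smallest phase) over speed-passing run
times, with cycle boundaries at each crossing of that phase. Cycles
qualify when at least 3 place cells fired and mean speed is at least
5 cm/s. Each qualifying cycle is decoded in 40 ms windows advanced by
10 ms; contiguity breaks where 2 consecutive windows contain no spikes,
and the longest contiguous run (edges trimmed to spiking windows, ≥ 3
windows) is fitted.

The fit takes each window's posterior-weighted circular center of mass
(COM) and regresses it (circular) on window-center time (linear), slope
bounded at ±3,000 deg/s. For circular data the package defines
r² = 1 − V(residuals)/V(COM), where V is circular variance and residuals
are shortest-arc distances to the line; this reduces to the ordinary
coefficient of determination in the small-angle limit and is clipped to
[0, 1]. The x-span is |slope|·t-span, with the t-span measured
center-to-center over the fitted windows (conventions where the source
methods admit either reading; both are parameterized).

Significance combines three criteria: (1) the observed r² must exceed 95%
of 1,000 refits in which every window's posterior is independently rotated
by a uniform random number of bins; (2) at least 60% of the posterior mass
over the fitted windows must lie within 20° of the line; (3) the minimum
distance between the line and the rat's actual position must be below 20°.
Because rotating a posterior on the equispaced circular bin grid rotates
its circular COM by exactly the shift, the shuffle refits operate on
shifted COMs — mathematically identical to recomputing the COM from the
rotated posterior and verified against the literal rotation in the tests.
The shuffle p-value uses the add-one estimator (k + 1)/(n + 1).

## Replay

Candidates are detected per rest session from the population rate of all
active place cells in 1 ms bins (the bin width is a package convention
under the stated 10 ms-SD Gaussian smoothing), thresholded at
mean + 3 SD with mean/SD computed within that rest session (per-session
statistics track slow drifts), bounded by the surrounding crossings of the
mean, merged when closer than 40 ms, trimmed inward to the first and last
spike, and kept when lasting 50–2,000 ms with at least 5 distinct cells.
"Participating" means firing at least one spike within the trimmed bounds.
No speed gate applies during rest (the rat sits in the flowerpot).

Each candidate is decoded in 20 ms windows advanced by 10 ms and fitted
with the same circular machinery (slope bounds widened to ±5,000 deg/s;
two windows suffice for classification). Replay requires r² ≥ 0.5, no
adjacent-window COM jump above 25% of the track, and occurrence in rest
sessions 2–5. The slope is reported as an absolute value (forward and
reverse replay alike); path distance is the shortest-arc distance between
the first and last window COMs (capped at 180° by construction — a
documented consequence of the shortest-arc convention). Per-unit firing
around replay onset (1 ms bins, 10 ms-SD smoothing, ±500 ms) averages only
over events in which the unit participated; the population ISI of an event
is the mean interval between consecutive pooled spikes (identically the
pooled span divided by the interval count) and the first-spike ISI uses
each cell's first spike only.

## Replay-associated LFP

Time–frequency power uses a complex Morlet transform, implemented as
frequency-domain Gaussians of width f/7 (seven cycles at every frequency)
with unit gain at each center frequency, evaluated at 1 Hz steps from 2 to
250 Hz on ±500 ms segments around event onset (the peri-event extent is a
parameter; the source methods do not state theirs). Power is z-scored
within each frequency over the concatenated peri-event segments of the day
and averaged across events for the maps.

The peak ripple frequency of an event is the argmax over 150–250 Hz of the
event's time-averaged *raw* wavelet power (ties break to the lower
frequency, a deterministic contract). Raw power is used deliberately:
within-frequency z-scoring is scale-invariant per row, so for a transient
that dominates its own rows' variance the z-profile across frequencies
flattens and the argmax degenerates to the band edge — with unit-gain
wavelets the raw power preserves the oscillation's spectral profile
exactly. Slow-gamma power remains the z-scored mean over 25–55 Hz and the
event's time extent, as a background-relative measure should be.

Ripples are intervals where the 150–250 Hz Hilbert envelope, smoothed with
an 8 ms-SD Gaussian and z-scored over the channel, reaches z ≥ 3; a ripple
counts toward an event when the intervals overlap.

## The synthetic generator

The generator exists so that every stage can be validated by recovering
known parameters. It emulates:

- constant-speed unidirectional running (30 cm/s default) with smoothed
  tracker jitter;
- Gaussian place tuning on the circle (60 evenly spaced fields, σ = 15°,
  peak 10 Hz by default), spikes from an inhomogeneous Poisson process by
  thinning (exact and seedable);
- theta LFP (8 Hz, 150 µV) over 1/f background noise (40 µV), with spike
  phase precession: the preferred phase declines linearly with normalized
  field position (360° per field by default) with von Mises concentration
  κ = 2. Precession of this form makes each theta cycle sweep a compressed
  path, with an implied sequence slope of roughly
  field-extent × 360 × f_theta / precession-slope;
- an alternative run generator (`simulate_sweep_run`) in which the
  represented position sweeps the track at an exactly scripted rate within
  each theta cycle, used for slope-recovery validation (the emergent
  precession route cannot pin the true slope exactly: the theta envelope
  biases each decoding window's effective spike time toward mid-cycle,
  attenuating fitted slopes — with the mild envelope used for sweeps,
  κ = 0.5, the bias is within a few percent);
- rest epochs with 1 Hz-per-unit baseline firing (a typical quiet-rest
  pyramidal rate), scripted replay events (600 deg/s for ~200 ms in the
  "wt" preset) in which units fire in field order along a constant-speed
  trajectory, Hann-enveloped ripple oscillations (180 Hz, 120 µV) during
  each event, and suppressed baseline in a 150 ms margin around each
  event. The margin reflects how population bursts rise out of relative
  quiescence; without it, the mean-crossing bounding rule attaches
  unrelated baseline spikes to event edges, and those edge windows then
  violate the jump criterion for reasons unrelated to the trajectory. An
  optional shared log-normal excitability modulation of the baseline is
  available but off by default: its peaks act as spurious bursts adjacent
  to scripted events.

The generator does not emulate: multi-day remapping, interneurons,
direction-selective fields, reward-site effects, behavioral pauses,
sleep-state structure in rest, biophysical LFP (theta harmonics,
sharp-wave polarity, phase-amplitude coupling), or electrode artifacts.
Passing recovery tests on this generator therefore demonstrates the
pipeline's correctness on data satisfying its statistical assumptions, not
robustness to every failure mode of real recordings.

Two presets mirror a genotype contrast: `"fxs"` lowers the replay
trajectory speed (350 vs 600 deg/s), lengthens events (350 vs 200 ms),
lowers in-event firing (45 vs 80 Hz peak), lowers the ripple frequency
(165 vs 180 Hz) and spreads precession over more phase per field (640° vs
360°, lowering the implied sequence slope). The pipeline recovers the
direction of each contrast.

## Validation problem sizes

The test suite and acceptance script run deliberately scaled versions of
each validation: a 60-unit, 20-lap (~210 s) run session for decoding
accuracy; 300 structureless cycles × 200 circular shuffles for the null
calibration of sequence significance (the full procedure uses 1,000
shuffles; the calibration is about the rate of false positives, which the
reduced shuffle count estimates with adequate precision); 25 s sweep
sessions at five scripted slopes (300–900 deg/s) with 50 cycles each; one
synthetic day of 60 s runs and 40 s rests with 3 scripted replay events
per rest for replay recovery and preset contrasts; and 30 s LFP segments
with five injected ripple bursts for the spectral checks. These sizes were
chosen so the whole battery runs in minutes while keeping every estimate's
sampling error well inside the margins being asserted.

## Known limitations

- The decoder is memoryless; no continuity prior or state-space smoothing.
- Tuning is fit and decoded on the same day (as in the methods followed);
  decoding-error estimates are therefore slightly optimistic.
- Circular r² is one of several possible definitions; values are
  comparable within this package, not across packages with other
  definitions.
- The shortest-arc path distance cannot exceed 180°, so trajectories
  sweeping more than half the track are reported by their net arc.
- `compare_presets` uses Wilcoxon rank-sum tests per metric; hierarchical
  (animal/day-nested) inference is out of scope.
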