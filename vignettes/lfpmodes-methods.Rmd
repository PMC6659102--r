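---
title: "Methods: mode decomposition and network-dynamics metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mode decomposition and network-dynamics metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures behind `lfpmodes`, the
assumptions they make, the tunable parameters that matter, and the design
choices taken where the methods literature leaves the details open. It
states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## Signal conventions

All traces are uniformly sampled `time_series` objects in mV (voltage) or pA
(current), with time in seconds, t = 0 at the trace start and every window
half-open `[start, end)`. Filters are Butterworth IIR designs (order 4 by
default) applied forward–backward (`filtfilt`), so filtering is zero-phase:
this matters because spike-triggered-average latencies and rise/decay
measurements would otherwise inherit the filter's group delay. Two numerical
points:

* a *bandpass* is realized as a highpass–lowpass cascade. A direct
  fourth-order bandpass design with cutoffs many decades apart (0.2–50 Hz at
  a 10 kHz rate gives a normalized low edge of 4·10⁻⁵) places poles so close
  to the unit circle that the filter output diverges in double precision;
  the cascade is stable. Even so, a 0.2 Hz highpass at 10 kHz has a
  numerical noise floor around −30 dB; analyses at 1 kHz rates are far below
  it.
* the DC level is subtracted before any high-pass stage. The filter rejects
  it asymptotically anyway, and removing it first avoids the large edge
  transients that forward–backward filtering otherwise produces on traces
  with an offset.

On-disk traces are two-column CSV (`time_s,value`, written at 17 significant
digits so round-trips are bit-exact) or little-endian float64, each with a
JSON sidecar carrying `sampling_rate`, `units`, `t0`, `channel_id`.

## Empirical mode decomposition

`sift_emd()` repeatedly subtracts the mean of the upper and lower extrema
envelopes (natural cubic splines) from the signal until the result is an
intrinsic mode function, then removes it and continues on the remainder.
Choices the algorithm family leaves open, fixed here as:

* **Sifting stop**: Cauchy-type criterion
  `sum((h_prev − h)²)/sum(h_prev²) < 0.2`, capped at 50 iterations. The cap
  bounds runtime; the threshold is the common default. A looser threshold
  leaves small "riding" ripples on low-frequency IMFs, which is why the IMF
  condition (extrema ≈ zero crossings) is only enforced approximately.
* **Envelope boundaries**: the extrema nearest each edge are mirrored about
  the first and last sample before spline fitting, so envelopes do not
  splay at the ends and end effects cannot leak into STA windows.
* **Termination**: sifting stops when the residual has fewer than two maxima
  or two minima; a monotone input therefore yields zero IMFs and
  `residual == input`, which is signaled, not an error.

`ceemdan()` implements the complete ensemble variant: stage k extracts the
ensemble mean of the first IMF of `residual + β_k·E_k(w_i)` over
`n_realizations` white-noise realizations `w_i` (decomposed once, up front),
with `β_k = noise_sd · sd(residual)`. Defaults `n_realizations = 100`,
`noise_sd = 0.2` are the values typical of the algorithm family; both are
exposed, and the noise generator is seeded, so a run is bit-reproducible.
Because each ensemble-mean mode is subtracted from the running residual, the
decomposition is complete to machine precision by construction — the
acceptance script reports the realized reconstruction error (~10⁻¹⁵
relative) rather than assuming it.

**Band assembly.** Theta (5–14 Hz), low gamma (25–55 Hz) and high gamma
(56–120 Hz) signals are the sums of IMFs whose *amplitude-weighted* mean
instantaneous frequency (weights = analytic-signal envelope) falls inside
the band. Amplitude weighting makes the assignment robust to phase noise in
low-amplitude stretches, where unweighted instantaneous frequency is
erratic. IMFs falling in the gaps (14–25 Hz, >120 Hz) stay unassigned
rather than being forced into a band, since only the three bands above are
defined. An empty band is returned as flagged zeros.

On noisy two-tone inputs, plain EMD can split a tone across an IMF pair
whose mean frequencies straddle a band edge; the noise-assisted ensemble
largely removes this. The band-routing acceptance check therefore runs on
CEEMDAN, which is also the decomposition intended for real recordings.

## Band statistics

*Average relative power* of a band is the mean of z², with
`z = (band − mean(band)) / sd(raw LFP)`. Normalizing by the raw trace —
not the band itself — is what makes the statistic comparable across
recordings and genotypes with different overall LFP amplitude; reading the
normalization any other way would make the cross-group comparison
meaningless. The statistic is dimensionless (a variance share), and is
reported as such even where the literature attaches mV² labels to it.

*Band occurrence frequency* z-scores the band against its **own** mean and
SD (deliberately unlike relative power — the two statistics normalize
differently), splits it into cycles at consecutive upward zero crossings,
counts cycles whose peak |z| exceeds 2, and divides by duration. The cycle
definition (upward crossing to upward crossing; cycle amplitude = max |z|
within) is the simplest one consistent with counting threshold-exceeding
cycles. A constant-amplitude sinusoid yields zero: its peak z is √2 < 2.
The 2-SD threshold keeps roughly the top 5% of cycle amplitudes when the
amplitude distribution is normal.

`welch_psd()` averages Hann-windowed periodograms at 50% overlap
(window 2048 by default; at 10 kHz the bin width is 4.88 Hz, i.e. ~5 Hz
resolution); segments are mean-subtracted, and the one-sided density is
scaled so its integral equals the signal variance (checked against Parseval
on white noise in the tests). No installed package exposes a Welch
estimator, so it is implemented here.

## Spike–field analyses

`detect_spikes()` band-passes (default 300–4500 Hz; use a 500 Hz highpass
for MUA before spike-triggered averaging), thresholds at
`threshold_sd × median(|x|)/0.6745`, and takes the extremum of each
supra-threshold excursion as the spike time. The robust scale estimate is
used because spikes themselves inflate the raw SD; the extremum (rather
than the threshold crossing) gives sub-millisecond timing stability.
Polarity is auto-detected from the dominant absolute extremum; detections
closer than the 1 ms refractory window merge, keeping the larger.

`spike_triggered_average()` cuts ±1 s of the 0.2–50 Hz LFP around each
spike (spikes within 1 s of an edge are skipped) and averages; it reports
the means over [−0.25, 0) and [0, 0.25) s, and flags the recording excluded
— rather than averaging — when the spike rate is below 1 Hz.

`spike_power_profile()` computes the band's average relative power in ten
100-ms bins before and ten after each spike and averages across spikes.
Bins are computed per spike independently, so windows of spikes closer than
1 s overlap; they are not deduplicated.

## Unit firing

A burst is a maximal run of interspike intervals each ≤ `max_isi_s`
(default 0.05 s, the reciprocal of the ≥20 Hz definition; per-cell choices
in the 20–50 ms range are accepted, values outside warn). Detection is a
greedy left-to-right run-length scan — the tests hold it equal to a
brute-force oracle on a thousand random trains. Burst boundaries are the
first and last spike of the run, with no padding, and no automated
per-cell threshold selection is attempted. Firing metrics decompose counts
exactly: singles + intra-burst spikes = total. Spike half-width is full
width at half the baseline-to-peak amplitude, baseline = median of the
first 20% of the window, crossings linearly interpolated.

## Synaptic currents

`template_detect()` is the classic optimally-scaled-template detector: at
every sample the template is fit to the data by least squares (scale +
offset), and the detection criterion is scale / standard error of the fit,
which is invariant to amplitude rescaling of the recording. Local criterion
maxima above threshold (default 3) become events; candidates within one
template length keep the higher score. The running sums are vectorized, and
the tests pin the scores to per-position `lm()` fits. Default templates are
biexponential — rise 0.5 ms / decay 8 ms (IPSC-like), 0.3 / 4 ms
(EPSC-like) — since acquisition-software template kinetics are not
standardized.

Evoked kinetics: 20–80% rise times interpolate linearly between samples;
decay fits `A·exp(−t/τ)` from the peak by Levenberg–Marquardt with
log-linear starting values. Two practical notes, both visible in the
acceptance fixtures: the baseline window should span the available
pre-stimulus interval (a 1 ms baseline estimated from noisy data shifts the
fitted asymptote and inflates τ dispersion several-fold), and evoked
amplitudes are best read from the fitted `A`, not the raw extremum — the
minimum of a noisy sweep is biased by the noise maximum.

Toxin subtraction uses means of stable windows (≥5 sweeps), not sweep-paired
differences: `sensitive % = 100·(1 − mean(post)/mean(control))`. Apparent
negative fractions are flagged, not clipped. Sweep amplitudes enter as
means (not medians), and the "after drug" window is taken as the last
stable sweeps before any further manipulation. The 5-pulse 20 Hz train
ratio is fifth/first amplitude.

## Behavior

Three-chamber scores are differences of per-compartment investigation times
supplied by tracking software; nose-point geometry is out of scope.
Open-field zone geometry: a 60-cm side tiled by 12-cm blocks gives 5 × 5 =
25 blocks, hence 16 perimeter and 9 center blocks; descriptions quoting 12
perimeter blocks cannot tile this arena, so the geometrically forced 16/9
split is implemented — the inner/outer classification (central 3 × 3
versus the rest) is unaffected. Distance is the euclidean path integral;
zone occupancy is per-sample, so inner + outer time equals the session
duration exactly.

## Synthetic data: what it emulates, and what it does not

The generators produce the signal *structure* the analyses assume, with
parameters chosen to mirror the anesthetized-hippocampus setting: a 0.2 mV
slow wave at 1 Hz with smaller theta (8 Hz) and gamma components; biphasic
extracellular spike waveforms of 0.3 ms half-width at configurable SNR;
bursting trains with ≥20 Hz intra-burst rates; Poisson synaptic events with
biexponential kinetics; evoked responses split into toxin-sensitive/
resistant fractions (control-like default 0.582/0.418) with a depressing
5-pulse profile; 600-s behavioral sessions around realistic investigation
times and path speeds. Every generator records ground truth (component
samples and variances, spike/burst/event times, true fractions, realized
path integrals) sufficient to score the estimators without re-deriving
anything.

Deliberate idealizations, and hence limits on what passing tests show about
real data:

* noise is Gaussian and white (an optional band-limited component exists);
  real LFPs have 1/f backgrounds, nonstationarities and movement artifacts;
* generated oscillations are sinusoidal, so band assignment is cleaner than
  for the asymmetric waveforms of real theta/gamma;
* bursting trains keep bursts and singles separated beyond the 20–50 ms
  criterion range (a hard-core renewal process whose mean interval still
  equals the nominal burst rate), so ground truth is unambiguous — real ISI
  sequences need the per-cell threshold judgment the method leaves to the
  experimenter;
* evoked "drug" sweeps zero the sensitive component instantly; wash-in
  kinetics and series-resistance drift are not modeled (the corresponding
  experimental exclusions are lab QC, not computations).

Sub-streams are seeded per component (seed + 10007·k), so editing one
component of a recipe leaves the others' realizations unchanged.

## Problem sizes and numerical defaults used in the checks

The shipped tests and the acceptance script run on: 10 s at 1 kHz for
completeness; 4 s two-tone fixtures (SNR 10) for band routing; 20 s for the
relative-power mixture; 60 s at 10 kHz with 50 embedded spikes for
detection; 300 s for STA (≈300 locked spikes) and burst-rate recovery;
100-seed Monte-Carlo for τ recovery; 20–40 replicate experiments for the
toxin fraction; and 100 replicate two-cohort comparisons (n = 10 + 10
traces of 2 s) for the rank-test separation of a twofold high-gamma power
difference. These sizes were chosen so each check's sampling error is well
inside its tolerance.
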