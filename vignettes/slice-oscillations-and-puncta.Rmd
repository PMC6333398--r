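---
title: "Methods: sharp wave-ripples, carbachol gamma, and synaptic puncta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sharp wave-ripples, carbachol gamma, and synaptic puncta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`slicephys` re-implements, as a tested pipeline, three quantification
workflows used in hippocampal slice work: detection and characterization
of spontaneous sharp wave-ripple complexes (SPW-Rs) in local field
potential (LFP) recordings, spectral and coherence metrics of
carbachol-induced gamma oscillations, and triple-channel colocalization
of immunofluorescent synaptic puncta. Every analysis is exercised
end-to-end against seeded synthetic data whose ground truth the package
also generates. This vignette documents the models, the defaults and the
numerical decisions, so results can be interpreted — and distrusted —
for the right reasons.

## Signal model and primitives

An LFP trace is a uniformly sampled voltage series in mV with its
sampling rate (10 kHz is the acquisition convention the defaults
assume). Three primitives underlie both oscillation analyses:

* **FFT brick-wall filtering** (`fft_bandpass()`). The whole trace is
  transformed, bins outside the band are zeroed conjugate-symmetrically,
  and the inverse transform is returned. This reproduces the "FFT
  filter" of standard acquisition software: exactly unity in-band,
  exactly zero out-of-band, zero-phase — at the price of ringing around
  sharp transients, which we accept and do not window away. Traces are
  filtered whole, never per analysis window.
* **Welch spectra** (`welch_psd()`). Averaged modified periodograms with
  segment length equal to the transform size (8192 samples), periodic
  Hann window, 50% overlap, mean averaging and one-sided density
  scaling. Only the transform size is pinned by the acquisition
  convention (at 10 kHz it yields the familiar 1.2207 Hz resolution);
  window shape and overlap are the most common Welch defaults and are
  exposed as arguments. Density scaling makes `sum(power) * df` an
  estimate of the signal variance, so areas under spectra carry mV².
* **Autocorrelation** (`autocorrelation()`). The biased (divide-by-n)
  normalized estimator, computed by FFT, with `r(0) = 1` guaranteed. The
  bias keeps `|r| <= 1`; its side effect on coherence fitting is
  corrected downstream (below).

`spectrogram()` provides a Morlet (omega0 = 6) time-frequency view with
log-spaced rows. It exists for visual inspection of ripple structure;
no quantitative metric is derived from it, so the wavelet choice only
affects pictures.

## Sharp wave-ripple detection

The trace is split into a slow component (0–80 Hz low-pass) used for
event detection, amplitude, duration and AUC, and a ripple component
(120–400 Hz band-pass) used for ripple counting at a threshold of 3
standard deviations of the band-passed signal. Choices the convention
leaves open, and how this package resolves them:

* **Detection threshold.** The slow-component threshold is 3 SD of the
  slow component, mirroring the stated ripple convention. Detection is
  polarity-agnostic (absolute deviation from baseline) because sharp
  wave polarity in slice recordings depends on electrode depth.
* **Baseline.** The median of the slow component over the whole trace —
  robust against the skew the events themselves introduce.
* **SD estimation.** Over the full trace, events included. This is the
  simplest faithful reading of "SD of the filtered signal"; it makes
  thresholds slightly conservative on event-dense traces.
* **Boundaries and merging.** Event edges sit at the nearest 1 SD
  crossings flanking the peak; peaks closer than 50 ms merge, keeping
  the larger. With the generator defaults this produces durations in
  the 30–100 ms range expected of SPW-Rs. Overlapping neighbours are
  trimmed at the inter-peak midpoint so events are always disjoint.
* **Ripple frequency** is the reciprocal of the median inter-peak
  interval of supra-threshold ripple maxima — more robust than a
  spectral peak for events containing only a handful of cycles. Events
  with fewer than two counted ripples report frequency 0.
* **AUC** integrates the rectified slow deviation over the event window
  (mV·ms). Rectified rather than signed, so polarity conventions do not
  flip its sign.

Per-slice summaries report medians plus incidence, and the inclusion
rule: accepted only if mean amplitude exceeds 0.04 mV **and** incidence
is at least 1 Hz (60/min), with the failing criterion recorded.

## Gamma metrics

The trailing 5 minutes of a recording are partitioned into
non-overlapping 30-s windows (10 windows per 5 min), each band-passed to
5–200 Hz. Per window, the Welch spectrum yields:

* `f` — bin-centre frequency of the power maximum in the search band
  (default 25–100 Hz; the lower edge aligns with the acceptance rule);
* `pPSD` — that maximum (mV²/Hz);
* the **peak region** — the maximal contiguous bin run containing `f`
  with power at or above half maximum;
* `FWHM` — the width of that region with linear interpolation at the
  half-power crossings, floored at one bin;
* `AUC` — the trapezoidal integral of power over the peak region
  (`pPSD * df` for a single-bin peak). Integrating over the half-max
  region rather than a fixed band makes AUC track the peak the eye sees;
  it is a documented choice, configurable via the metrics function.

Medians across windows are the per-recording values; a recording is
accepted when the median peak frequency strictly exceeds 25 Hz.

**TAU (inner coherence).** Autocorrelation peaks near integer multiples
of the oscillation period (zero lag excluded) are fitted with
`A * exp(-lag/tau)` by least squares on log peaks — deterministic, no
initialization, `A` left free. Three numerical refinements matter on
single recordings:

1. the triangular taper of the biased autocorrelation (factor
   `1 - lag/T` for window length `T`) is divided out first; left in, it
   masquerades as a genuine coherence decay with time constant `T`,
   which dominates whenever TAU is within an order of magnitude of the
   window length;
2. within each period-wide lag window the local maximum *nearest the
   expected lag* is taken, not the largest — taking the largest biases
   noise-floor peaks upward and flattens the fit;
3. the fit is weighted by the squared peak value (the correct relative
   weighting after the log transform) and the peak sequence is truncated
   at the first non-positive peak, beyond which the envelope estimate is
   noise.

Fewer than three usable peaks yields a declared-undefined TAU with a
reason, never a number; an undamped oscillation reports `Inf` with
reason `"non_decaying"`.

Even so, 30-s windows estimate long coherence times with substantial
spread, and the median across ten windows of a 5-min recording can sit
tens of percent away from the value a full-recording fit gives. The
package's tests therefore check windowed TAU for *ordering* (it must
fall as generator phase diffusion rises) and reserve quantitative
recovery checks for full-recording autocorrelations and closed-form
constructions.

## Synthetic LFP generators

The generators define the conditions under which the pipeline is
validated; their defaults are fixed and are not tuned per test.

* **SPW-R traces.** Events at 2/s, 0.1 mV Gaussian deflections
  (SD 10 ms) carrying a 180 Hz ripple at half the sharp-wave amplitude
  under the same envelope, on 1/f Gaussian background noise of 0.01 mV
  SD (SNR 10 against the sharp-wave peak). Event timing uses a
  dead-time renewal process: inter-event intervals are the 250 ms
  refractory interval plus an exponential whose mean tops the interval
  up to `1/rate`, so the *mean rate is exactly the requested rate* while
  no two events fall closer than the refractory gap. (Naive thinning of
  a Poisson stream by a dead time would depress the realized rate by
  ~40% at these settings, breaking rate-recovery validation against the
  planted intensity.) The generator also records, per event, the number
  of ripple cycles exceeding 3 SD of the *noise-free* ripple component —
  its own brute-force oracle for ripple counting.
* **Gamma traces.** `A cos(2*pi*f*t + W(t))` plus white noise, with `W`
  a Wiener phase walk of variance rate `D` (rad²/s). This puts the
  coherence loss where the TAU model assumes it: the autocorrelation
  envelope decays as `exp(-D*lag/2)`, i.e. an expected TAU of `2000/D`
  ms, tunable independently of amplitude. The recorded ground-truth TAU
  is measured by a direct-lag correlation fit on the noise-free
  oscillation — a code path separate from the analysis machinery.
* Both generators are bit-reproducible for a given seed, and every
  planted event appears exactly once in the truth tables.

What these generators do *not* emulate: non-stationary event rates,
amplitude/duration distributions across events (all planted sharp waves
share one amplitude), CA3-to-CA1 propagation, theta or other competing
rhythms, electrode drift, and line noise. Passing tests therefore show
the *estimators* are correct under the stated statistical structure, not
that real slices will be this clean.

## Puncta stacks and colocalization

Quantification follows the projection-based convention: per channel, the
maximum-intensity projection of the 8-section stack is segmented
(fixed or Otsu threshold, connected components at configurable 4/8
connectivity, area-filtered), and a reference-channel punctum counts as
triple-positive when its pixel set overlaps foreground of both other
channels by at least one pixel (configurable). Per-section
colocalization is not part of the convention being reproduced and is
not implemented; densities are reported per 100 µm². The synthetic
generator plants non-overlapping disk puncta with controlled per-channel
presence flags (a set fraction triple-positive, the rest two-channel,
plus single-positive extras), optional inter-channel jitter, noise and
blur, and errors out rather than silently packing sites too densely.
Default connectivity 8 with a 4-px minimum area suppresses single-pixel
noise. Stacks travel as channel-major multi-page TIFF with a JSON
sidecar for geometry; 16-bit storage quantizes intensities to 1/65535,
which is far below any threshold the package applies.

Real confocal data differ in ways the generator ignores: empty point
spread, autofluorescence, intensity gradients, puncta touching and
overlapping, and anisotropic z-blur. The exact-recovery tests
(triple counts equal to the plant) certify the counting logic, not
robustness to those artifacts; the blurred/noisy variants probe only
mild departures.

## Statistical decision tree

Group comparisons reproduce the conventional gate: Shapiro-Wilk per
group at alpha 0.05 (configurable); all groups normal leads to one-way
ANOVA with pooled-variance pairwise t comparisons under step-down
Holm-Sidak correction, any group non-normal leads to Kruskal-Wallis
with Dunn's rank-based z comparisons (tie-corrected,
Bonferroni-adjusted). "Not normally distributed" is read conservatively
as *any* group failing the gate. Two-group calls compute both Student's
t (equal variances, as "Student's t" implies) and Mann-Whitney, and
promote one per the same gate; zero-variance groups are flagged
degenerate rather than tested. The decision path taken is always
recorded in the result object. Under 1000 null simulations (four
N(0,1) groups, n = 10) the parametric branch's family-wise error sits
at the nominal level — the acceptance script recomputes this on every
run. Reporting conventions follow the respective domains:
median ± IQR for electrophysiology (per-slice values), mean ± SEM for
imaging (per-animal values), with reference-group normalization mapping
the control mean to 1.

## Problem sizes

The shipped tests and the acceptance script validate on: 10 synthetic
slices of 60 s at 10 kHz for SPW-R recovery; 30–90 s gamma recordings
(1–3 windows) plus closed-form autocorrelations for TAU; 256-px,
8-section stacks with 100 sites for colocalization; and 1000 null
replicates for the error-rate calibration. These sizes keep a full
validation run in the low minutes on one core while leaving every
estimator in its intended operating regime; the `analysis/` drivers run
the same code over a 16-slice simulated design.

## Known limitations

* Brick-wall filtering rings at sharp edges; event boundaries derived
  from the slow component inherit a few-ms uncertainty.
* The ripple-count threshold uses the SD of the *noisy* ripple band, so
  against the generator's noise-free oracle a cycle near threshold can
  drop; tests allow one cycle of slack at nonzero noise.
* Windowed TAU medians are upward-biased when the true coherence time
  approaches the window length (see above).
* The amplitude inclusion rule uses the mean event amplitude; slices
  with heavy-tailed amplitude distributions can be accepted or rejected
  differently than a median-based rule would decide.
* Otsu thresholding assumes a bimodal intensity histogram; sparse or
  dim channels may need the fixed threshold with a recorded value.
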