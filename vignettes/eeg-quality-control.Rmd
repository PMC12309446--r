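---
title: "Automated quality control for field EEG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated quality control for field EEG: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegqc)
```

## The problem

Field EEG programs collect thousands of short resting-state recordings
(16 channels of the 10–20 system at 256 Hz; ~3 minutes per condition:
eyes closed, eyes open, task) under conditions far from a shielded lab:
open-air sites, variable hair and electrode contact, mains contamination,
movement and eyeblink artifacts. Data quality must be scored automatically,
per recording, the same day, so that supervisors can trace problems to a
team or a device before weeks of data are lost. This package implements
that scoring pipeline end to end, together with the statistics used to
compare cohorts and the synthetic data used to validate every stage.

## The detection model

All detection operates on the recording after a 0.5 Hz high-pass filter,
and epoch-level criteria on non-overlapping 2 s epochs (so a 3-minute
recording has N = 90 epochs, and one bad epoch is 1.11%; one bad channel of
16 is 6.25%).

### FASTER-family criteria (threshold |Z| > 3)

Each criterion computes one statistic per channel (or epoch) and
standardizes it *across* channels (or epochs) with the sample Z-score.
This makes every criterion invariant to global gain — only relative
abnormality is flagged. Channel statistics:

* **correlation** — mean absolute Pearson correlation with every other
  channel over the whole recording. We use the unweighted mean (no
  electrode-distance weighting), since the montage file ships as editable
  data and distances are not guaranteed.
* **variance** of the channel.
* **Hurst exponent** — rescaled-range (R/S) estimate over dyadic block
  sizes 16 … length/4, least-squares slope of log mean(R/S) vs log block
  size. EEG-like signals cluster tightly; electrode pops and disconnected
  channels deviate. The estimator has a small positive bias on white noise
  (≈ 0.55 rather than 0.5 at 2^16 samples); this is irrelevant here because
  only the cross-channel Z matters.
* **powerline** — mean Welch band power over 48–62 Hz, one band covering
  both 50 and 60 Hz mains so the same configuration works across sites.

Epoch statistics: amplitude range and within-epoch variance (averaged
across channels), and the *deviation parameter*: the epoch-mean of each
channel minus that channel's average epoch-mean, averaged across channels.
The reference mean is channel-wise (each channel is compared with its own
average), the reading we consider most faithful to "deviation of an
epoch's average value"; the per-channel construction is exposed in the
result so the alternative (grand-mean) reading can be recomputed.

All FASTER flags are two-sided (|Z| > 3). A statistic with zero spread
yields all-zero Z-scores and no flags: identical channels are not evidence
of badness. With M channels the sample Z-score is bounded by
(M−1)/√M, so at least 11 channels are needed before |Z| > 3 can fire at
all — one reason the epoch criteria (N = 90) are more sensitive than the
channel criteria on small montages.

### PREP-family criteria (robust threshold 5)

Robust statistics replace mean/sd with median and the IQR-based robust
spread `(Q3 − Q1) × 0.7413`; the factor is `1/(2Φ⁻¹(0.75))`, making the
spread consistent for the standard deviation under Gaussianity while
tolerating up to 25% outliers per tail. Channel criteria:

* **flat/NaN** — any NaN; or peak-to-peak below 1e−15 μV over the channel
  or in more than 1% of 2 s windows. This is the only absolute-scale
  (gain-sensitive) criterion, deliberately: a flat channel is flat in
  microvolts, not relative to its neighbours. Channels flagged here are
  excluded from the cross-channel standardization and the correlation pool
  of the remaining criteria, so one dead channel cannot mask another.
* **amplitude** — robust spread of the full signal, |robust Z| > 5 across
  channels. Two-sided: both inflated (artifact) and collapsed (poor
  contact) amplitude are abnormal.
* **correlation** — per 2 s window, the channel's maximum absolute
  correlation with any other channel; flagged when below 0.4 in more than
  1% of windows. The window length is 2 s throughout, matching the epoch
  length used everywhere else in the pipeline.
* **noisiness** — ratio of high- to low-frequency robust amplitude after a
  50 Hz zero-phase FIR split, robust Z > 5 one-sided (an unusually *clean*
  high band is not a defect).

The epoch-level criterion standardizes, per channel across its N epochs,
both the epoch median (catches drift and baseline jumps) and the epoch
robust spread (catches bursts), takes the larger magnitude, and flags the
epoch when the maximum over channels exceeds 5 — a single-channel artifact
is enough, by design. Both components are returned in the result, so a
location-only or scale-only reading can be recovered. Note one structural
consequence of robustness: a transient occupying under ~25% of an epoch's
samples moves the epoch's IQR only partially, so very brief spikes are
detected mainly through the FASTER range criterion, while PREP excels at
sustained within-epoch artifacts.

## Filtering and epoching

Filters are Hamming-window FIR designs applied with exact zero phase: the
symmetric (linear-phase) kernel is applied once by FFT convolution after
reflect-padding by one filter length, and the integer group delay is
removed. A single zero-phase pass preserves the designed magnitude
response (a forward–backward pass would square it); zero phase matters
because channel- and epoch-level criteria must see sample-aligned data.
Transition bandwidths: 0.5 Hz for the 0.5 Hz high-pass (1691 taps at
256 Hz), 5 Hz for the 50 Hz split (169 taps). The high-pass kernel is
offset-corrected so its DC gain is exactly zero. Recordings shorter than
one filter length are rejected explicitly. Epochs are contiguous and
non-overlapping; a trailing partial epoch is discarded.

## Spectra and peak alpha frequency

Welch spectra use a Hann taper, 2 s windows, 50% overlap, one-sided
scaling in μV²/Hz, so the bin width is 0.5 Hz and integrated power equals
variance. Peak alpha frequency (PAF) is the argmax bin within 7–12 Hz
(endpoints inclusive; ties broken toward the lower frequency; no
interpolation or 1/f correction — the estimate is deliberately the plain
spectral peak). Two summaries are reported: the mean of per-channel peaks,
and the peak of the channel-averaged spectrum. They differ when some
channels carry little alpha (frontal sites, flat channels): the averaged
spectrum is dominated by channels with real alpha and is the more stable
of the two, which is why both are labelled rather than collapsed.

## Aggregation, comparison, dashboard

Per-recording results become percentages (`100 × flagged/total`). Group
cells pool counts — the pooled percentage is the channel-count-weighted
mean of per-recording percentages — and the unweighted per-recording mean
is emitted alongside, since summary tables in the wild use either
convention. Cohort contrasts use two-sided Welch t tests (the safer
default when "a t test" is unspecified); no multiple-testing correction is
applied across the contrast grid, matching the reporting style this
dashboard mirrors.

For field-vs-benchmark comparisons where one sample is far larger, the
bootstrap comparison draws, per iteration, a subsample of the benchmark's
size *without replacement* from the field values ("samples from the
dataset" semantics), runs a Welch t test, and reports the mean p over
iterations (default 50). With one iteration and equal sizes this is
exactly a single t test. The mean-p statistic is calibrated rather than
uniform under the null: its expectation is 0.5 but its spread across
benchmark draws is substantial at n = 60, so the package's own calibration
check averages over 20 independent null replicates of 200 iterations each.

The daily report aggregates summaries at four scopes — overall, per
condition, per team, per device — with on-date and year-to-date (same
calendar year) counts: recordings, nonstandard montage channels, missing
channels (out of 16), and the pooled percentages. Condition rows and team
rows each partition the overall row exactly. Future-dated records are an
error, not silently dropped. Because the protocol's exact electrode names
are documented only graphically, the standard-16 and alternate montage
sets ship as an editable CSV (`inst/extdata/montage_flex16.csv`); labels
outside both sets are a validation error, surfacing metadata-capture
problems rather than absorbing them.

## The synthetic generator

`synthetic_spec()` defaults describe the recording protocol: 16 channels,
256 Hz, 180 s, eyes closed. The signal model is

* a background of four shared pink-noise sources (PSD ∝ 1/f^1, spectral
  synthesis) mixed into channels with a dominant common source — this
  keeps clean channels' windowed correlations well above the 0.4 PREP
  threshold, as in real EEG where volume conduction correlates neighbours;
  per-channel amplitude 15 μV;
* an alpha rhythm: amplitude-modulated sinusoid (0.3 modulation depth at
  0.1 Hz) at the spec's peak frequency, 8 μV, weighted 0.5 → 1.5 from
  frontal to posterior channels (the default montage is ordered front to
  back);
* 2 μV per-channel white noise; optional 50/60 Hz mains.

Artifacts with ground-truth labels: `flat_channel` (zeros),
`noisy_channel` (+150 μV white noise by default), `uncorrelated_channel`
(independent pink noise), `burst_epoch` (200 μV Gaussian-windowed 5 Hz
burst, ~0.4 s), `blink` (biphasic ~0.3 s deflection decaying from frontal
channels). Magnitudes are calibration choices documented here, not field
measurements — artifact sizes in the field are unreported, and these
defaults were chosen once to sit clearly above the detection thresholds
while leaving clean channels clean. All randomness flows through one seed;
the same spec and seed reproduce a recording bit for bit.

What the generator does *not* emulate: biophysical head geometry, task
structure, non-stationary background, impedance drift, heavy-tailed
real-world artifact diversity. Passing detector-recovery tests on this
generator therefore demonstrates that the criteria are implemented
correctly and calibrated sensibly — not that field recovery rates will
match these numbers.

## Validation and problem sizes

The test suite checks each criterion against loop-based reference
implementations (exact agreement on 100 seeded toys), recovery of injected
artifacts with ≥90% sensitivity and ≤10% false flags over 20 seeded
recordings, bootstrap null calibration (mean p within [0.35, 0.65]) and
power under a 5-sd shift (mean p < 0.01), PAF recovery to within half a
0.5 Hz bin over 50 recordings, and dashboard partition/pooling identities.
Tests use 8–60 s recordings; the acceptance script
(`scripts/acceptance.R`) uses the full 180 s protocol length for the
recovery experiments — both lengths give the detectors ≥30 epochs, ample
for the cross-epoch standardizations. In the recovery experiments the
burst epoch is injected on a channel distinct from the injected bad
channel: a burst added onto an already-replaced channel would be masked by
construction, which would measure the experiment, not the detector.

## Known limitations

* FASTER channel criteria are insensitive on montages below ~11 channels
  (bounded Z-scores) and the package refuses fewer than 4.
* The PREP epoch criterion under-weights very brief transients (IQR
  robustness); pair it with FASTER, as `run_qc()` does.
* EDF export quantizes to 16 bits over each channel's observed range;
  CSV is the loss-free interchange.
* The Hurst estimator is the classical R/S slope; alternatives (DFA) would
  need to be swapped in at `hurst_exponent()` if EEG with strong trends is
  analyzed.
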