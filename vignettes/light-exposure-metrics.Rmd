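---
title: "Quantifying personal light exposure with lightdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying personal light exposure with lightdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lightdose)
```

## The problem

Light is the dominant zeitgeber of the human circadian system, and wrist-worn
light loggers and dosimeters now make it routine to record a person's light
exposure for days to weeks at epochs of 15 s to 1 min. Relating those
recordings to sleep, mood or metabolic outcomes requires a small set of
standard summary metrics — time above threshold, mean light timing, the
L5/M10 nonparametric windows, interdaily stability and intradaily
variability — computed after careful conditioning of the raw series
(non-wear masking, truncation, resampling, filtering, log transformation).
`lightdose` implements that pipeline device-agnostically: any logger whose
export is a delimited text file with a timestamp column and one or more
numeric light channels can be analysed, without vendor-specific parsers.

## Data model

A recording is a set of channels on one strictly regular timestamp grid
(`light_recording`), each channel an `epoch_series` of non-negative
intensities (lux, melanopic EDI, or any other photometric quantity — the
metrics are agnostic). Three conventions hold everywhere:

* **Clock time, not civil time.** Timestamps are timezone-naive local clock
  time; daylight-saving transitions are not modelled. All metrics below are
  defined on the 24-h clock, so clock time is the correct axis; recordings
  spanning a DST change should be split or shifted by the user.
* **Epoch-start, half-open intervals.** Daily period `h` (1-based) covers
  clock interval `[(h-1)·Δ, h·Δ)` for epoch length `Δ`; truncation windows
  and mask intervals are half-open `[start, stop)`. This makes "6 days of
  minute data" exactly 8640 epochs, with no boundary double-counting.
* **Masked = missing.** A masked epoch (non-wear, covered sensor) and a
  missing value are treated identically downstream: excluded from every sum
  and count. Irregular sampling is rejected at construction rather than
  silently resampled, because every formula below assumes a constant epoch.

The day-folding primitive `daily_profile()` computes the per-clock-period
means across days (the vector \(\bar x_h\)); MLiT, IS and L5/M10 all reduce
to operations on this folded representation. Folding conserves the grand
mean (the count-weighted mean of the profile equals the mean of all valid
values), which the test suite checks to 1e-12 relative. Whether leading and
trailing partial days should be dropped before folding is not a settled
convention, so it is exposed as the `whole_days_only` flag (default
`FALSE`) rather than fixed.

## Preprocessing

**Masking** (`apply_mask`) sets mask bits from half-open interval files;
existing bits are never cleared, so masks compose by union, commutatively
and idempotently. Mask files are JSON (`{"masks": [{"start": ..., "stop":
...}]}`) — editable by hand, with unambiguous ISO-8601 timestamps.

**Resampling** (`resample`) aggregates non-overlapping blocks with `sum`,
`mean`, `median`, `min` or `max` over the valid values in each block; an
all-missing block stays missing, and block timestamps are left-labelled
(block start), matching the epoch-start convention.

**Filtering** (`butterworth_filter`) applies a Butterworth filter forward
and backward, so the result is zero-phase and the effective amplitude
response is the squared one-pass magnitude. Cutoffs are given in cycles per
day — the natural unit for circadian work (the diurnal rhythm is 1
cycle/day) — and converted internally via the epoch length. The default
order is 3, a common compromise between roll-off and ringing; it is
overridable. Two numerical decisions matter:

* the series must be gap-free — silently interpolating across non-wear gaps
  would fabricate data, so gap policy stays with the caller;
* edge transients are controlled by odd-reflection padding whose length is
  derived from the slowest filter pole (long enough for transients to decay
  below ~1e-8 of signal scale, capped at the series length), so DC gain is
  1 to better than 1e-6 and interior amplitudes match the analytic
  forward–backward response. Output is not clipped: small negative
  excursions near sharp transitions are a property of linear filtering, and
  clipping would bias downstream means.

**Thresholding.** `threshold_filter` discards values at or below `C`;
`binarize` maps to 1/0. The comparison is *strict* (`value > C` counts as
"above") and the same rule is used in TAT, MLiT and the exposure level, so
the identities between these operations hold exactly. Strict-vs-non-strict
is immaterial for continuous data but must be consistent; strictness was
chosen once and is documented here.

**Log transform.** `log_transform(series, offset)` computes
`log10(value + offset)`. Illuminance spans ~7 orders of magnitude, so
thresholds are conventionally placed on the log scale: a 100-lux criterion
becomes `log10(100 + 1)` with the customary offset of 1 keeping darkness
finite at 0.

## The metrics

Let \(x_i\) be the intensity at period \(i\), \(n\) the number of valid
periods, \(p\) (or \(m\)) the number of periods per day, and \(\bar x\) the
grand mean over valid values.

**Exposure level.** The mean of the valid values strictly above a threshold
`C` (plain mean when `C` is omitted). The field uses "exposure level" with
a threshold argument but no canonical formula; the thresholded mean is the
natural reading and is what this package computes — flagged here because
other tools may differ.

**TAT.** Time above threshold: the count of valid epochs with
\(x_i > C\) times the epoch length, reported in minutes, as a time delta,
or as a raw count. Identically `epoch * sum(binarize(series, C))`.

**MLiT.** Mean light timing above threshold (Reid et al.):
\[
\mathrm{MLiT}(C) \;=\; \frac{\sum_{j=1}^{m}\sum_{k=1}^{n} j\, I_{jk}(C)}
                            {\sum_{j=1}^{m}\sum_{k=1}^{n} I_{jk}(C)},
\]
the mean 1-based daily-period index of supra-threshold epochs over days
\(k\). Missing epochs contribute 0 to both sums; when nothing exceeds `C`
the ratio is 0/0 and the result is reported as missing with
`exceedance_count = 0` rather than as an error, since "never above
threshold" is a legitimate observation. The index is converted to clock
time as `(index − 1)·Δ` after midnight, per the epoch-start convention. By
construction MLiT is invariant under strictly monotone transforms of the
values (with the threshold transformed accordingly), so it does not matter
whether it is computed on raw or log-scale data.

**L5/M10.** The 5-h window of least and 10-h window of maximal exposure.
Three design choices were genuinely open and are fixed as follows: the
windows are located on the *averaged* daily profile (not per-day, not on
the raw concatenated series), candidate onsets wrap circularly around
midnight (essential for L5, which typically straddles the night), and ties
are broken by the earliest onset in [00:00, 24:00). Averaging first matches
the nonparametric circadian-analysis tradition and makes the result
deterministic; a candidate window is eligible only if every profile period
inside it has data, since a partial mean over a 5-h window is not
comparable to complete ones.

**IS and IV.**
\[
IS = \frac{n \sum_{h=1}^{p} (\bar x_h - \bar x)^2}
          {p \sum_{i=1}^{n} (x_i - \bar x)^2},
\qquad
IV = \frac{n \sum_{i=1}^{n-1} (x_{i+1} - x_i)^2}
          {(n-1) \sum_{i=1}^{n} (x_i - \bar x)^2}.
\]
IS is the fraction of variance explained by the mean 24-h profile: 1 for a
perfectly repeated daily pattern, expectation \(1/d\) for \(d\) days of
independent noise. IV is the normalized mean squared successive
difference: ≈2 for independent noise, small for smooth profiles, up to 4
for strict alternation. Both are 0/0 for a constant series and raise a
typed `undefined_metric` error (which `compute_metric_table` converts to a
missing cell so batch runs never abort). With missing data, IS uses all
valid values (\(n\) = valid count, profile means over available values,
\(p\) kept at periods-per-day as in the defining formula), and IV sums only
over adjacent pairs where both values are valid, the \(n-1\) factor
becoming the valid-pair count — the natural generalizations of formulas
written for complete data. Both metrics are sensitive to the sampling
frequency, so the optional `freq` argument resamples (mean aggregation)
to an explicit analysis epoch first; 1 h is the conventional choice, and
whether to compute them on raw or log-transformed values is likewise left
to the caller (the worked examples log first).

**Periodogram.** `is_at_period()` evaluates the same variance ratio with an
arbitrary folding period; at 24 h it *is* IS (same code path), and scanned
over trial periods it is a chi-square periodogram normalized by \(n\),
peaking near the dominant periodicity.

## The synthetic generator

`generate_recording()` emulates the regimes a wrist logger actually sees:
a smooth Gaussian-bell daylight template (default peak 10,000 lux at 13:00,
SD 3 h — bright afternoon daylight) when the wearer is outdoors, a constant
indoor level (default 200 lux, typical office illuminance) otherwise, with
the outdoor state drawn per epoch from an hour-of-day probability profile
(commute and lunch peaks, zero at night) and multiplicative lognormal noise
(default CV 0.5). Non-wear intervals arrive as a Poisson process (default
0.5/day, mean 30 min, exponential durations) and record 0 lux, as a covered
sensor does; the true intervals and per-epoch state labels are returned so
tests can verify masking against ground truth. Defaults produce 8-day,
1-min recordings, mirroring the common field protocol of ~week-long wear
analysed over the first 6 whole days.

The generator is deliberately *not* radiometrically realistic: no spectra,
no weather, no geolocation, no seasonal photoperiod, and the indoor level
does not dim in the evening. Passing tests therefore demonstrate
correctness of the *computations* on data with realistic structure
(diurnal rhythm, level switching, heavy-tailed noise, gaps) — not that any
particular population's exposure statistics are reproduced. A single seed
drives one reproducible stream, so cohorts regenerate byte-identically.

## Problem sizes and verification

The test suite verifies every metric against an independent oracle: MLiT
against a literal transcription of the double sum (100 random series, 2–5
days, 12–48 periods/day, exact agreement), L5/M10 against an exhaustive
circular scan of all onsets (50 random profiles), IS against a direct
formula transcription and its analytic limits (periodic → 1 within 1e-9;
200 replicates of 7-day hourly noise → mean within 0.02 of 1/7), IV
against closed forms (alternating series → exactly 4; 100 replicates of
iid noise at n = 10⁴ → mean in [1.95, 2.05]; 28-day hourly sinusoid →
within 1% of \(4\sin^2(\pi/24)\)), and the Butterworth filter against its
analytic forward–backward magnitude response (within 5% at probe
frequencies; DC to 1e-6). The end-to-end check generates a 5-subject
cohort, runs the batch CLI pipeline with the conventional parameter idiom
(first 6 days, thresholds `log10(100+1)` and `log10(500+1)` on the
`log10(x+1)` scale), and requires cell-exact agreement with direct library
calls plus byte-identical reruns. `scripts/acceptance.R` repeats that
cohort computation from scratch at any seed.

## Limitations

* No spectral (per-wavelength, α-opic) quantities: melanopic conversions
  belong to dedicated tools; `lightdose` treats whatever the channel
  records as "intensity".
* No automated non-wear detection; masking is interval-file-based.
* No imputation: masked/missing epochs are excluded, never filled.
* Vendor binary formats are out of scope; export to text first.
* Statistical comparison between groups (tests, plots) is left to standard
  R tooling on the summary tables.
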