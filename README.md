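# lightdose

Metrics and preprocessing for wearable light-logger recordings.

Light is the principal zeitgeber of the human circadian clock, and
wrist-worn light loggers and dosimeters record a person's light exposure as
multi-day time series at fixed epochs (typically 15 s – 1 min).
`lightdose` is for chronobiologists and sleep/light researchers who need to
turn such recordings — from *any* device whose export is a delimited text
file — into the field's standard exposure metrics, reproducibly and in
batch:

- **Summary statistics** over the recording or arbitrary windows.
- **Exposure level**: mean intensity strictly above a threshold *C*.
- **TAT(C)** — time above threshold: the number of epochs with
  *x<sub>i</sub> > C*, times the epoch length.
- **MLiT(C)** — mean light timing above threshold (Reid et al.):

  MLiT(C) = Σ<sub>j=1..m</sub> Σ<sub>k=1..n</sub> j·I<sub>jk</sub>(C) / Σ<sub>j</sub> Σ<sub>k</sub> I<sub>jk</sub>(C)

  with I<sub>jk</sub> = 1 when the intensity at daily period *j* of day *k*
  exceeds *C* (*m* = 1440 for minute data), reported as a clock time.
- **L5 / M10**: the 5-h window of least and the 10-h window of maximal
  exposure on the average daily profile, with circular (midnight-wrapping)
  windows.
- **IS / IV** — interdaily stability and intradaily variability:

  IS = n Σ<sub>h=1..p</sub> (x̄<sub>h</sub> − x̄)² / [ p Σ<sub>i=1..n</sub> (x<sub>i</sub> − x̄)² ]  
  IV = n Σ<sub>i=1..n−1</sub> (x<sub>i+1</sub> − x<sub>i</sub>)² / [ (n−1) Σ<sub>i=1..n</sub> (x<sub>i</sub> − x̄)² ]

  IS is the 24-h chi-square periodogram value normalized by *n*
  (`is_at_period()` evaluates it at any trial period).

Around the metrics sits the conditioning layer every real recording needs:
non-wear **masking** from half-open interval files, **truncation**,
**resampling** with custom aggregation, zero-phase **Butterworth
filtering** (cutoffs in cycles/day), **log transform**, **thresholding**
and **binarization** — plus a seeded **synthetic-recording generator** and
a **CLI** for cohort workflows. See the vignette
(`vignettes/light-exposure-metrics.Rmd`) for the modelling conventions and
design decisions.

## Worked example

```r
library(lightdose)

## generate a synthetic 8-day wrist recording and write it as CSV
params <- synthetic_params(n_days = 8, seed = 42)
sim <- generate_recording(params)
write_fixture(sim$recording, "subject.csv")

## read it back (first 6 days) and log-transform the masked channel
rec <- read_recording("subject.csv", csv_dialect("White Light"), period = "6D")
rec
#> <light_recording> 'subject': 8640 epochs @ 60s, channels [White Light], 0 masked
s <- log_transform(channel_data(rec, "White Light", masked = TRUE), offset = 1)

## exposure metrics at the conventional thresholds (log10(x + 1) scale)
light_exposure_level(s, log10(101))   # mean log-intensity above 100 lux
#> [1] 2.48394
tat(s, log10(101), "minute")          # minutes above 100 lux in 6 days
#> [1] 7536
mlit(s, log10(501))                   # mean timing of >500 lux exposure
#> <mlit_result> index 798.156 / m=1440 -> clock time 13:17:09 (1144 exceedances over 6 day(s))

## nonparametric circadian metrics on the raw series at a 1 h analysis epoch
raw <- channel_data(rec, "White Light", masked = TRUE)
interdaily_stability(raw, freq = "1H")
#> [1] 0.9260935
intradaily_variability(raw, freq = "1H")
#> [1] 0.5597106
l5m10(raw)$M10
#> <window_result> 10h window from 08:02:00, mean 1766
l5m10(raw)$L5
#> <window_result> 5h window from 23:32:00, mean 182.8
```

The numbers read naturally: this simulated wearer spends 7536 of 8640
recorded minutes above 100 lux, their >500 lux exposure is centred at 13:17
(the afternoon daylight peak), the most-lit 10 hours start at 08:02 and the
dimmest 5 hours straddle midnight; a stable day-to-day routine gives IS
0.93, and the smooth diurnal profile gives a low fragmentation IV of 0.56.

Batch workflows mirror the same pipeline over a file glob and write a
summary CSV (one row per recording), either in R:

```r
cfg <- run_config(
  input = "cohort/subject_*.csv",
  metrics = list(
    Level_100 = list(metric = "light_exposure_level", threshold = log10(101)),
    TAT_100   = list(metric = "tat", threshold = log10(101), output_format = "minute"),
    MLit_500  = list(metric = "mlit", threshold = log10(501))),
  output = "tab1.csv", period = "6D", log10_offset = 1)
cmd_metrics(cfg)
```

or from a shell via the bundled entry point:

```sh
Rscript inst/cli/lightdose simulate --params params.json --n-subjects 5 --output-dir cohort
Rscript inst/cli/lightdose metrics --input 'cohort/subject_*.csv' \
    --output tab1.csv --period 6D --log10-offset 1 \
    --metric 'TAT_100=tat:threshold=lux:100,oformat=minute' \
    --metric 'MLit_500=mlit:threshold=lux:500'
```

(`lux:100` means `log10(100 + 1)` whenever a log transform is active.)

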