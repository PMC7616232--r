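#' Mask epochs falling inside exclusion intervals
#'
#' Sets the recording mask to `TRUE` for every epoch whose timestamp lies
#' in the union of the spec's half-open intervals. Existing mask entries
#' are preserved (union semantics -- applying masks is commutative and
#' idempotent), and channel values are untouched: masking only controls
#' which epochs contribute to downstream analyses. Intervals that do not
#' intersect the recording are ignored.
#'
#' @param recording a [light_recording()].
#' @param spec a [mask_spec()].
#' @return the recording with its mask updated.
#' @export
apply_mask <- function(recording, spec) {
  ld_assert(inherits(recording, "light_recording"), "parameter",
            "expected a light_recording")
  ld_assert(inherits(spec, "mask_spec"), "parameter", "expected a mask_spec")
  t <- as.numeric(recording$time)
  hit <- rep(FALSE, length(t))
  for (i in seq_len(nrow(spec)))
    hit <- hit | (t >= as.numeric(spec$start[i]) & t < as.numeric(spec$stop[i]))
  recording$mask <- recording$mask | hit
  recording
}

#' Restrict a recording to a continuous time window
#'
#' Keeps the epochs in the half-open window `[start, start + period)`;
#' channels and mask are sliced consistently.
#'
#' @param recording a [light_recording()].
#' @param start window start (timestamp).
#' @param period window length (duration token or seconds).
#' @return the truncated [light_recording()].
#' @export
truncate_recording <- function(recording, start, period) {
  ld_assert(inherits(recording, "light_recording"), "parameter",
            "expected a light_recording")
  start <- ld_time(start)
  span <- parse_duration(period)
  t <- as.numeric(recording$time)
  keep <- t >= as.numeric(start) & t < as.numeric(start) + span
  ld_assert(any(keep), "empty_selection",
            "window [%s, +%gs) does not intersect the recording",
            format_time(start), span)
  recording$time <- recording$time[keep]
  recording$channels <- lapply(recording$channels, function(v) v[keep])
  recording$mask <- recording$mask[keep]
  recording
}

agg_fun <- function(agg) {
  ld_assert(is.character(agg) && length(agg) == 1L &&
              agg %in% c("sum", "mean", "median", "min", "max"),
            "parameter",
            "agg must be one of 'sum', 'mean', 'median', 'min', 'max'")
  switch(agg, sum = sum, mean = mean, median = stats::median,
         min = min, max = max)
}

#' Resample a series to a coarser epoch
#'
#' Aggregates consecutive non-overlapping blocks of
#' `k = new_epoch / epoch_length` epochs with the chosen function, applied
#' to the non-missing values in each block; a block with no valid value
#' becomes missing. Block timestamps use the block-start (left-labelled)
#' convention, matching the epoch-start convention used throughout.
#' A trailing incomplete block is aggregated over the epochs it has.
#'
#' @param series an [epoch_series()].
#' @param new_epoch target epoch (duration token or seconds); must be a
#'   positive integer multiple of the current epoch.
#' @param agg one of `"sum"`, `"mean"`, `"median"`, `"min"`, `"max"`.
#' @return the resampled [epoch_series()].
#' @export
resample <- function(series, new_epoch, agg = "mean") {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  target <- parse_duration(new_epoch)
  k <- target / series$epoch
  ld_assert(abs(k - round(k)) < 1e-9 && k >= 1, "resample_incompatibility",
            "new epoch (%gs) is not an integer multiple of the current epoch (%gs)",
            target, series$epoch)
  k <- as.integer(round(k))
  if (k == 1L) return(series)
  f <- agg_fun(agg)
  n <- length(series)
  block <- (seq_len(n) - 1L) %/% k
  vals <- vapply(split(series$values, block), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else f(v)
  }, numeric(1))
  times <- series$time[!duplicated(block)]
  new_epoch_series(times, unname(vals), target)
}

#' Zero-phase Butterworth filter
#'
#' Applies a Butterworth filter forward and backward (zero-phase
#' filtering), so the output has no phase distortion and the effective
#' amplitude response is the squared magnitude of the one-pass filter.
#' Cutoffs are given in cycles per day -- the natural unit for circadian
#' data -- and converted internally using the epoch length. The series
#' must be gap-free: how to bridge missing epochs (masking out, resampling,
#' interpolation) is a modelling decision left to the caller. Output
#' values may be slightly negative near sharp transitions (a standard
#' linear-filtering artifact) and are not clipped.
#'
#' @param series a gap-free [epoch_series()].
#' @param kind `"lowpass"`, `"highpass"`, `"bandpass"` or `"bandstop"`.
#' @param cutoffs one cutoff frequency (low/highpass) or two strictly
#'   increasing frequencies (bandpass/bandstop), in cycles per day; all
#'   must lie below the Nyquist frequency `86400 / (2 * epoch)`.
#' @param order filter order (default 3).
#' @return the filtered [epoch_series()]; values may be negative.
#' @export
butterworth_filter <- function(series, kind = "lowpass", cutoffs, order = 3L) {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  if (anyNA(series$values))
    ld_stop("missing_data",
            "series contains missing values; resolve gaps before filtering")
  ld_assert(kind %in% c("lowpass", "highpass", "bandpass", "bandstop"),
            "parameter", "unknown filter kind '%s'", kind)
  n_cut <- if (kind %in% c("lowpass", "highpass")) 1L else 2L
  ld_assert(length(cutoffs) == n_cut, "invalid_filter",
            "%s filter requires exactly %d cutoff(s)", kind, n_cut)
  ld_assert(all(is.finite(cutoffs)) && all(cutoffs > 0), "invalid_filter",
            "cutoffs must be positive and finite")
  if (n_cut == 2L)
    ld_assert(cutoffs[1] < cutoffs[2], "invalid_filter",
              "bandpass/bandstop cutoffs must be strictly increasing")
  ld_assert(order >= 1 && order == round(order), "parameter",
            "order must be a positive integer")
  fs_cpd <- 86400 / series$epoch            # sampling rate, samples per day
  nyquist <- fs_cpd / 2
  ld_assert(all(cutoffs < nyquist), "invalid_filter",
            "cutoff %g cycles/day is not below the Nyquist frequency (%g cycles/day)",
            max(cutoffs), nyquist)
  type <- switch(kind, lowpass = "low", highpass = "high",
                 bandpass = "pass", bandstop = "stop")
  coef <- signal::butter(as.integer(order), cutoffs / nyquist, type = type)
  out <- series
  out$values <- zero_phase_filter(coef$b, coef$a, series$values)
  out
}

# Forward-backward filtering with odd-reflection padding. The pad length is
# chosen from the slowest pole of the filter so that edge transients decay
# below ~1e-8 of the signal scale before reaching the data (capped at n-1
# for short series).
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  poles <- polyroot(rev(a))
  maxr <- min(max(Mod(poles)), 1 - 1e-6)
  padlen <- max(3 * (length(a) - 1), ceiling(-18.5 / log(maxr)))
  padlen <- min(n - 1, padlen)
  idx_front <- seq.int(padlen + 1, 2)
  idx_back <- seq.int(n - 1, n - padlen)
  ext <- c(2 * x[1] - x[idx_front], x, 2 * x[n] - x[idx_back])
  y <- as.numeric(signal::filter(b, a, ext))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[seq.int(padlen + 1, padlen + n)]
}

#' Base-10 logarithmic transform
#'
#' Computes `log10(value + offset)` elementwise. Light intensities span
#' orders of magnitude (moonlight to direct sun), so thresholds in the
#' field are commonly placed on the log scale -- e.g. a 100-lux threshold
#' becomes `log10(100 + 1)` with offset 1, the offset keeping darkness
#' (0 lux) finite at `log10(1) = 0`. Missing values stay missing.
#'
#' @param series an [epoch_series()].
#' @param offset non-negative value added before taking the logarithm;
#'   every `value + offset` must be strictly positive.
#' @return the transformed [epoch_series()].
#' @export
log_transform <- function(series, offset = 1) {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  ld_assert(is.numeric(offset) && length(offset) == 1L && offset >= 0,
            "parameter", "offset must be a non-negative number")
  if (any(series$values + offset <= 0, na.rm = TRUE))
    ld_stop("domain", "value + offset must be > 0 for the log transform")
  out <- series
  out$values <- log10(series$values + offset)
  out
}

#' Discard values at or below a threshold
#'
#' Values `> C` are kept; values `<= C` are replaced by missing. The
#' comparison is strict everywhere in the package ("above threshold" means
#' strictly above), so [tat()], [binarize()], [light_exposure_level()] and
#' `threshold_filter()` always agree on which epochs count.
#'
#' @param series an [epoch_series()].
#' @param C threshold, on the same scale as the series values.
#' @return the thresholded [epoch_series()].
#' @export
threshold_filter <- function(series, C) {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  ld_assert(is.numeric(C) && length(C) == 1L && is.finite(C), "parameter",
            "threshold C must be a finite number")
  out <- series
  out$values[!is.na(out$values) & out$values <= C] <- NA_real_
  out
}

#' Binarize a series against a threshold
#'
#' Values strictly above `C` become 1, values at or below become 0;
#' missing stays missing. [tat()] is exactly the epoch length times the
#' sum of the binarized series.
#'
#' @inheritParams threshold_filter
#' @return an [epoch_series()] of 0/1 (and `NA`) values.
#' @export
binarize <- function(series, C) {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  ld_assert(is.numeric(C) && length(C) == 1L && is.finite(C), "parameter",
            "threshold C must be a finite number")
  out <- series
  out$values <- as.numeric(series$values > C)
  out
}
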