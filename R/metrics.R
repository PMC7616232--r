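# Exposure-metric suite. All metrics operate on a single epoch_series
# (typically obtained via channel_data(rec, ch, masked = TRUE), optionally
# log-transformed); missing values and masked epochs are excluded from every
# sum and count. Threshold comparisons are strict throughout: "above C"
# means value > C.

valid_values <- function(series) series$values[!is.na(series$values)]

slice_window <- function(series, start, stop) {
  t <- as.numeric(series$time)
  series$values[t >= as.numeric(ld_time(start)) & t < as.numeric(ld_time(stop))]
}

#' Summary statistics over a recording or arbitrary windows
#'
#' Mean, median, standard deviation, minimum, maximum and requested
#' percentiles of the non-missing values, either over the whole series or
#' separately over user-defined half-open time windows.
#'
#' @param series an [epoch_series()].
#' @param windows optional list of `c(start, stop)` timestamp pairs
#'   (half-open windows); names, when given, label the output columns.
#' @param percentiles percentiles to report, in `[0, 100]`.
#' @return a one-row data frame; with windows, each statistic is suffixed
#'   by the window label. A window with no valid data yields `NA` cells.
#' @export
summary_statistics <- function(series, windows = NULL,
                               percentiles = c(25, 75)) {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  ld_assert(all(percentiles >= 0 & percentiles <= 100), "parameter",
            "percentiles must lie in [0, 100]")
  one <- function(v) {
    v <- v[!is.na(v)]
    qs <- if (length(v)) stats::quantile(v, percentiles / 100, names = FALSE)
          else rep(NA_real_, length(percentiles))
    stats_ <- if (length(v))
      c(mean = mean(v), median = stats::median(v),
        sd = if (length(v) > 1) stats::sd(v) else 0,
        min = min(v), max = max(v))
    else c(mean = NA_real_, median = NA_real_, sd = NA_real_,
           min = NA_real_, max = NA_real_)
    names(qs) <- sprintf("p%g", percentiles)
    c(stats_, qs)
  }
  if (is.null(windows)) {
    ld_assert(length(valid_values(series)) > 0, "empty_selection",
              "series has no valid values")
    return(as.data.frame(as.list(one(series$values)), check.names = FALSE))
  }
  labels <- names(windows)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- sprintf("w%d", seq_along(windows))
  cells <- unlist(lapply(seq_along(windows), function(i) {
    s <- one(slice_window(series, windows[[i]][1], windows[[i]][2]))
    names(s) <- paste(names(s), labels[i], sep = "_")
    s
  }))
  as.data.frame(as.list(cells), check.names = FALSE)
}

#' Thresholded light exposure level
#'
#' Mean intensity over the epochs strictly above the threshold `C` (the
#' mean of all valid values when `C` is omitted). This is the mean of
#' [threshold_filter()]'s surviving values.
#'
#' @param series an [epoch_series()].
#' @param C optional threshold, on the same scale as the series values.
#' @return the mean intensity above threshold, or `NA` when no valid value
#'   exceeds `C`.
#' @export
light_exposure_level <- function(series, C = NULL) {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  v <- valid_values(series)
  if (!is.null(C)) {
    ld_assert(is.numeric(C) && length(C) == 1L && is.finite(C), "parameter",
              "threshold C must be a finite number")
    v <- v[v > C]
  }
  if (!length(v)) NA_real_ else mean(v)
}

#' Time above threshold (TAT)
#'
#' The total duration spent strictly above the threshold `C`: the count of
#' valid epochs with `value > C` times the epoch length. Identically equal
#' to `epoch_length * sum(binarize(series, C))`.
#'
#' @param series an [epoch_series()].
#' @param C threshold, on the same scale as the series values.
#' @param output_format `"minute"` (duration in minutes, numeric),
#'   `"timedelta"` (a [base::difftime] in seconds) or `"count"` (number of
#'   supra-threshold epochs).
#' @return duration or count per `output_format`.
#' @export
tat <- function(series, C, output_format = "minute") {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  ld_assert(is.numeric(C) && length(C) == 1L && is.finite(C), "parameter",
            "threshold C must be a finite number")
  ld_assert(length(output_format) == 1L &&
              output_format %in% c("minute", "timedelta", "count"),
            "parameter",
            "output_format must be 'minute', 'timedelta' or 'count'")
  n_above <- sum(series$values > C, na.rm = TRUE)
  switch(output_format,
         minute = n_above * series$epoch / 60,
         timedelta = as.difftime(n_above * series$epoch, units = "secs"),
         count = n_above)
}

#' TAT within arbitrary time windows
#'
#' [tat()] restricted to each half-open window. Disjoint windows covering
#' the recording sum to the total TAT.
#'
#' @inheritParams tat
#' @param windows list of `c(start, stop)` timestamp pairs; names label
#'   the output columns.
#' @return a one-row data frame with one TAT value per window.
#' @export
tat_per_window <- function(series, C, windows, output_format = "minute") {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  ld_assert(is.list(windows) && length(windows) >= 1L, "parameter",
            "windows must be a non-empty list of (start, stop) pairs")
  labels <- names(windows)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- sprintf("TAT_w%d", seq_along(windows))
  ld_assert(is.numeric(C) && length(C) == 1L && is.finite(C), "parameter",
            "threshold C must be a finite number")
  ld_assert(output_format %in% c("minute", "timedelta", "count"), "parameter",
            "output_format must be 'minute', 'timedelta' or 'count'")
  vals <- vapply(windows, function(w) {
    n_above <- sum(slice_window(series, w[1], w[2]) > C, na.rm = TRUE)
    switch(output_format,
           minute = n_above * series$epoch / 60,
           timedelta = n_above * series$epoch,  # seconds
           count = n_above)
  }, numeric(1))
  out <- as.data.frame(as.list(vals), check.names = FALSE)
  names(out) <- labels
  out
}

#' Mean light timing above threshold (MLiT)
#'
#' The intensity-indicator-weighted mean time of day of the epochs
#' strictly above the threshold `C`. With `m` periods per day (1440 for
#' one-minute data), `n` days, and the indicator `I_jk = 1` when the value
#' at daily period `j` of day `k` exceeds `C`, the metric is the ratio
#'
#' \deqn{MLiT(C) = \frac{\sum_{j=1}^{m}\sum_{k=1}^{n} j \, I_{jk}(C)}
#'                     {\sum_{j=1}^{m}\sum_{k=1}^{n} I_{jk}(C)}}
#'
#' i.e. the mean 1-based daily-period index of the supra-threshold epochs.
#' Missing/masked epochs contribute 0 to both sums. Period `j` covers the
#' clock interval `[(j-1) epoch, j epoch)`, so the reported clock time is
#' `(index - 1) * epoch` seconds after midnight.
#'
#' @param series an [epoch_series()] whose epoch length divides 24 h.
#' @param C threshold, on the same scale as the series values.
#' @param whole_days_only drop leading/trailing partial days first.
#' @return an object of class `mlit_result`: a list with `index`
#'   (fractional 1-based daily-period index), `clock_time` (seconds after
#'   midnight), `m` (periods per day), `n` (days in the recording) and
#'   `exceedance_count`. When no epoch exceeds `C`, `index` and
#'   `clock_time` are `NA` and `exceedance_count` is 0.
#' @export
mlit <- function(series, C, whole_days_only = FALSE) {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  ld_assert(is.numeric(C) && length(C) == 1L && is.finite(C), "parameter",
            "threshold C must be a finite number")
  m <- 86400 / series$epoch
  ld_assert(abs(m - round(m)) < 1e-9, "irregular_epoch",
            "epoch length (%gs) does not divide 24 h", series$epoch)
  m <- as.integer(round(m))
  if (isTRUE(whole_days_only)) series <- trim_to_whole_days(series)
  j <- as.integer(round(seconds_of_day(series$time) / series$epoch)) %% m + 1L
  I <- !is.na(series$values) & series$values > C
  n_days <- length(unique(as.integer(floor(as.numeric(series$time) / 86400))))
  count <- sum(I)
  index <- if (count > 0) sum(j[I]) / count else NA_real_
  structure(list(index = index,
                 clock_time = if (count > 0) (index - 1) * series$epoch
                              else NA_real_,
                 m = m, n = n_days, exceedance_count = count),
            class = "mlit_result")
}

#' @export
print.mlit_result <- function(x, ...) {
  if (x$exceedance_count == 0) {
    cat("<mlit_result> no epochs above threshold\n")
  } else {
    cat(sprintf("<mlit_result> index %.3f / m=%d -> clock time %s (%d exceedances over %d day(s))\n",
                x$index, x$m, hms(x$clock_time), x$exceedance_count, x$n))
  }
  invisible(x)
}

hms <- function(sec) {
  sec <- round(sec)
  sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
}

# rolling circular window means over a daily profile; NA-contaminated
# windows are NA
circular_window_means <- function(means, w) {
  p <- length(means)
  ext <- c(means, means[seq_len(w - 1L)])
  cs <- cumsum(ifelse(is.na(ext), 0, ext))
  bad <- cumsum(is.na(ext))
  sums <- cs[w:(p + w - 1L)] - c(0, cs[seq_len(p - 1L)])
  nas <- bad[w:(p + w - 1L)] - c(0, bad[seq_len(p - 1L)])
  out <- sums / w
  out[nas > 0] <- NA_real_
  out
}

#' L5 and M10 nonparametric windows
#'
#' The classic nonparametric circadian descriptors applied to light: the
#' 5-hour window of least exposure (L5) and the 10-hour window of maximal
#' exposure (M10), located on the average daily profile with circular
#' (midnight-wrapping) candidate windows at every profile period. Ties are
#' broken by the earliest onset in `[00:00, 24:00)`. A candidate window is
#' only eligible when every profile period inside it has data.
#'
#' @param series an [epoch_series()] whose epoch divides both 24 h and
#'   5 h (so 5 h and 10 h are whole numbers of periods).
#' @param whole_days_only passed to [daily_profile()].
#' @return a list with elements `L5` and `M10`, each of class
#'   `window_result` with `onset` (seconds after midnight), `onset_hms`,
#'   `mean_value` and `window_length` (seconds).
#' @export
l5m10 <- function(series, whole_days_only = FALSE) {
  prof <- daily_profile(series, whole_days_only = whole_days_only)
  windows <- list(L5 = 5 * 3600, M10 = 10 * 3600)
  out <- lapply(names(windows), function(nm) {
    len <- windows[[nm]]
    w <- len / prof$epoch
    ld_assert(abs(w - round(w)) < 1e-9, "parameter",
              "window length %gs is not a whole number of %gs periods",
              len, prof$epoch)
    wm <- circular_window_means(prof$period_means, as.integer(round(w)))
    if (all(is.na(wm)))
      ld_stop("insufficient_data",
              "every candidate %s window contains an empty profile period", nm)
    pick <- if (nm == "L5") which.min(wm) else which.max(wm)
    onset <- (pick - 1L) * prof$epoch
    structure(list(onset = onset, onset_hms = hms(onset),
                   mean_value = wm[pick], window_length = len),
              class = "window_result")
  })
  names(out) <- names(windows)
  out
}

#' @export
print.window_result <- function(x, ...) {
  cat(sprintf("<window_result> %gh window from %s, mean %.4g\n",
              x$window_length / 3600, x$onset_hms, x$mean_value))
  invisible(x)
}

#' Interdaily stability (IS)
#'
#' Quantifies how reproducible the 24-hour light-exposure pattern is
#' across days: the between-period-of-day variance relative to the total
#' variance,
#'
#' \deqn{IS = \frac{n \sum_{h=1}^{p} (\bar x_h - \bar x)^2}
#'                 {p \sum_{i=1}^{n} (x_i - \bar x)^2}}
#'
#' where \eqn{\bar x_h} is the mean at daily period `h` across days (the
#' daily profile), \eqn{\bar x} the grand mean, `n` the number of valid
#' periods in the recording and `p` the number of periods per day. IS is
#' 1 for a perfectly repeated daily pattern and tends to `1/d` for `d`
#' days of independent noise; for complete data it lies in `[0, 1]`. IS is
#' the 24-hour value of the chi-square periodogram normalized by `n` --
#' see [is_at_period()] for the periodogram at other trial periods.
#'
#' @param series an [epoch_series()] covering at least two days.
#' @param freq optional coarser epoch (duration token or seconds); the
#'   series is first resampled with mean aggregation. IS is
#'   frequency-sensitive, so the analysis epoch is an explicit choice
#'   (1 h is conventional).
#' @return IS (dimensionless).
#' @export
interdaily_stability <- function(series, freq = NULL) {
  is_at_period(series, 86400, freq = freq)
}

#' Chi-square periodogram value at an arbitrary trial period
#'
#' The IS statistic generalized to a folding period other than 24 h: fold
#' the series at `test_period`, and compare the variance of the folded
#' profile to the total variance. `is_at_period(series, 86400)` is
#' [interdaily_stability()] exactly (same code path); scanning
#' `test_period` yields a normalized chi-square periodogram whose maximum
#' sits near the dominant periodicity.
#'
#' @param series an [epoch_series()] covering at least two cycles of
#'   `test_period`.
#' @param test_period trial folding period (duration token or seconds);
#'   must be an integer multiple of the (possibly resampled) epoch.
#' @param freq optional resampling epoch, as in [interdaily_stability()].
#' @return the normalized periodogram value (dimensionless).
#' @export
is_at_period <- function(series, test_period, freq = NULL) {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  if (!is.null(freq)) series <- resample(series, freq, "mean")
  period <- parse_duration(test_period)
  q <- period / series$epoch
  ld_assert(abs(q - round(q)) < 1e-9 && q >= 1, "parameter",
            "test period (%gs) is not an integer multiple of the epoch (%gs)",
            period, series$epoch)
  q <- as.integer(round(q))
  span <- length(series) * series$epoch
  ld_assert(span >= 2 * period, "insufficient_data",
            "series spans %.2f cycle(s) of the test period; at least 2 required",
            span / period)
  ok <- !is.na(series$values)
  x <- series$values[ok]
  n <- length(x)
  ld_assert(n >= 2L, "insufficient_data", "fewer than 2 valid values")
  gm <- mean(x)
  denom <- sum((x - gm)^2)
  if (denom == 0)
    ld_stop("undefined_metric",
            "series has zero variance; IS is undefined (0/0)")
  h <- (as.integer(round((as.numeric(series$time) %% period) / series$epoch)) %% q + 1L)[ok]
  counts <- tabulate(h, nbins = q)
  sums <- rep(0, q)
  agg <- rowsum(x, group = h)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  nonempty <- counts > 0
  means_h <- sums[nonempty] / counts[nonempty]
  n * sum((means_h - gm)^2) / (q * denom)
}

#' Intradaily variability (IV)
#'
#' Quantifies the fragmentation of the exposure pattern within days: the
#' mean squared successive difference relative to the variance,
#'
#' \deqn{IV = \frac{n \sum_{i=1}^{n-1} (x_{i+1} - x_i)^2}
#'                 {(n-1) \sum_{i=1}^{n} (x_i - \bar x)^2}}
#'
#' IV is near 2 for independent noise, near 0 for a slowly varying smooth
#' pattern, and reaches its maximum for rapid alternation (an alternating
#' two-level series gives exactly 4). With missing epochs, squared
#' differences are summed only over adjacent pairs where both values are
#' valid, and the `n - 1` factor becomes the number of such pairs.
#'
#' @inheritParams interdaily_stability
#' @return IV (dimensionless, non-negative).
#' @export
intradaily_variability <- function(series, freq = NULL) {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  if (!is.null(freq)) series <- resample(series, freq, "mean")
  v <- series$values
  ok <- !is.na(v)
  n <- sum(ok)
  ld_assert(n >= 2L, "insufficient_data", "fewer than 2 valid values")
  pair <- ok[-length(ok)] & ok[-1]
  ld_assert(any(pair), "insufficient_data",
            "no adjacent pair of valid values")
  d <- (v[-1] - v[-length(v)])[pair]
  x <- v[ok]
  denom <- sum((x - mean(x))^2)
  if (denom == 0)
    ld_stop("undefined_metric",
            "series has zero variance; IV is undefined (0/0)")
  n * sum(d^2) / (sum(pair) * denom)
}

metric_registry <- c("mean", "median", "light_exposure_level", "tat",
                     "mlit", "is", "iv", "l5_mean", "l5_onset",
                     "m10_mean", "m10_onset")

# evaluate one metric spec entry on a prepared series; returns a scalar
metric_value <- function(series, entry) {
  ld_assert(is.list(entry) && !is.null(entry$metric), "parameter",
            "each metric spec entry needs a 'metric' field")
  metric <- entry$metric
  ld_assert(metric %in% metric_registry, "parameter",
            "unknown metric '%s' (available: %s)", metric,
            paste(metric_registry, collapse = ", "))
  switch(metric,
    mean = mean(valid_values(series)),
    median = stats::median(valid_values(series)),
    light_exposure_level = light_exposure_level(series, entry$threshold),
    tat = as.numeric(tat(series, entry$threshold,
                         entry$output_format %||% "minute")),
    mlit = {
      r <- mlit(series, entry$threshold)
      if (r$exceedance_count == 0) NA_real_ else r$clock_time / 3600
    },
    is = interdaily_stability(series, freq = entry$freq),
    iv = intradaily_variability(series, freq = entry$freq),
    l5_mean = l5m10(series)$L5$mean_value,
    l5_onset = l5m10(series)$L5$onset / 3600,
    m10_mean = l5m10(series)$M10$mean_value,
    m10_onset = l5m10(series)$M10$onset / 3600)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute a group-level metric table
#'
#' Evaluates a list of named metric requests on one channel of every
#' recording, producing one row per recording and one column per metric.
#' A metric that fails on one recording (e.g. IS on a constant series)
#' becomes a missing cell and is reported in the `errors` attribute; the
#' batch never aborts.
#'
#' Available metrics: `mean`, `median`, `light_exposure_level`
#' (`threshold`, optional), `tat` (`threshold`, `output_format`), `mlit`
#' (`threshold`; the cell holds the MLiT clock time in decimal hours after
#' midnight), `is` / `iv` (`freq`, optional resampling epoch), and
#' `l5_mean` / `l5_onset` / `m10_mean` / `m10_onset` (onsets in decimal
#' hours).
#'
#' @param recordings list of [light_recording()]s.
#' @param channel channel name, present in every recording.
#' @param spec named list of metric requests; each element is a list with
#'   a `metric` field plus that metric's parameters, and the element name
#'   becomes the column name (e.g.
#'   `list(TAT_100 = list(metric = "tat", threshold = log10(101)))`).
#' @param log10_offset when non-`NULL`, each series is log-transformed
#'   with this offset before any metric is evaluated (thresholds are then
#'   on the log scale).
#' @return a data frame with a `name` column and one numeric column per
#'   metric; failures are `NA` cells, detailed in `attr(, "errors")`.
#' @export
compute_metric_table <- function(recordings, channel, spec,
                                 log10_offset = NULL) {
  ld_assert(is.list(recordings) && length(recordings) >= 1L, "parameter",
            "recordings must be a non-empty list")
  ld_assert(is.list(spec) && length(spec) >= 1L && !is.null(names(spec)) &&
              all(nzchar(names(spec))), "parameter",
            "spec must be a non-empty named list of metric requests")
  errors <- list()
  rows <- lapply(recordings, function(rec) {
    cells <- rep(NA_real_, length(spec))
    names(cells) <- names(spec)
    series <- tryCatch({
      s <- channel_data(rec, channel, masked = TRUE)
      if (!is.null(log10_offset)) s <- log_transform(s, log10_offset) else s
    }, error = function(e) e)
    if (inherits(series, "error")) {
      errors[[rec$name]] <<- conditionMessage(series)
      return(cells)
    }
    for (col in names(spec)) {
      val <- tryCatch(metric_value(series, spec[[col]]),
                      error = function(e) e)
      if (inherits(val, "error")) {
        errors[[paste(rec$name, col, sep = "/")]] <<- conditionMessage(val)
      } else {
        cells[[col]] <- val
      }
    }
    cells
  })
  out <- data.frame(name = vapply(recordings, function(r) r$name, character(1)),
                    do.call(rbind, rows), check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}
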