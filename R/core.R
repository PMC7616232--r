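#' Fixed-epoch light time series
#'
#' An `epoch_series` is the elementary container of the package: an ordered
#' vector of timestamps at a strictly constant spacing (the epoch length),
#' with one non-negative intensity value -- or `NA` for a missing epoch --
#' per timestamp. All metric formulas in the package assume a constant
#' epoch, so irregular spacing is rejected at construction rather than
#' silently resampled.
#'
#' @param timestamps ordered timestamps (`POSIXct`, or strings parsed as
#'   timezone-naive local clock time).
#' @param values numeric vector of intensities, same length as
#'   `timestamps`; values must be non-negative or `NA`.
#' @param epoch_length epoch spacing in seconds (or a duration token, see
#'   [parse_duration()]); inferred from the timestamps when omitted.
#' @return an object of class `epoch_series` with fields `time`, `values`
#'   and `epoch` (seconds).
#' @examples
#' t0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
#' es <- epoch_series(t0 + 60 * (0:59), runif(60, 0, 1000))
#' es$epoch
#' @export
epoch_series <- function(timestamps, values, epoch_length = NULL) {
  time <- ld_time(timestamps)
  ld_assert(!anyNA(time), "parse", "unparsable timestamp in series")
  n <- length(time)
  ld_assert(n >= 1L, "parameter", "series must contain at least one epoch")
  ld_assert(length(values) == n, "parameter",
            "values (%d) and timestamps (%d) differ in length",
            length(values), n)
  values <- as.numeric(values)
  ld_assert(all(values >= 0, na.rm = TRUE), "parameter",
            "light intensities cannot be negative")
  if (n > 1L) {
    d <- diff(as.numeric(time))
    ld_assert(max(d) - min(d) < 1e-6, "irregular_epoch",
              "timestamps are not at constant spacing (gap of %gs among %gs epochs)",
              max(d), min(d))
    inferred <- d[1]
    ld_assert(inferred > 0, "irregular_epoch", "timestamps must be strictly increasing")
  } else {
    inferred <- NA_real_
  }
  if (is.null(epoch_length)) {
    ld_assert(!is.na(inferred), "parameter",
              "epoch_length must be given for a single-epoch series")
    epoch <- inferred
  } else {
    epoch <- parse_duration(epoch_length)
    ld_assert(is.na(inferred) || abs(inferred - epoch) < 1e-6, "irregular_epoch",
              "declared epoch_length (%gs) does not match timestamp spacing (%gs)",
              epoch, inferred)
  }
  structure(list(time = time, values = values, epoch = epoch),
            class = "epoch_series")
}

# Internal constructor: no validation. Used when slicing/aggregating an
# already-valid series, whose values may legitimately be negative after a
# transform (log scale, filtering).
new_epoch_series <- function(time, values, epoch) {
  structure(list(time = time, values = as.numeric(values), epoch = epoch),
            class = "epoch_series")
}

#' @export
length.epoch_series <- function(x) length(x$values)

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %d epochs @ %gs, %s .. %s (%d missing)\n",
              length(x), x$epoch, format_time(x$time[1]),
              format_time(x$time[length(x)]), sum(is.na(x$values))))
  invisible(x)
}

#' Multi-channel light recording
#'
#' A `light_recording` bundles one or more channels (e.g. `"White Light"`,
#' melanopic EDI) that share a single timestamp grid, together with a
#' per-epoch logical mask. Masked epochs (`TRUE`) are excluded from every
#' downstream computation, exactly as if their values were missing.
#'
#' @param name identifier for the recording (used as the row key in metric
#'   tables).
#' @param timestamps shared timestamp grid (see [epoch_series()]).
#' @param channels named list of numeric value vectors, one per channel,
#'   each the same length as `timestamps`.
#' @param epoch_length epoch spacing in seconds; inferred when omitted.
#' @param mask optional logical vector (`TRUE` = excluded); defaults to
#'   all-`FALSE`.
#' @return an object of class `light_recording`.
#' @export
light_recording <- function(name, timestamps, channels, epoch_length = NULL,
                            mask = NULL) {
  ld_assert(is.character(name) && length(name) == 1L && nzchar(name),
            "parameter", "recording name must be a non-empty string")
  ld_assert(is.list(channels) && length(channels) >= 1L &&
              !is.null(names(channels)) && all(nzchar(names(channels))),
            "parameter", "channels must be a non-empty named list")
  ref <- epoch_series(timestamps, channels[[1]], epoch_length)
  n <- length(ref)
  for (ch in names(channels)) {
    ld_assert(length(channels[[ch]]) == n, "parameter",
              "channel '%s' has %d values but the grid has %d epochs",
              ch, length(channels[[ch]]), n)
    v <- as.numeric(channels[[ch]])
    ld_assert(all(v >= 0, na.rm = TRUE), "parameter",
              "channel '%s': light intensities cannot be negative", ch)
    channels[[ch]] <- v
  }
  if (is.null(mask)) mask <- rep(FALSE, n)
  ld_assert(is.logical(mask) && length(mask) == n && !anyNA(mask),
            "parameter", "mask must be a logical vector of length %d", n)
  structure(list(name = name, time = ref$time, epoch = ref$epoch,
                 channels = channels, mask = mask),
            class = "light_recording")
}

#' @export
print.light_recording <- function(x, ...) {
  cat(sprintf("<light_recording> '%s': %d epochs @ %gs, channels [%s], %d masked\n",
              x$name, length(x$time), x$epoch,
              paste(names(x$channels), collapse = ", "), sum(x$mask)))
  invisible(x)
}

#' List the channels of a recording
#'
#' @param recording a [light_recording()].
#' @return character vector of channel names, in insertion order.
#' @export
channel_list <- function(recording) {
  ld_assert(inherits(recording, "light_recording"), "parameter",
            "expected a light_recording")
  names(recording$channels)
}

#' Extract one channel as an epoch series
#'
#' @param recording a [light_recording()].
#' @param name channel name.
#' @param masked if `TRUE`, values at masked epochs are replaced by `NA`
#'   (the timestamps are kept, so the grid stays regular).
#' @return an [epoch_series()].
#' @export
channel_data <- function(recording, name, masked = FALSE) {
  ld_assert(inherits(recording, "light_recording"), "parameter",
            "expected a light_recording")
  if (!name %in% names(recording$channels))
    ld_stop("channel_not_found", "no channel '%s' (available: %s)",
            name, paste(names(recording$channels), collapse = ", "))
  v <- recording$channels[[name]]
  if (isTRUE(masked)) v[recording$mask] <- NA_real_
  epoch_series(recording$time, v, recording$epoch)
}

# Drop leading/trailing epochs so the series starts and ends on midnight
# boundaries; used by the whole_days_only policy.
trim_to_whole_days <- function(series) {
  tod <- seconds_of_day(series$time)
  first <- match(0, tod)  # first epoch at exactly 00:00
  ld_assert(!is.na(first), "insufficient_data",
            "series does not contain a whole day")
  n <- length(series)
  remaining <- n - first + 1L
  per_day <- 86400 / series$epoch
  n_days <- floor(remaining / per_day)
  ld_assert(n_days >= 1, "insufficient_data",
            "series does not contain a whole day")
  idx <- seq.int(first, first + n_days * per_day - 1L)
  new_epoch_series(series$time[idx], series$values[idx], series$epoch)
}

#' Fold a series into its average daily profile
#'
#' Collapses a multi-day series onto the 24-hour clock: period `h` of the
#' profile (1-based, covering clock interval `[(h-1)*epoch, h*epoch)`)
#' receives the mean of all non-missing values observed at that time of
#' day. This day-folding is the shared primitive behind MLiT, IS/IV and
#' L5/M10.
#'
#' @param series an [epoch_series()] whose epoch length divides 24 h.
#' @param whole_days_only drop leading/trailing partial days before
#'   folding, so every clock period is backed by the same number of days.
#' @return an object of class `daily_profile` with fields `period_means`
#'   (length `p`; `NA` where no valid observation exists), `period_counts`,
#'   `p`, `epoch` and `n_days_used`.
#' @export
daily_profile <- function(series, whole_days_only = FALSE) {
  ld_assert(inherits(series, "epoch_series"), "parameter",
            "expected an epoch_series")
  p <- 86400 / series$epoch
  ld_assert(abs(p - round(p)) < 1e-9, "irregular_epoch",
            "epoch length (%gs) does not divide 24 h", series$epoch)
  p <- as.integer(round(p))
  if (isTRUE(whole_days_only)) series <- trim_to_whole_days(series)
  h <- as.integer(round(seconds_of_day(series$time) / series$epoch)) %% p + 1L
  ok <- !is.na(series$values)
  counts <- tabulate(h[ok], nbins = p)
  sums <- rep(0, p)
  if (any(ok)) {
    agg <- rowsum(series$values[ok], group = h[ok])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  means <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  n_days <- length(unique(as.integer(floor(as.numeric(series$time) / 86400))))
  structure(list(period_means = means, period_counts = counts, p = p,
                 epoch = series$epoch, n_days_used = n_days),
            class = "daily_profile")
}

#' @export
print.daily_profile <- function(x, ...) {
  cat(sprintf("<daily_profile> p=%d periods @ %gs over %d day(s), %d empty period(s)\n",
              x$p, x$epoch, x$n_days_used, sum(is.na(x$period_means))))
  invisible(x)
}
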