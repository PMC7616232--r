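#' Parameters for the synthetic light-exposure generator
#'
#' Describes a simulated wearer of a wrist light logger. Each epoch the
#' wearer is outdoors with an hour-of-day-dependent probability; outdoor
#' epochs follow a smooth Gaussian-bell daylight template peaking in the
#' early afternoon, indoor epochs sit at a constant architectural lighting
#' level, and both are jittered by multiplicative lognormal noise.
#' Non-wear periods (device off-wrist or covered by a sleeve) arrive as a
#' Poisson process with exponentially distributed durations and record 0
#' lux, as a covered sensor does.
#'
#' @param n_days number of whole recording days.
#' @param epoch_length epoch in seconds (must divide 24 h); 60 s is the
#'   typical wrist-logger export resolution.
#' @param daylight_peak peak of the outdoor daylight template, in lux.
#' @param peak_time clock time of the daylight peak (`"HH:MM"` or seconds
#'   after midnight).
#' @param daylight_width SD of the Gaussian daylight bell, in seconds.
#' @param indoor_level constant indoor illuminance, in lux.
#' @param outdoor_probability_by_hour 24 probabilities (hour 0..23) of
#'   being outdoors.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal intensity noise (0 = noiseless).
#' @param nonwear_intervals_per_day expected number of non-wear intervals
#'   per day (Poisson rate).
#' @param nonwear_mean_duration mean non-wear duration, in seconds.
#' @param seed integer seed; the whole recording is a deterministic
#'   function of the parameters.
#' @param start_date first timestamp of the recording (midnight).
#' @return an object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_days = 8L,
                             epoch_length = 60,
                             daylight_peak = 10000,
                             peak_time = "13:00",
                             daylight_width = 3 * 3600,
                             indoor_level = 200,
                             outdoor_probability_by_hour =
                               default_outdoor_probability(),
                             noise_cv = 0.5,
                             nonwear_intervals_per_day = 0.5,
                             nonwear_mean_duration = 1800,
                             seed = 1L,
                             start_date = "2024-01-01 00:00:00") {
  epoch <- parse_duration(epoch_length)
  ld_assert(n_days >= 1 && n_days == round(n_days), "parameter",
            "n_days must be a positive integer")
  ld_assert(abs(86400 / epoch - round(86400 / epoch)) < 1e-9, "parameter",
            "epoch_length must divide 24 h")
  ld_assert(daylight_peak > 0 && indoor_level > 0 && daylight_width > 0,
            "parameter", "level and width parameters must be positive")
  ld_assert(length(outdoor_probability_by_hour) == 24L &&
              all(outdoor_probability_by_hour >= 0) &&
              all(outdoor_probability_by_hour <= 1), "parameter",
            "outdoor_probability_by_hour must be 24 probabilities")
  ld_assert(noise_cv >= 0, "parameter", "noise_cv must be non-negative")
  ld_assert(nonwear_intervals_per_day >= 0, "parameter",
            "nonwear_intervals_per_day must be non-negative")
  peak_sec <- if (is.character(peak_time) && grepl(":", peak_time)) {
    parts <- as.numeric(strsplit(peak_time, ":")[[1]])
    parts[1] * 3600 + parts[2] * 60
  } else parse_duration(peak_time)
  structure(list(n_days = as.integer(n_days), epoch_length = epoch,
                 daylight_peak = daylight_peak, peak_time = peak_sec,
                 daylight_width = daylight_width,
                 indoor_level = indoor_level,
                 outdoor_probability_by_hour = outdoor_probability_by_hour,
                 noise_cv = noise_cv,
                 nonwear_intervals_per_day = nonwear_intervals_per_day,
                 nonwear_mean_duration = parse_duration(nonwear_mean_duration),
                 seed = as.integer(seed),
                 start_date = start_date),
            class = "synthetic_params")
}

#' @rdname synthetic_params
#' @export
default_outdoor_probability <- function() {
  # night: never outdoors; commuting shoulders; midday outdoor breaks
  c(rep(0, 7),            # 00-06
    0.1, 0.3,             # 07, 08 commute
    0.15, 0.15, 0.2,      # 09-11
    0.4, 0.3,             # 12-13 lunch
    0.15, 0.15, 0.2,      # 14-16
    0.35, 0.25,           # 17-18 commute
    0.1, 0.05,            # 19-20
    rep(0, 3))            # 21-23
}

# circular clock distance to the template peak
diurnal_template <- function(tod, peak_time, peak, width) {
  d <- abs(tod - peak_time)
  d <- pmin(d, 86400 - d)
  peak * exp(-d^2 / (2 * width^2))
}

#' Generate a synthetic light-logger recording
#'
#' Deterministic for a fixed seed. Returns the recording together with the
#' generation ground truth -- the true non-wear intervals as a
#' [mask_spec()] and the per-epoch state labels -- so tests can verify
#' masking and metric behaviour against known structure.
#'
#' @param params a [synthetic_params()].
#' @param channel name of the generated channel.
#' @return a list with elements `recording` (a [light_recording()]),
#'   `nonwear` (a [mask_spec()] of the true non-wear intervals) and
#'   `states` (character vector per epoch: `"indoor"`, `"outdoor"` or
#'   `"nonwear"`).
#' @export
generate_recording <- function(params, channel = "White Light") {
  ld_assert(inherits(params, "synthetic_params"), "parameter",
            "expected synthetic_params")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(params$seed)

  epoch <- params$epoch_length
  n <- as.integer(params$n_days * 86400 / epoch)
  t0 <- ld_time(params$start_date)
  time <- t0 + epoch * (seq_len(n) - 1)
  tod <- seconds_of_day(time)
  hour <- as.integer(tod %/% 3600)

  outdoor <- stats::runif(n) < params$outdoor_probability_by_hour[hour + 1L]
  base <- ifelse(outdoor,
                 diurnal_template(tod, params$peak_time,
                                  params$daylight_peak, params$daylight_width),
                 params$indoor_level)
  if (params$noise_cv > 0) {
    sdlog <- sqrt(log(1 + params$noise_cv^2))
    noise <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    values <- base * noise
  } else {
    values <- base
  }
  states <- ifelse(outdoor, "outdoor", "indoor")

  span <- params$n_days * 86400
  k <- stats::rpois(1, params$nonwear_intervals_per_day * params$n_days)
  if (k > 0) {
    starts <- t0 + sort(stats::runif(k, 0, span))
    durations <- stats::rexp(k, rate = 1 / params$nonwear_mean_duration)
    stops <- pmin(starts + durations, t0 + span)
    keep <- as.numeric(stops) > as.numeric(starts)
    nw <- mask_spec(starts[keep], stops[keep])
  } else {
    nw <- mask_spec()
  }
  if (nrow(nw) > 0) {
    tn <- as.numeric(time)
    covered <- rep(FALSE, n)
    for (i in seq_len(nrow(nw)))
      covered <- covered | (tn >= as.numeric(nw$start[i]) &
                              tn < as.numeric(nw$stop[i]))
    values[covered] <- 0          # covered sensor reads dark
    states[covered] <- "nonwear"
  }

  rec <- light_recording(sprintf("synthetic_seed%d", params$seed), time,
                         stats::setNames(list(values), channel), epoch)
  list(recording = rec, nonwear = nw, states = states)
}

#' Write a recording as a CSV fixture
#'
#' Serializes one recording under a [csv_dialect()] so that
#' [read_recording()] with the same dialect reproduces it exactly (values
#' are printed with 17 significant digits, enough to round-trip doubles).
#'
#' @param recording a [light_recording()].
#' @param path output file.
#' @param dialect a [csv_dialect()] whose `channel_columns` are a subset
#'   of the recording's channels.
#' @return the path, invisibly.
#' @export
write_fixture <- function(recording, path, dialect = NULL) {
  ld_assert(inherits(recording, "light_recording"), "parameter",
            "expected a light_recording")
  if (is.null(dialect))
    dialect <- csv_dialect(channel_columns = channel_list(recording))
  missing_ch <- setdiff(dialect$channel_columns, channel_list(recording))
  ld_assert(length(missing_ch) == 0L, "channel_not_found",
            "recording has no channel(s) %s",
            paste(sQuote(missing_ch), collapse = ", "))
  fmt_num <- function(v) {
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- ""
    if (dialect$decimal_mark == ",") s <- gsub(".", ",", s, fixed = TRUE)
    s
  }
  ts <- if (is.null(dialect$timestamp_format)) format_time(recording$time)
        else format(recording$time, dialect$timestamp_format, tz = "UTC")
  cols <- c(list(ts), lapply(dialect$channel_columns,
                             function(ch) fmt_num(recording$channels[[ch]])))
  header <- paste(c(dialect$timestamp_column, dialect$channel_columns),
                  collapse = dialect$delimiter)
  lines <- do.call(paste, c(cols, sep = dialect$delimiter))
  ok <- tryCatch(writeLines(c(header, lines), path),
                 error = function(e) ld_stop("io", "cannot write %s: %s",
                                             path, conditionMessage(e)))
  invisible(path)
}
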