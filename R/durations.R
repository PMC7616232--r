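#' Parse a duration token into seconds
#'
#' Durations throughout the package are plain numbers of seconds, but the
#' reader, truncation and resampling functions also accept compact tokens in
#' the style used by time-series tooling: an integer (or decimal) count
#' followed by a unit. Recognised units are `s`/`sec`/`S` (seconds),
#' `min`/`T` (minutes), `h`/`H` (hours), `d`/`D` (days) and `w`/`W` (weeks).
#' A bare number is taken to be seconds already.
#'
#' @param x a single duration token, e.g. `"6D"`, `"24H"`, `"30min"`,
#'   `"15s"`, or a plain number of seconds.
#' @return duration in seconds (numeric scalar).
#' @examples
#' parse_duration("6D")    # 518400
#' parse_duration("30min") # 1800
#' @export
parse_duration <- function(x) {
  if (is.numeric(x)) {
    ld_assert(length(x) == 1L && is.finite(x) && x > 0,
              "parameter", "duration must be a single positive number")
    return(as.numeric(x))
  }
  ld_assert(is.character(x) && length(x) == 1L,
            "parameter", "duration must be a number or a single token")
  m <- regmatches(x, regexec("^\\s*([0-9]*\\.?[0-9]+)\\s*([A-Za-z]*)\\s*$", x))[[1]]
  ld_assert(length(m) == 3L && nzchar(m[2]),
            "parameter", "cannot parse duration token '%s'", x)
  value <- as.numeric(m[2])
  unit <- m[3]
  if (!nzchar(unit)) return(value)  # bare number: seconds
  mult <- switch(tolower(unit),
    "s" = 1, "sec" = 1, "secs" = 1, "second" = 1, "seconds" = 1,
    "min" = 60, "t" = 60, "minute" = 60, "minutes" = 60,
    "h" = 3600, "hr" = 3600, "hour" = 3600, "hours" = 3600,
    "d" = 86400, "day" = 86400, "days" = 86400,
    "w" = 604800, "week" = 604800, "weeks" = 604800,
    ld_stop("parameter", "unknown duration unit '%s' in '%s'", unit, x)
  )
  value * mult
}

# Timestamps are timezone-naive local clock time; internally they are POSIXct
# pinned to UTC so arithmetic never crosses a DST transition.
ld_time <- function(x, format = NULL) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), tz = "UTC",
                                               origin = "1970-01-01"))
  if (is.null(format)) {
    out <- as.POSIXct(x, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                     "%Y-%m-%d"))
  } else {
    out <- as.POSIXct(x, tz = "UTC", format = format)
  }
  out
}

format_time <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

# seconds since the most recent midnight
seconds_of_day <- function(t) as.numeric(t) %% 86400
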