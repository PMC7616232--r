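#' CSV dialect for device exports
#'
#' Device-exported light-logger files differ in delimiter, decimal mark,
#' timestamp format and header conventions. A `csv_dialect` captures those
#' choices explicitly, so one reader covers any text export without
#' per-vendor parsers. Metadata/comment lines starting with `skip_prefix`
#' and an optional fixed count of leading rows (device serials, calibration
#' blocks) are skipped before the header row.
#'
#' @param channel_columns character vector of value-column names to load as
#'   channels (non-empty).
#' @param timestamp_column name of the timestamp column.
#' @param delimiter field separator character.
#' @param decimal_mark decimal mark, `"."` or `","`; must differ from
#'   `delimiter`.
#' @param timestamp_format optional `strptime`-style format; when `NULL`,
#'   ISO-8601 style timestamps are auto-detected.
#' @param skip_prefix comment-line prefix (single character).
#' @param skip_rows fixed number of leading lines to drop before parsing.
#' @param missing_tokens strings treated as missing values.
#' @return an object of class `csv_dialect`.
#' @export
csv_dialect <- function(channel_columns,
                        timestamp_column = "Timestamp",
                        delimiter = ",",
                        decimal_mark = ".",
                        timestamp_format = NULL,
                        skip_prefix = "#",
                        skip_rows = 0L,
                        missing_tokens = c("", "NaN", "NA")) {
  ld_assert(length(channel_columns) >= 1L && all(nzchar(channel_columns)),
            "parameter", "channel_columns must be non-empty")
  ld_assert(!timestamp_column %in% channel_columns, "parameter",
            "timestamp_column cannot also be a channel column")
  ld_assert(decimal_mark %in% c(".", ","), "parameter",
            "decimal_mark must be '.' or ','")
  ld_assert(!identical(delimiter, decimal_mark), "parameter",
            "delimiter and decimal_mark must differ")
  structure(list(channel_columns = as.character(channel_columns),
                 timestamp_column = timestamp_column,
                 delimiter = delimiter,
                 decimal_mark = decimal_mark,
                 timestamp_format = timestamp_format,
                 skip_prefix = skip_prefix,
                 skip_rows = as.integer(skip_rows),
                 missing_tokens = missing_tokens),
            class = "csv_dialect")
}

parse_values <- function(x, dialect, path, col) {
  x[x %in% dialect$missing_tokens] <- NA_character_
  if (dialect$decimal_mark == ",") x <- gsub(",", ".", x, fixed = TRUE)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    ld_stop("parse", "%s: cannot parse value '%s' in column '%s' (data row %d)",
            path, x[bad[1]], col, bad[1])
  out
}

#' Read one light-logger recording from a delimited text file
#'
#' Loads the timestamp column and the dialect's channel columns, infers the
#' (strictly constant) epoch length from consecutive timestamps, and
#' optionally restricts the data to the half-open window
#' `[start_time, start_time + period)` -- so a `period` of `"6D"` on
#' one-minute data yields exactly 8640 epochs. The recording mask starts
#' all-clear; apply a mask file afterwards with [apply_mask()].
#'
#' @param path file to read.
#' @param dialect a [csv_dialect()].
#' @param start_time optional window start (defaults to the first
#'   timestamp on file).
#' @param period optional window length (duration token or seconds, see
#'   [parse_duration()]); when omitted the full file is kept.
#' @param name recording identifier; defaults to the file stem.
#' @return a [light_recording()].
#' @export
read_recording <- function(path, dialect, start_time = NULL, period = NULL,
                           name = NULL) {
  ld_assert(inherits(dialect, "csv_dialect"), "parameter",
            "expected a csv_dialect")
  ld_assert(file.exists(path), "parameter", "file not found: %s", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = dialect$delimiter,
                      colClasses = "character", comment.char = dialect$skip_prefix,
                      skip = dialect$skip_rows, check.names = FALSE,
                      quote = "\"", blank.lines.skip = TRUE),
    error = function(e) ld_stop("parse", "%s: %s", path, conditionMessage(e)))
  need <- c(dialect$timestamp_column, dialect$channel_columns)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    ld_stop("parse", "%s: missing column(s) %s", path,
            paste(sQuote(missing_cols), collapse = ", "))
  ld_assert(nrow(df) >= 1L, "empty_selection", "%s: no data rows", path)
  time <- ld_time(df[[dialect$timestamp_column]], dialect$timestamp_format)
  bad <- which(is.na(time))
  if (length(bad))
    ld_stop("parse", "%s: cannot parse timestamp '%s' (data row %d)",
            path, df[[dialect$timestamp_column]][bad[1]], bad[1])
  channels <- lapply(dialect$channel_columns, function(col)
    parse_values(df[[col]], dialect, path, col))
  names(channels) <- dialect$channel_columns
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  rec <- light_recording(name, time, channels)
  if (!is.null(start_time) || !is.null(period)) {
    start <- if (is.null(start_time)) rec$time[1] else ld_time(start_time)
    span <- if (is.null(period))
      as.numeric(rec$time[length(rec$time)]) - as.numeric(start) + rec$epoch
    else parse_duration(period)
    rec <- truncate_recording(rec, start, span)
  }
  rec
}

#' Read a batch of recordings matching a glob pattern
#'
#' Files are read in lexicographic name order and each recording is named
#' by its file stem. A file that fails to parse does not abort the batch:
#' it is reported in the `errors` element and the remaining files are still
#' loaded.
#'
#' @param pattern a glob pattern (e.g. `"data/subject_*.csv"`), or a
#'   character vector of explicit paths.
#' @param dialect a [csv_dialect()].
#' @param period optional truncation window length, as in
#'   [read_recording()].
#' @return a list with elements `recordings` (list of
#'   [light_recording()]s) and `errors` (named character vector of
#'   per-file failure messages, empty when all files parsed).
#' @export
read_batch <- function(pattern, dialect, period = NULL) {
  files <- if (length(pattern) == 1L && grepl("[*?[]", pattern))
    Sys.glob(pattern) else pattern[file.exists(pattern)]
  files <- sort(unique(files))
  ld_assert(length(files) >= 1L, "empty_selection",
            "no files match '%s'", paste(pattern, collapse = ", "))
  recordings <- list()
  errors <- character()
  for (f in files) {
    res <- tryCatch(read_recording(f, dialect, period = period),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[basename(f)]] <- conditionMessage(res)
    } else {
      recordings[[length(recordings) + 1L]] <- res
    }
  }
  list(recordings = recordings, errors = errors)
}

#' Read a mask-interval file
#'
#' Masks (non-wear, covered sensor, artefacts) are stored separately from
#' the data for easy editing: a JSON document of the form
#' `{"masks": [{"start": "...", "stop": "..."}, ...]}` with ISO-8601
#' timestamps and half-open `[start, stop)` semantics.
#'
#' @param path JSON file as above.
#' @return a [mask_spec()].
#' @export
read_mask_file <- function(path) {
  ld_assert(file.exists(path), "parameter", "file not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e) ld_stop("parse", "%s: %s", path,
                                              conditionMessage(e)))
  ld_assert(is.list(doc) && "masks" %in% names(doc), "parse",
            "%s: expected a top-level \"masks\" array", path)
  m <- doc$masks
  if (is.null(m) || (is.data.frame(m) && nrow(m) == 0L) || length(m) == 0L)
    return(mask_spec())
  ld_assert(is.data.frame(m) && all(c("start", "stop") %in% names(m)),
            "parse", "%s: each mask needs \"start\" and \"stop\"", path)
  start <- ld_time(m$start)
  stop_ <- ld_time(m$stop)
  bad <- which(is.na(start) | is.na(stop_))
  if (length(bad))
    ld_stop("parse", "%s: malformed timestamp in mask %d", path, bad[1])
  mask_spec(start, stop_)
}

#' Set of half-open exclusion intervals
#'
#' @param start,stop parallel vectors of interval bounds (timestamps);
#'   each interval is half-open `[start, stop)` and must satisfy
#'   `start < stop`. Intervals may overlap; union semantics apply. Call
#'   with no arguments for an empty (no-op) mask.
#' @return an object of class `mask_spec`: a data frame with columns
#'   `start` and `stop`.
#' @export
mask_spec <- function(start = NULL, stop = NULL) {
  if (is.null(start)) {
    out <- data.frame(start = ld_time(character()), stop = ld_time(character()))
  } else {
    start <- ld_time(start); stop <- ld_time(stop)
    ld_assert(length(start) == length(stop), "parameter",
              "start and stop must have equal length")
    bad <- which(!(as.numeric(start) < as.numeric(stop)))
    if (length(bad))
      ld_stop("invalid_interval", "mask interval %d has start >= stop", bad[1])
    out <- data.frame(start = start, stop = stop)
  }
  class(out) <- c("mask_spec", "data.frame")
  out
}

#' Write a metric summary table to CSV
#'
#' Writes RFC-4180 CSV with a header row, '.' decimal mark and the
#' recording name in the first column. Values are written with 15
#' significant digits so that reading the file back reproduces them to at
#' least 12 significant digits.
#'
#' @param table a metric table (data frame with a `name` column, as
#'   produced by [compute_metric_table()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_summary <- function(table, path) {
  ld_assert(is.data.frame(table) && "name" %in% names(table), "parameter",
            "expected a metric table with a 'name' column")
  out <- table
  for (col in setdiff(names(out), "name")) {
    v <- out[[col]]
    if (is.numeric(v))
      out[[col]] <- ifelse(is.na(v), "", sprintf("%.15g", v))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", dec = ".", qmethod = "double",
                       row.names = FALSE, col.names = TRUE, quote = FALSE,
                       na = "")
    TRUE
  }, error = function(e) ld_stop("io", "cannot write %s: %s", path,
                                 conditionMessage(e)))
  invisible(path)
}

#' Read back a metric summary CSV
#'
#' Inverse of [write_summary()]; used for round-trip checks and for
#' consuming CLI output programmatically.
#'
#' @param path CSV file written by [write_summary()].
#' @return a data frame with a `name` column and numeric metric columns.
#' @export
read_summary <- function(path) {
  ld_assert(file.exists(path), "parameter", "file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  for (col in setdiff(names(df), "name")) {
    v <- df[[col]]
    v[v == ""] <- NA_character_
    df[[col]] <- as.numeric(v)
  }
  df
}
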