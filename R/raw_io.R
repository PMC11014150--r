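# Reading and writing raw recordings, epoch tables, sleep logs and cohort
# tables. Raw storage unit is g throughout; MAD-family features are reported
# in mg, with the factor 1000 applied exactly once at feature computation.
# Timestamps are local clock time; epochs are half-open [start, start + 6 s).

#' Construct a raw triaxial recording
#'
#' A `raw_recording` holds uniformly sampled triaxial acceleration in units of
#' g together with the device metadata needed downstream: start time, sampling
#' rate, saturation range and quantization resolution.
#'
#' @param data Numeric matrix (or data frame) with three columns x, y, z in g.
#' @param sampling_rate Sampling frequency in Hz (> 0).
#' @param start_time `POSIXct` timestamp of the first sample. Interpreted as
#'   local clock time; hour-of-day summaries use this clock.
#' @param range_g Saturation bound of the sensor in g (default 16).
#' @param resolution_g Quantization step in g (default 0.004).
#' @param subject_id Opaque subject label.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, sampling_rate, start_time,
                          range_g = 16, resolution_g = 0.004,
                          subject_id = "unknown") {
  data <- as.matrix(data)
  if (!is.numeric(data) || ncol(data) != 3L)
    stop_format("raw data must have exactly three numeric columns (x, y, z)")
  if (nrow(data) < 1L) stop_data("recording must contain at least one sample")
  if (anyNA(data)) stop_data("raw samples contain missing values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop_config("sampling_rate must be a single positive number")
  if (!inherits(start_time, "POSIXct")) {
    start_time <- as.POSIXct(start_time, tz = "UTC")
  }
  colnames(data) <- c("x", "y", "z")
  n_clipped <- sum(abs(data) > range_g)
  if (n_clipped > 0)
    warning(sprintf("%d sample values exceed the +/-%g g range; kept as-is and flagged",
                    n_clipped, range_g))
  structure(
    list(data = data, sampling_rate = as.numeric(sampling_rate),
         start_time = start_time, range_g = range_g,
         resolution_g = resolution_g, subject_id = subject_id,
         n_clipped = n_clipped),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  dur <- nrow(x$data) / x$sampling_rate
  cat(sprintf("<raw_recording> subject %s: %d samples at %g Hz (%.1f min) from %s\n",
              x$subject_id, nrow(x$data), x$sampling_rate, dur / 60,
              format(x$start_time, "%Y-%m-%d %H:%M:%OS3")))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `raw_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$sampling_rate

.parse_times <- function(x) {
  if (is.numeric(x)) return(NULL)  # offsets handled by caller
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out)) stop_format("unparseable timestamps in input")
  out
}

#' Read a raw recording from a delimited-text or columnar table
#'
#' Supported dialects: delimited text with a header (columns `x`, `y`, `z` and
#' optionally `t`/`time`/`timestamp`), and Parquet/Feather columnar tables with
#' the same columns (via the arrow package). The declared unit is normalized to
#' g on load; values outside the sensor range are flagged, never altered.
#'
#' @param path Input file. `.parquet`/`.feather` files are read as columnar
#'   tables, anything else as delimited text.
#' @param unit Unit of the acceleration columns: `"g"` or `"mg"` (divided by
#'   1000 on load).
#' @param sampling_rate Sampling rate in Hz. Required when the file has no time
#'   column; otherwise inferred from median timestamp spacing if omitted.
#' @param start_time Start time; required when the file has no time column or
#'   carries seconds offsets (defaults to 1970-01-01 UTC for offsets).
#' @param sep Field separator for delimited text.
#' @param range_g,resolution_g,subject_id Passed to [raw_recording()].
#' @return A [raw_recording()].
#' @export
read_raw_recording <- function(path, unit = c("g", "mg"), sampling_rate = NULL,
                               start_time = NULL, sep = ",", range_g = 16,
                               resolution_g = 0.004, subject_id = NULL) {
  unit <- tryCatch(match.arg(unit),
                   error = function(e) stop_config("unknown unit; use 'g' or 'mg'"))
  if (!file.exists(path)) stop_data("file not found: ", path)
  if (grepl("\\.(parquet|feather)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop_config("the arrow package is required for columnar tables")
    df <- as.data.frame(if (grepl("\\.parquet$", path, ignore.case = TRUE))
      arrow::read_parquet(path) else arrow::read_feather(path))
  } else {
    df <- read.csv(path, sep = sep, check.names = FALSE)
  }
  names(df) <- tolower(names(df))
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop_format("missing required columns: ",
                paste(setdiff(need, names(df)), collapse = ", "))
  tcol <- intersect(c("t", "time", "timestamp"), names(df))[1]
  if (!is.na(tcol)) {
    tv <- df[[tcol]]
    if (is.numeric(tv)) {
      if (is.unsorted(tv, strictly = TRUE))
        stop_data("timestamps must be strictly increasing")
      if (is.null(sampling_rate)) {
        dt <- median(diff(tv))
        if (!is.finite(dt) || dt <= 0) stop_data("cannot infer sampling rate")
        sampling_rate <- 1 / dt
      }
      start_time <- (start_time %||% as.POSIXct("1970-01-01", tz = "UTC")) + tv[1]
    } else {
      tt <- .parse_times(as.character(tv))
      if (is.unsorted(as.numeric(tt), strictly = TRUE))
        stop_data("timestamps must be strictly increasing")
      if (is.null(sampling_rate)) {
        dt <- median(diff(as.numeric(tt)))
        if (!is.finite(dt) || dt <= 0) stop_data("cannot infer sampling rate")
        sampling_rate <- 1 / dt
      }
      start_time <- tt[1]
    }
  } else {
    if (is.null(sampling_rate))
      stop_config("sampling_rate is required when the file has no time column")
    start_time <- start_time %||% as.POSIXct("1970-01-01", tz = "UTC")
  }
  m <- as.matrix(df[, need])
  if (unit == "mg") m <- m / 1000
  raw_recording(m, sampling_rate = sampling_rate, start_time = start_time,
                range_g = range_g, resolution_g = resolution_g,
                subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a raw recording to delimited text
#'
#' Columns `t` (seconds offset from start), `x`, `y`, `z` in g.
#'
#' @param rec A [raw_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  t <- (seq_len(nrow(rec$data)) - 1) / rec$sampling_rate
  df <- data.frame(t = t, x = rec$data[, 1], y = rec$data[, 2], z = rec$data[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.epoch_required_cols <- c("start_time", "n_samples", "mad_mg", "madxyz_mg",
                          "xave_g", "yave_g", "zave_g", "rave_g", "steps",
                          "met", "wear")

#' Write an epoch table to delimited text
#'
#' Column names carry their units (`mad_mg`, `xave_g`, ...); `start_time` is
#' written as ISO-8601 with millisecond precision.
#'
#' @param epochs Epoch data frame as produced by [compute_epochs()] (possibly
#'   with APE/posture columns from [annotate_postures()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_table <- function(epochs, path) {
  miss <- setdiff(.epoch_required_cols, names(epochs))
  if (length(miss))
    stop_format("epoch table missing columns: ", paste(miss, collapse = ", "))
  out <- epochs
  out$start_time <- format(out$start_time, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  ok <- tryCatch({ write.csv(out, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path, call. = FALSE)
  invisible(path)
}

#' Read an epoch table written by [write_epoch_table()]
#' @param path Input path.
#' @return Epoch data frame with `start_time` parsed to `POSIXct` (UTC).
#' @export
read_epoch_table <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  miss <- setdiff(.epoch_required_cols, names(df))
  if (length(miss))
    stop_format("epoch table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    df$start_time <- .parse_times(as.character(df$start_time))
    df$wear <- as.logical(df$wear)
    if ("stationary" %in% names(df)) df$stationary <- as.logical(df$stationary)
    if ("is_reference" %in% names(df)) df$is_reference <- as.logical(df$is_reference)
  } else {
    df$start_time <- as.POSIXct(character(0), tz = "UTC")
  }
  df
}

#' Construct and validate a sleep log
#'
#' @param start,end `POSIXct` vectors of in-bed and wake times.
#' @return Data frame of class `sleep_log`, sorted, with validated
#'   non-overlapping intervals.
#' @export
sleep_log <- function(start, end) {
  start <- .parse_times(as.character(start))
  end <- .parse_times(as.character(end))
  if (length(start) != length(end)) stop_format("start/end length mismatch")
  if (any(end <= start)) stop_data("sleep interval ends before it starts")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1 && any(start[-1] < end[-length(end)]))
    stop_data("sleep intervals overlap")
  structure(data.frame(start = start, end = end),
            class = c("sleep_log", "data.frame"))
}

#' Read a sleep log from two-column delimited text
#'
#' Columns: in-bed start time and wake time (ISO-8601), one row per night.
#'
#' @param path Input path.
#' @return A [sleep_log()].
#' @export
read_sleep_log <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop_format("sleep log needs two columns (start, end)")
  sleep_log(df[[1]], df[[2]])
}

#' Read a cohort covariate table
#'
#' Expected columns: `subject_id`, `age` (years), `sex` (two-level label),
#' `bmi` (kg/m^2), `vo2max` (mL/kg/min), plus any per-bin summary-minute
#' columns.
#'
#' @param path Input path (delimited text with header).
#' @return Validated data frame.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c("subject_id", "age", "sex", "bmi", "vo2max")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("cohort table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$age < 0, na.rm = TRUE)) stop_data("negative age")
  if (any(df$bmi <= 0, na.rm = TRUE)) stop_data("non-positive BMI")
  bins <- setdiff(names(df), need)
  for (b in bins) if (is.numeric(df[[b]]) && any(df[[b]] < 0, na.rm = TRUE))
    stop_data("negative bin minutes in column ", b)
  df
}
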