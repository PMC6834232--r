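#' Overnight SpO2 trace
#'
#' Container for a uniformly sampled pulse-oximetry saturation series.
#' Missing or dropped-out samples are encoded as `NA` in `values` with
#' `valid_mask = FALSE`; the sample count is never changed by missingness.
#' Sample `i` (1-based) covers the half-open time interval
#' `[(i-1)/fs, i/fs)` seconds from recording start.
#'
#' @param values Numeric vector of SpO2 percentages. Valid entries must be
#'   integers in `[50, 100]`; invalid samples are `NA`.
#' @param fs Sampling rate in Hz. The devices modelled here record at 1 Hz
#'   (smartphone-compatible fingertip oximeter) or 8 Hz (polygraph oximeter).
#' @param device `"app"` or `"polygraph"`.
#' @param start_time Recording start, a `POSIXct` timestamp.
#'
#' @return An object of class `spo2_trace`: a list with elements `values`,
#'   `valid_mask`, `fs`, `device`, `start_time`.
#' @examples
#' tr <- spo2_trace(c(96, 95, NA, 96), fs = 1)
#' trace_duration_hours(tr)
#' @export
spo2_trace <- function(values, fs, device = c("app", "polygraph"),
                       start_time = as.POSIXct("2000-01-01 22:00:00", tz = "UTC")) {
  device <- match.arg(device)
  if (!is.numeric(fs) || length(fs) != 1 || !(fs %in% c(1, 8))) {
    stop("`fs` must be 1 or 8 Hz (supported oximeter sampling rates)",
         call. = FALSE)
  }
  values <- as.numeric(values)
  valid_mask <- !is.na(values)
  ok <- values[valid_mask]
  if (length(ok) && (any(ok < 50) || any(ok > 100))) {
    stop("valid SpO2 values must lie in [50, 100]", call. = FALSE)
  }
  if (length(ok) && any(ok != round(ok))) {
    stop("SpO2 samples must be integer percent (oximeters report integers)",
         call. = FALSE)
  }
  structure(
    list(values = values, valid_mask = valid_mask, fs = fs,
         device = device, start_time = as.POSIXct(start_time, tz = "UTC")),
    class = "spo2_trace"
  )
}

#' @export
print.spo2_trace <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<spo2_trace> %s device, %g Hz, %d samples (%.2f h), %d invalid\n",
              x$device, x$fs, n, n / (x$fs * 3600), sum(!x$valid_mask)))
  invisible(x)
}

#' @export
length.spo2_trace <- function(x) length(x$values)

#' Recording span of a trace in hours
#'
#' @param trace An [spo2_trace()].
#' @return Total recording span (sample count / fs / 3600), hours.
#' @export
trace_duration_hours <- function(trace) {
  stopifnot(inherits(trace, "spo2_trace"))
  length(trace$values) / (trace$fs * 3600)
}

# Onset time (seconds from recording start) of each sample.
sample_onsets <- function(trace) {
  (seq_along(trace$values) - 1) / trace$fs
}
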