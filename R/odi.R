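#' Baseline saturation specification
#'
#' Two conventions are in clinical use for the reference saturation from
#' which desaturation dips are measured. `"fixed"` takes a value measured
#' once at device hookup (the polygraph convention here); `"eleventh_minute"`
#' averages the valid samples of the 11th minute of recording
#' (seconds 600--659), by which time the signal has usually stabilised
#' (the smartphone-app convention here).
#'
#' @param method `"fixed"` or `"eleventh_minute"`.
#' @param fixed_value SpO2 percent in `[50, 100]`; required iff
#'   `method = "fixed"`.
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(method = c("eleventh_minute", "fixed"),
                          fixed_value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_value) || !is.numeric(fixed_value) ||
        length(fixed_value) != 1 || fixed_value < 50 || fixed_value > 100) {
      stop("`fixed` baseline needs a fixed_value in [50, 100]", call. = FALSE)
    }
  } else if (!is.null(fixed_value)) {
    stop("fixed_value is only meaningful with method = \"fixed\"",
         call. = FALSE)
  }
  structure(list(method = method, fixed_value = fixed_value),
            class = "baseline_spec")
}

#' Compute the baseline saturation of a trace
#'
#' @param trace An [spo2_trace()].
#' @param spec A [baseline_spec()].
#' @return Baseline SpO2 in percent (may be fractional: it is an average of
#'   integer samples).
#' @details Under `eleventh_minute` the trace must span at least 660 s and
#'   contain at least one valid sample with onset in `[600, 660)` s; a
#'   shorter trace is an error, never a silent fallback -- callers deciding
#'   patient eligibility should catch it (see [run_synthetic_study()]'s
#'   exclusion log).
#' @examples
#' tr <- spo2_trace(rep(96, 700), fs = 1)
#' compute_baseline(tr, baseline_spec("eleventh_minute"))
#' @export
compute_baseline <- function(trace, spec) {
  stopifnot(inherits(trace, "spo2_trace"), inherits(spec, "baseline_spec"))
  if (spec$method == "fixed") return(spec$fixed_value)
  onsets <- sample_onsets(trace)
  if (length(trace$values) / trace$fs < 660) {
    stop("trace shorter than 11 minutes: eleventh-minute baseline undefined",
         call. = FALSE)
  }
  win <- onsets >= 600 & onsets < 660 & trace$valid_mask
  if (!any(win)) {
    stop("no valid samples in the 11th minute [600 s, 660 s): baseline undefined",
         call. = FALSE)
  }
  mean(trace$values[win])
}

#' Detect oxygen desaturation dips
#'
#' A dip is a maximal run of consecutive valid samples whose value is at or
#' below `baseline - min_drop`, whose span (run length / fs) is at least
#' `min_duration` seconds. The defaults implement the screening definition
#' used throughout this package: a >=3 percentage-point decrease sustained
#' >=10 s. Both thresholds are inclusive. A dip ends as soon as saturation
#' returns above `baseline - min_drop` (no recovery-to-baseline hysteresis).
#' Invalid samples break a run by default -- a dip is never assumed to span
#' a signal dropout -- but short dropouts can be bridged with `bridge_gap_s`
#' for sensitivity analyses.
#'
#' @param trace An [spo2_trace()].
#' @param baseline Baseline SpO2 percent, in `[50, 100]`.
#' @param min_drop Minimum depth below baseline, percentage points (> 0).
#' @param min_duration Minimum duration in seconds (> 0).
#' @param bridge_gap_s Invalid-sample gaps up to this many seconds inside a
#'   below-threshold run are bridged (default 0: any dropout splits runs).
#' @return A `data.frame` with one row per dip, columns `onset_s`,
#'   `duration_s`, `nadir` and `depth` (nadir depth below baseline), sorted
#'   by onset. Zero rows when no dip qualifies.
#' @examples
#' v <- rep(96, 3600); v[1001:1030] <- 92
#' detect_dips(spo2_trace(v, fs = 1), baseline = 96)
#' @export
detect_dips <- function(trace, baseline, min_drop = 3, min_duration = 10,
                        bridge_gap_s = 0) {
  stopifnot(inherits(trace, "spo2_trace"))
  if (!is.numeric(baseline) || length(baseline) != 1 ||
      baseline < 50 || baseline > 100) {
    stop("baseline must be a single value in [50, 100]", call. = FALSE)
  }
  if (min_drop <= 0 || min_duration <= 0) {
    stop("min_drop and min_duration must be positive", call. = FALSE)
  }
  empty <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      nadir = numeric(0), depth = numeric(0))
  if (!any(trace$valid_mask)) {
    if (length(trace$values)) {
      warning("trace has no valid samples; no dips detectable", call. = FALSE)
    }
    return(empty)
  }
  thr <- baseline - min_drop
  below <- trace$valid_mask & !is.na(trace$values) & trace$values <= thr
  if (bridge_gap_s > 0) {
    # bridge invalid-sample gaps <= bridge_gap_s flanked by below-threshold runs
    r <- rle(ifelse(trace$valid_mask, ifelse(below, "b", "a"), "x"))
    idx_end <- cumsum(r$lengths)
    for (k in seq_along(r$values)) {
      if (r$values[k] == "x" && k > 1 && k < length(r$values) &&
          r$values[k - 1] == "b" && r$values[k + 1] == "b" &&
          r$lengths[k] / trace$fs <= bridge_gap_s) {
        below[(idx_end[k] - r$lengths[k] + 1):idx_end[k]] <- TRUE
      }
    }
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / trace$fs >= min_duration)
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  nadir <- vapply(seq_along(starts), function(i) {
    min(trace$values[starts[i]:ends[i]], na.rm = TRUE)
  }, numeric(1))
  data.frame(
    onset_s = (starts - 1) / trace$fs,
    duration_s = (ends - starts + 1) / trace$fs,
    nadir = nadir,
    depth = baseline - nadir
  )
}

#' Nightly oximetry summary
#'
#' Computes the standard overnight oximetry report: mean and lowest valid
#' SpO2, percentage of valid time spent below 90 percent, dip count and the
#' oxygen desaturation index (ODI, dips per hour).
#'
#' @inheritParams detect_dips
#' @param spec A [baseline_spec()] used for dip detection.
#' @param use_valid_time If `TRUE` the ODI denominator is valid recording
#'   time (valid samples / fs); default uses total recording span.
#' @return An object of class `oximetry_summary`: list with `mean_spo2`,
#'   `lowest_spo2`, `pct_time_below_90`, `total_dips`, `odi`,
#'   `recording_hours`, `baseline`.
#' @examples
#' tr <- spo2_trace(rep(96, 3600), fs = 1)
#' compute_summary(tr, baseline_spec("fixed", fixed_value = 96))
#' @export
compute_summary <- function(trace, spec, min_drop = 3, min_duration = 10,
                            use_valid_time = FALSE, bridge_gap_s = 0) {
  stopifnot(inherits(trace, "spo2_trace"))
  if (!any(trace$valid_mask)) {
    stop("trace has no valid samples: summary undefined", call. = FALSE)
  }
  vals <- trace$values[trace$valid_mask]
  baseline <- compute_baseline(trace, spec)
  dips <- detect_dips(trace, baseline, min_drop = min_drop,
                      min_duration = min_duration,
                      bridge_gap_s = bridge_gap_s)
  rec_h <- trace_duration_hours(trace)
  denom_h <- if (use_valid_time) sum(trace$valid_mask) / (trace$fs * 3600) else rec_h
  structure(
    list(
      mean_spo2 = mean(vals),
      lowest_spo2 = min(vals),
      pct_time_below_90 = 100 * sum(vals < 90) / length(vals),
      total_dips = nrow(dips),
      odi = nrow(dips) / denom_h,
      recording_hours = rec_h,
      baseline = baseline,
      dips = dips
    ),
    class = "oximetry_summary"
  )
}

#' @export
print.oximetry_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Overnight oximetry summary (%.2f h recording)\n",
    "  baseline SpO2      %.1f%%\n",
    "  mean / lowest SpO2 %.1f%% / %.0f%%\n",
    "  time below 90%%     %.1f%%\n",
    "  dips (>=3%%, >=10 s) %d\n",
    "  ODI                %.1f /h\n"),
    x$recording_hours, x$baseline, x$mean_spo2, x$lowest_spo2,
    x$pct_time_below_90, x$total_dips, x$odi))
  invisible(x)
}
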