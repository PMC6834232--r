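#' Read an app-dialect oximetry CSV
#'
#' The smartphone oximeter app exports one CSV row per second with header
#' `timestamp,spo2_pct,pulse_bpm,pi_pct` (ISO-8601 timestamps, UTF-8, LF
#' line endings). This dialect is a documented stand-in for the vendor
#' export, whose exact layout is not public; adapt real exports to it with
#' a converter. Blank, missing or zero SpO2 fields become invalid samples
#' (`NA` with `valid_mask = FALSE`) -- they are never dropped, so the row
#' count always equals the sample count.
#'
#' @param path Path to the CSV file.
#' @return An [spo2_trace()] at 1 Hz, device `"app"`.
#' @seealso [write_app_csv()]
#' @export
read_app_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  expected <- c("timestamp", "spo2_pct", "pulse_bpm", "pi_pct")
  if (!identical(names(df), expected)) {
    stop("malformed header: expected columns ",
         paste(expected, collapse = ","), " but found ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(spo2_trace(numeric(0), fs = 1, device = "app"))
  }
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) {
    stop("unparseable timestamp at row ", which(is.na(ts))[1], call. = FALSE)
  }
  dt <- diff(as.numeric(ts))
  if (length(dt) && any(dt <= 0)) {
    stop("non-monotonic timestamps: first offending row ",
         which(dt <= 0)[1] + 1, call. = FALSE)
  }
  raw <- trimws(df$spo2_pct)
  vals <- suppressWarnings(as.numeric(raw))
  # blank or zero SpO2 = no signal (e.g. probe detached); keep the row
  vals[raw == "" | is.na(vals) | vals == 0] <- NA_real_
  spo2_trace(vals, fs = 1, device = "app", start_time = ts[1])
}

#' Write an app-dialect oximetry CSV
#'
#' Inverse of [read_app_csv()]: one row per sample, invalid samples written
#' as empty SpO2 fields. Pulse rate and perfusion index are constant
#' placeholders (the analysis does not use them). Round-trips bit-exactly
#' through [read_app_csv()].
#'
#' @param trace An [spo2_trace()] at 1 Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_app_csv <- function(trace, path) {
  stopifnot(inherits(trace, "spo2_trace"))
  if (trace$fs != 1) {
    stop("app CSV dialect is 1 Hz; got fs = ", trace$fs, call. = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("timestamp,spo2_pct,pulse_bpm,pi_pct", con, sep = "\n")
  n <- length(trace$values)
  if (n > 0) {
    ts <- format(trace$start_time + seq_len(n) - 1,
                 "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    spo2 <- ifelse(trace$valid_mask,
                   format(as.integer(trace$values)), "")
    spo2[!trace$valid_mask] <- ""
    writeLines(paste(ts, spo2, "60", "2.0", sep = ","), con, sep = "\n")
  }
  invisible(path)
}

#' Read a scored respiratory-event list
#'
#' Reads the JSON event schema used for ground-truth annotations and for
#' scored polygraph exports: an array of objects with fields `onset_s`,
#' `duration_s`, `type` (`"apnea"` or `"hypopnea"`) and `mechanism`
#' (`"central"` or `"obstructive"`). Events are returned sorted by onset;
#' overlapping events and unknown mechanism strings are rejected. Events
#' labelled `"mixed"` in external data are rejected here rather than being
#' silently bucketed, because the downstream classification rule is binary.
#'
#' @param path Path to a JSON file (either a bare events array or an object
#'   with an `events` element, as written by [write_ground_truth()]).
#' @return A `data.frame` with columns `onset_s`, `duration_s`, `type`,
#'   `mechanism`, sorted by onset.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  ev <- if (is.data.frame(doc)) doc else doc$events
  if (is.null(ev) || length(ev) == 0 ||
      (is.data.frame(ev) && nrow(ev) == 0)) {
    return(empty_events())
  }
  validate_events(as.data.frame(ev))
}

# Shared event-list validation: schema, sort, overlap, mechanism vocabulary.
validate_events <- function(ev, recording_span = NULL) {
  need <- c("onset_s", "duration_s", "type", "mechanism")
  missing_cols <- setdiff(need, names(ev))
  if (length(missing_cols)) {
    stop("event list missing fields: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ev <- ev[need]
  bad_mech <- setdiff(unique(ev$mechanism), c("central", "obstructive"))
  if (length(bad_mech)) {
    stop("unknown event mechanism: ", paste(bad_mech, collapse = ", "),
         " (only central/obstructive are scored)", call. = FALSE)
  }
  bad_type <- setdiff(unique(ev$type), c("apnea", "hypopnea"))
  if (length(bad_type)) {
    stop("unknown event type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  if (any(ev$onset_s < 0) || any(ev$duration_s <= 0)) {
    stop("events need onset_s >= 0 and duration_s > 0", call. = FALSE)
  }
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) > 1) {
    ends <- ev$onset_s + ev$duration_s
    clash <- which(ev$onset_s[-1] < ends[-nrow(ev)])
    if (length(clash)) {
      stop(sprintf("overlapping events: #%d (onset %.1f s) and #%d (onset %.1f s)",
                   clash[1], ev$onset_s[clash[1]],
                   clash[1] + 1, ev$onset_s[clash[1] + 1]), call. = FALSE)
    }
  }
  if (!is.null(recording_span) && nrow(ev) &&
      any(ev$onset_s + ev$duration_s > recording_span + 1e-9)) {
    stop("event extends past end of recording", call. = FALSE)
  }
  ev
}

empty_events <- function() {
  data.frame(onset_s = numeric(0), duration_s = numeric(0),
             type = character(0), mechanism = character(0),
             stringsAsFactors = FALSE)
}

#' Write ground-truth annotations as JSON
#'
#' Serializes a ground-truth object from [generate_trace()] (patient id,
#' phenotype, true diagnosis and the scored event array) to the JSON schema
#' read back by [read_events()].
#'
#' @param gt A `ground_truth` object.
#' @param path Output path.
#' @param patient_id Identifier stored in the document.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path, patient_id = "P01") {
  stopifnot(inherits(gt, "ground_truth"))
  doc <- list(
    patient_id = patient_id,
    phenotype = gt$phenotype,
    true_diagnosis = gt$true_diagnosis,
    true_odi_poly = gt$true_odi_poly,
    clipped = gt$clipped,
    events = gt$events
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
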