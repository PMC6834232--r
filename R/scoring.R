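#' Scored sleep study
#'
#' Bundles an annotated respiratory-event list (already scored apneas and
#' hypopneas with central/obstructive mechanism labels) with the sleep
#' duration used as the index denominator. Event scoring itself -- airflow,
#' effort and desaturation criteria -- is upstream of this package; sleep
#' time is an input, not estimated.
#'
#' @param events A `data.frame` as returned by [read_events()] (columns
#'   `onset_s`, `duration_s`, `type`, `mechanism`).
#' @param sleep_hours Sleep duration in hours (> 0).
#' @return An object of class `sleep_study`.
#' @export
sleep_study <- function(events, sleep_hours) {
  if (!is.numeric(sleep_hours) || length(sleep_hours) != 1 ||
      !is.finite(sleep_hours) || sleep_hours <= 0) {
    stop("sleep_hours must be a single positive number", call. = FALSE)
  }
  events <- validate_events(as.data.frame(events))
  structure(list(events = events, sleep_hours = sleep_hours),
            class = "sleep_study")
}

#' Apnea-hypopnea index
#'
#' @param study A [sleep_study()].
#' @return AHI: (apneas + hypopneas) per hour of sleep.
#' @export
compute_ahi <- function(study) {
  stopifnot(inherits(study, "sleep_study"))
  nrow(study$events) / study$sleep_hours
}

#' Classify a sleep study as none / OSA / CSA
#'
#' Applies the study's diagnostic rule: sleep apnea is present when the
#' apnea-hypopnea index is at least 15 events per hour; present cases are
#' central sleep apnea (CSA) when at least half of all scored events carry
#' mechanism `"central"`, otherwise obstructive (OSA). The 50 percent
#' boundary counts as central.
#'
#' @param study A [sleep_study()].
#' @return An object of class `apnea_diagnosis`: list with `ahi`,
#'   `central_fraction` (`NA` when there are no events) and `label`
#'   (`"none"`, `"CSA"` or `"OSA"`).
#' @examples
#' ev <- data.frame(onset_s = seq(0, by = 60, length.out = 16),
#'                  duration_s = 20, type = "apnea",
#'                  mechanism = rep(c("central", "obstructive"), each = 8))
#' classify_apnea(sleep_study(ev, sleep_hours = 1))
#' @export
classify_apnea <- function(study) {
  stopifnot(inherits(study, "sleep_study"))
  n <- nrow(study$events)
  ahi <- n / study$sleep_hours
  cf <- if (n == 0) NA_real_ else mean(study$events$mechanism == "central")
  label <- if (ahi < 15) {
    "none"
  } else if (cf >= 0.5) {  # n > 0 guaranteed: ahi >= 15 needs events
    "CSA"
  } else {
    "OSA"
  }
  structure(list(ahi = ahi, central_fraction = cf, label = label),
            class = "apnea_diagnosis")
}

#' @export
print.apnea_diagnosis <- function(x, ...) {
  cf <- if (is.na(x$central_fraction)) "-" else sprintf("%.0f%%", 100 * x$central_fraction)
  cat(sprintf("<apnea_diagnosis> %s (AHI %.1f /h, central fraction %s)\n",
              x$label, x$ahi, cf))
  invisible(x)
}

#' Cohort prevalence of sleep-apnea diagnoses
#'
#' @param labels Character vector of diagnosis labels (`"none"`, `"CSA"`,
#'   `"OSA"`), or a list of `apnea_diagnosis` objects.
#' @return Named numeric vector `c(any_sa, csa, osa)` of percentages,
#'   rounded half-up to integers (reporting convention). The unrounded
#'   percentages are attached as attribute `"raw"`; before rounding,
#'   `csa + osa == any_sa` always.
#' @export
cohort_prevalence <- function(labels) {
  if (is.list(labels)) {
    labels <- vapply(labels, function(d) {
      stopifnot(inherits(d, "apnea_diagnosis")); d$label
    }, character(1))
  }
  if (length(labels) == 0) stop("empty cohort", call. = FALSE)
  bad <- setdiff(unique(labels), c("none", "CSA", "OSA"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  n <- length(labels)
  raw <- c(any_sa = 100 * sum(labels != "none") / n,
           csa = 100 * sum(labels == "CSA") / n,
           osa = 100 * sum(labels == "OSA") / n)
  out <- round_half_up(raw)
  attr(out, "raw") <- raw
  out
}

# Half-up rounding (base round() is round-half-even). digits = 0 default.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
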