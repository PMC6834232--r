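#' Synthetic patient profile
#'
#' Parameters of one simulated overnight recording. The generator emulates
#' the phenomenology a desaturation-based screen sees, not cardiorespiratory
#' physiology: a stable integer baseline, desaturation episodes with a
#' piecewise-linear descent / nadir plateau / recovery shape, additive
#' integer-rounded sensor noise, and dropout artifacts.
#'
#' Phenotypes differ in event layout and mechanism mix:
#' * `"central"`: periodic Cheyne-Stokes-like event train, events spaced
#'   `cycle_length` seconds apart with +/-10 percent jitter; at least 90
#'   percent of events are labelled central.
#' * `"obstructive"`: events with exponential inter-arrival times
#'   (clustered); at most 25 percent labelled central.
#' * `"none"`: sparse obstructive-style events at a rate keeping the
#'   apnea-hypopnea index well below 15/h.
#'
#' @param phenotype `"none"`, `"central"` or `"obstructive"`.
#' @param baseline_spo2 Integer baseline saturation, percent, in `[90, 99]`.
#' @param event_rate Respiratory events per hour of sleep (>= 0). Defaults:
#'   4 (none), 35 (central or obstructive) -- the apneic rates sit near the
#'   upper quartile of the AHI range seen in heart-failure sleep cohorts,
#'   giving clear separation from the 15/h diagnostic cutoff.
#' @param event_depth_mean Mean desaturation depth, percentage points
#'   (>= 3). Defaults: 4 (none), 6 (central), 5 (obstructive).
#' @param event_duration_mean Mean nadir-plateau duration, seconds (>= 10).
#' @param cycle_length Cheyne-Stokes cycle length in seconds, `[45, 90]`;
#'   used by the central phenotype only.
#' @param sleep_hours Recording span in hours, `[4, 10]` (recording span
#'   equals sleep span: no wake periods are modelled).
#' @param artifact_rate Signal-dropout segments per hour (>= 0); dropout
#'   lengths are exponential with mean 30 s.
#' @param noise_sd SD of the additive Gaussian sensor noise, percentage
#'   points, rounded to integers after addition (default 0.5).
#' @return An object of class `patient_profile`.
#' @export
patient_profile <- function(phenotype = c("none", "central", "obstructive"),
                            baseline_spo2 = 96,
                            event_rate = NULL,
                            event_depth_mean = NULL,
                            event_duration_mean = 20,
                            cycle_length = 60,
                            sleep_hours = 7,
                            artifact_rate = 0.5,
                            noise_sd = 0.5) {
  phenotype <- match.arg(phenotype)
  if (is.null(event_rate)) {
    event_rate <- switch(phenotype, none = 4, central = 35, obstructive = 35)
  }
  if (is.null(event_depth_mean)) {
    event_depth_mean <- switch(phenotype, none = 4, central = 6, obstructive = 5)
  }
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  stop_if(baseline_spo2 != round(baseline_spo2) ||
            baseline_spo2 < 90 || baseline_spo2 > 99,
          "baseline_spo2 must be an integer in [90, 99]")
  stop_if(event_rate < 0, "event_rate must be >= 0")
  stop_if(event_depth_mean < 3, "event_depth_mean must be >= 3 points")
  stop_if(event_duration_mean < 10, "event_duration_mean must be >= 10 s")
  stop_if(cycle_length < 45 || cycle_length > 90,
          "cycle_length must be in [45, 90] s")
  stop_if(sleep_hours < 4 || sleep_hours > 10,
          "sleep_hours must be in [4, 10]")
  stop_if(artifact_rate < 0, "artifact_rate must be >= 0")
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  structure(
    list(phenotype = phenotype, baseline_spo2 = as.integer(baseline_spo2),
         event_rate = event_rate, event_depth_mean = event_depth_mean,
         event_duration_mean = event_duration_mean,
         cycle_length = cycle_length, sleep_hours = sleep_hours,
         artifact_rate = artifact_rate, noise_sd = noise_sd),
    class = "patient_profile"
  )
}

# Plan the night's respiratory events. Uses the current RNG stream.
# Returns a data.frame with scheduling columns (descent/recovery ramp
# lengths, depth) alongside the scored-event schema columns.
plan_events <- function(profile) {
  total_s <- profile$sleep_hours * 3600
  # keep the first ~11.5 min event-free so both baseline conventions (first
  # minute, 11th minute) see undisturbed signal
  t_min <- 700
  k_target <- stats::rpois(1, profile$event_rate * profile$sleep_hours)
  if (k_target == 0) {
    plan <- empty_events()
    plan$depth <- numeric(0); plan$descent_s <- numeric(0)
    plan$recovery_s <- numeric(0); plan$clipped <- logical(0)
    return(plan)
  }
  descent <- stats::runif(k_target, 10, 20)
  recovery <- stats::runif(k_target, 10, 20)
  duration <- pmax(10, stats::rnorm(k_target, profile$event_duration_mean, 3))
  depth <- pmax(3, round(stats::rnorm(k_target, profile$event_depth_mean, 1)))
  clipped <- (profile$baseline_spo2 - depth) < 50
  depth[clipped] <- profile$baseline_spo2 - 50
  footprint <- descent + duration + recovery

  if (profile$phenotype == "central") {
    # periodic train: onset-to-onset spacing = jittered cycle length, but
    # never less than the previous event's footprint + 4 s of recovered
    # signal, so planted desaturations cannot merge into one run
    spacing <- profile$cycle_length * stats::runif(k_target, 0.9, 1.1)
    spacing <- pmax(spacing, footprint + 4)
    onset <- t_min + cumsum(c(0, spacing[-k_target]))
  } else {
    gap <- stats::rexp(k_target, rate = profile$event_rate / 3600)
    onset <- t_min + cumsum(gap)
    # push events apart so they never overlap
    if (k_target > 1) {
      for (i in 2:k_target) {
        min_onset <- onset[i - 1] + footprint[i - 1] + 4
        if (onset[i] < min_onset) onset[i] <- min_onset
      }
    }
  }
  fits <- onset + footprint <= total_s - 5
  plan <- data.frame(
    onset_s = onset[fits],
    duration_s = duration[fits],
    type = sample(c("apnea", "hypopnea"), sum(fits), replace = TRUE,
                  prob = c(0.4, 0.6)),
    mechanism = "obstructive",
    depth = depth[fits],
    descent_s = descent[fits],
    recovery_s = recovery[fits],
    clipped = clipped[fits],
    stringsAsFactors = FALSE
  )
  k <- nrow(plan)
  if (k > 0) {
    # deterministic mechanism counts so the phenotype rule holds on every
    # draw, not just in expectation
    n_central <- switch(profile$phenotype,
                        central = ceiling(0.9 * k),
                        obstructive = floor(0.25 * k),
                        none = floor(0.2 * k))
    if (n_central > 0) {
      plan$mechanism[sample.int(k, n_central)] <- "central"
    }
  }
  plan
}

# Render the clean (noise-free, artifact-free, integer-quantized) trace for
# an event plan at sampling rate fs. Deterministic given the plan.
render_clean <- function(plan, profile, fs) {
  n <- round(profile$sleep_hours * 3600 * fs)
  sig <- rep(as.numeric(profile$baseline_spo2), n)
  t <- (seq_len(n) - 1) / fs
  b <- profile$baseline_spo2
  for (i in seq_len(nrow(plan))) {
    o <- plan$onset_s[i]; de <- plan$descent_s[i]
    du <- plan$duration_s[i]; re <- plan$recovery_s[i]
    dp <- plan$depth[i]
    i0 <- max(1L, floor(o * fs) + 1L)
    i1 <- min(n, ceiling((o + de + du + re) * fs) + 1L)
    if (i0 > n) next
    tt <- t[i0:i1]
    seg <- ifelse(tt < o, b,
           ifelse(tt < o + de, b - dp * (tt - o) / de,
           ifelse(tt < o + de + du, b - dp,
           ifelse(tt < o + de + du + re, b - dp + dp * (tt - o - de - du) / re,
                  b))))
    sig[i0:i1] <- pmin(sig[i0:i1], seg)
  }
  pmin(100, pmax(50, round(sig)))
}

# Add sensor noise and dropout artifacts. Uses the current RNG stream.
apply_device_noise <- function(clean, fs, hours, noise_sd, artifact_rate) {
  vals <- clean
  if (noise_sd > 0) {
    vals <- pmin(100, pmax(50, vals + round(stats::rnorm(length(vals), 0, noise_sd))))
  }
  if (artifact_rate > 0) {
    n_drop <- stats::rpois(1, artifact_rate * hours)
    if (n_drop > 0) {
      starts <- floor(stats::runif(n_drop, 0, length(vals) - 1)) + 1
      lens <- pmax(1, round(stats::rexp(n_drop, 1 / 30) * fs))
      for (j in seq_len(n_drop)) {
        vals[starts[j]:min(length(vals), starts[j] + lens[j] - 1)] <- NA_real_
      }
    }
  }
  vals
}

ground_truth_from_plan <- function(plan, profile, fs_ref = 8) {
  events <- plan[c("onset_s", "duration_s", "type", "mechanism", "depth")]
  rownames(events) <- NULL
  # dips/hour on the clean reference-rate trace, counted by the same
  # definition the screen uses (>=3 points below baseline for >=10 s)
  clean8 <- render_clean(plan, profile, fs_ref)
  tr8 <- spo2_trace(clean8, fs = fs_ref, device = "polygraph")
  n_dips <- nrow(detect_dips(tr8, baseline = profile$baseline_spo2))
  diag <- classify_apnea(sleep_study(events[setdiff(names(events), "depth")],
                                     profile$sleep_hours))
  structure(
    list(events = events,
         true_odi_poly = n_dips / profile$sleep_hours,
         true_diagnosis = diag$label,
         true_ahi = diag$ahi,
         phenotype = profile$phenotype,
         clipped = any(plan$clipped)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s phenotype: %d events, AHI %.1f /h, clean ODI %.1f /h, diagnosis %s\n",
              x$phenotype, nrow(x$events), x$true_ahi, x$true_odi_poly,
              x$true_diagnosis))
  invisible(x)
}

#' Generate one synthetic overnight SpO2 trace with ground truth
#'
#' Plans a night of respiratory events for the profile, renders the
#' integer-quantized saturation signal at the requested sampling rate,
#' applies the profile's sensor noise and dropout artifacts, and returns the
#' trace together with the ground-truth annotation (event list, diagnosis
#' under the AHI/central-fraction rules, and the dip rate counted on the
#' clean 8 Hz rendering).
#'
#' Identical `(profile, fs, seed)` reproduce the identical output
#' bit-for-bit. Events whose nominal depth would push saturation below 50
#' percent are clipped at 50 and flagged (`ground_truth$clipped`).
#'
#' @param profile A [patient_profile()].
#' @param fs Sampling rate: 1 (app device) or 8 (polygraph device) Hz.
#' @param seed Integer RNG seed.
#' @return List with elements `trace` (an [spo2_trace()]) and
#'   `ground_truth`.
#' @examples
#' x <- generate_trace(patient_profile("central", noise_sd = 0), fs = 1, seed = 7)
#' x$ground_truth
#' @export
generate_trace <- function(profile, fs, seed) {
  stopifnot(inherits(profile, "patient_profile"))
  if (!fs %in% c(1, 8)) {
    stop("`fs` must be 1 or 8 Hz (supported oximeter sampling rates)",
         call. = FALSE)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  plan <- plan_events(profile)
  gt <- ground_truth_from_plan(plan, profile)
  clean <- render_clean(plan, profile, fs)
  vals <- apply_device_noise(clean, fs, profile$sleep_hours,
                             profile$noise_sd, profile$artifact_rate)
  device <- if (fs == 1) "app" else "polygraph"
  list(trace = spo2_trace(vals, fs = fs, device = device),
       ground_truth = gt)
}

#' Generate a synthetic dual-device cohort
#'
#' Draws a phenotype for each patient by the given prevalences and renders
#' two traces from one shared event plan per patient: a clean 8 Hz
#' polygraph-oximeter trace and a 1 Hz app trace carrying the profile's
#' independent device noise and dropout artifacts -- mirroring a study night
#' in which a patient wears both devices simultaneously.
#'
#' @param n_patients Number of patients (>= 1).
#' @param prevalence_csa,prevalence_osa Phenotype proportions in `[0, 1]`
#'   with sum <= 1; the remainder is the no-apnea phenotype.
#' @param seed Integer RNG seed; patient `i` uses seed `seed + i`, so
#'   cohorts are reproducible and patients independent.
#' @param profile_fun Function `(phenotype, rng_ready)` returning the
#'   [patient_profile()] for one patient; the default randomizes the
#'   baseline over 94--97 percent and the night length over 6--8.5 h.
#' @return List of `n_patients` elements, each a list with `id`, `poly`
#'   (8 Hz [spo2_trace()]), `app` (1 Hz trace) and `ground_truth`.
#' @export
generate_cohort <- function(n_patients, prevalence_csa, prevalence_osa, seed,
                            profile_fun = default_profile) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  for (p in c(prevalence_csa, prevalence_osa)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop("prevalences must lie in [0, 1]", call. = FALSE)
    }
  }
  if (prevalence_csa + prevalence_osa > 1) {
    stop("prevalence_csa + prevalence_osa must be <= 1", call. = FALSE)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  lapply(seq_len(n_patients), function(i) {
    set.seed(as.integer(seed) + i)
    phen <- sample(c("central", "obstructive", "none"), 1,
                   prob = c(prevalence_csa, prevalence_osa,
                            1 - prevalence_csa - prevalence_osa))
    profile <- profile_fun(phen)
    plan <- plan_events(profile)
    gt <- ground_truth_from_plan(plan, profile)
    poly_vals <- render_clean(plan, profile, fs = 8)
    app_clean <- render_clean(plan, profile, fs = 1)
    app_vals <- apply_device_noise(app_clean, 1, profile$sleep_hours,
                                   profile$noise_sd, profile$artifact_rate)
    list(id = sprintf("S%03d", i),
         profile = profile,
         poly = spo2_trace(poly_vals, fs = 8, device = "polygraph"),
         app = spo2_trace(app_vals, fs = 1, device = "app"),
         ground_truth = gt)
  })
}

#' Default per-patient profile used by [generate_cohort()]
#'
#' Randomizes the stable baseline over 94--97 percent and the night length
#' over 6--8.5 h (uses the current RNG stream); event structure follows the
#' phenotype defaults of [patient_profile()].
#'
#' @param phenotype `"none"`, `"central"` or `"obstructive"`.
#' @return A [patient_profile()].
#' @export
default_profile <- function(phenotype) {
  patient_profile(
    phenotype,
    baseline_spo2 = sample(94:97, 1),
    sleep_hours = stats::runif(1, 6, 8.5)
  )
}
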