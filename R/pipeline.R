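# Expected MD5 digests of the packaged fixtures; a mismatch means the
# installed data were edited and the endpoint replication would be silently
# wrong, so loading aborts.
.fixture_md5 <- c(
  study_patients_synthetic.csv = "8dfb203c63921485b75c53fd005103b7",
  polygraph_diagnoses_synthetic.csv = "99e74c7fba1ea71e1180c441874b2f74"
)

#' Packaged per-patient study fixtures
#'
#' The study that this pipeline replicates published only marginal 2x2
#' tables, never per-patient data. These fixtures are synthetic
#' reconstructions: a 22-patient table (polygraph diagnosis plus mobile and
#' polygraph ODI values) chosen to be simultaneously consistent with all
#' four published screen-versus-reference tables, and the 24-patient
#' diagnosis list of the full polygraph cohort (the 22 plus the two
#' patients whose app recording of the study night was missing). The ODI
#' magnitudes are synthetic; only their position relative to the 15/h
#' cutoff is determined by the published tables.
#'
#' @param which `"patients"` (22 analyzable patients) or `"polygraph"`
#'   (24 diagnosed patients).
#' @return A `data.frame`.
#' @export
study_fixture <- function(which = c("patients", "polygraph")) {
  which <- match.arg(which)
  fname <- switch(which,
                  patients = "study_patients_synthetic.csv",
                  polygraph = "polygraph_diagnoses_synthetic.csv")
  path <- system.file("extdata", fname, package = "apneascreen")
  if (path == "") stop("fixture ", fname, " not found in installed package",
                       call. = FALSE)
  digest <- unname(tools::md5sum(path))
  if (!identical(digest, unname(.fixture_md5[[fname]]))) {
    stop("fixture checksum mismatch for ", fname,
         ": installed data do not match the packaged reconstruction",
         call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

new_study_report <- function(tables, stats, prevalence, power_n, provenance,
                             exclusions = data.frame(id = character(0),
                                                     reason = character(0))) {
  structure(list(tables = tables, stats = stats, prevalence = prevalence,
                 power_n = power_n, provenance = provenance,
                 exclusions = exclusions),
            class = "study_report")
}

#' Replicate the published screening endpoints from the packaged fixture
#'
#' Runs the complete endpoint analysis on the packaged per-patient
#' reconstruction: builds the four screen-versus-reference tables
#' (mobile-ODI vs central sleep apnea, mobile-ODI vs any sleep apnea,
#' polygraph-ODI vs central sleep apnea, polygraph-ODI vs any sleep apnea)
#' at the 15 dips/hour cutoff, computes McNemar p-values and diagnostic
#' metrics for each, the cohort prevalences over the 24-patient polygraph
#' cohort, and the paired-proportions sample-size calculation that sized
#' the design (alpha .05, power .80, p01/p10 = 12, p01+p10 = 0.39).
#'
#' @param threshold Screen-positivity ODI cutoff (dips/hour).
#' @param method McNemar method for the reported p-values.
#' @return A `study_report`: list with `tables` (four
#'   [contingency_2x2()]), `stats` (matching `agreement_stats`),
#'   `prevalence`, `power_n` and `provenance`.
#' @examples
#' rep <- replicate_study()
#' rep$tables$mobile_csa
#' rep$stats$mobile_csa
#' @export
replicate_study <- function(threshold = 15,
                            method = c("exact", "continuity_corrected")) {
  method <- match.arg(method)
  patients <- study_fixture("patients")
  cohort24 <- study_fixture("polygraph")
  tables <- list(
    mobile_csa = build_table(patients$diagnosis == "CSA",
                             patients$odi_mobile, threshold),
    mobile_any = build_table(patients$diagnosis != "none",
                             patients$odi_mobile, threshold),
    poly_csa = build_table(patients$diagnosis == "CSA",
                           patients$odi_poly, threshold),
    poly_any = build_table(patients$diagnosis != "none",
                           patients$odi_poly, threshold)
  )
  stats <- lapply(tables, diagnostic_metrics, method = method)
  new_study_report(
    tables = tables,
    stats = stats,
    prevalence = cohort_prevalence(cohort24$diagnosis),
    power_n = mcnemar_sample_size(alpha = 0.05, beta = 0.20,
                                  psi = 12, pdisc = 0.39),
    provenance = list(source = "packaged fixture", threshold = threshold,
                      method = method, n_analyzable = nrow(patients),
                      n_polygraph = nrow(cohort24))
  )
}

#' Run the full screening analysis on a synthetic cohort
#'
#' End-to-end study emulation: generates a dual-device cohort with
#' [generate_cohort()], computes each patient's app-trace ODI (baseline =
#' mean saturation of the 11th minute) and polygraph-trace ODI (baseline =
#' the hookup value, emulated as the rounded mean of the first minute of
#' the polygraph trace), derives the reference diagnosis from the
#' ground-truth event list via [classify_apnea()], and assembles the same
#' four agreement tables and statistics as [replicate_study()].
#'
#' Patients whose app trace cannot yield an eleventh-minute baseline (too
#' short, or fully dropped-out window) are excluded and logged, so included
#' patients + exclusions always account for the whole cohort.
#'
#' @param n_patients Cohort size.
#' @param prevalence_csa,prevalence_osa Phenotype proportions.
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param threshold Screen-positivity ODI cutoff (dips/hour).
#' @param method McNemar method.
#' @param profile_fun Per-patient profile factory, see [generate_cohort()].
#' @return A `study_report` with an `exclusions` data.frame and, in
#'   `provenance`, the seed, configuration and per-patient results
#'   (`provenance$patients`).
#' @examples
#' rep <- run_synthetic_study(12, 7 / 22, 6 / 22, seed = 42)
#' rep$prevalence
#' @export
run_synthetic_study <- function(n_patients, prevalence_csa, prevalence_osa,
                                seed, threshold = 15,
                                method = c("exact", "continuity_corrected"),
                                profile_fun = default_profile) {
  method <- match.arg(method)
  cohort <- generate_cohort(n_patients, prevalence_csa, prevalence_osa,
                            seed, profile_fun = profile_fun)
  rows <- list()
  excl <- list()
  for (pat in cohort) {
    ref <- pat$ground_truth$true_diagnosis
    app_odi <- tryCatch({
      s <- compute_summary(pat$app, baseline_spec("eleventh_minute"))
      s$odi
    }, error = function(e) e)
    if (inherits(app_odi, "error")) {
      excl[[length(excl) + 1]] <- data.frame(id = pat$id,
                                             reason = conditionMessage(app_odi))
      next
    }
    hookup <- pat$poly$values[sample_onsets(pat$poly) < 60 & pat$poly$valid_mask]
    poly_base <- round(mean(hookup))
    poly_sum <- compute_summary(pat$poly,
                                baseline_spec("fixed", fixed_value = poly_base))
    rows[[length(rows) + 1]] <- data.frame(
      id = pat$id, diagnosis = ref,
      odi_mobile = app_odi, odi_poly = poly_sum$odi,
      true_odi = pat$ground_truth$true_odi_poly,
      ahi = pat$ground_truth$true_ahi,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no analyzable patients in cohort", call. = FALSE)
  res <- do.call(rbind, rows)
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(0), reason = character(0))
  tables <- list(
    mobile_csa = build_table(res$diagnosis == "CSA", res$odi_mobile, threshold),
    mobile_any = build_table(res$diagnosis != "none", res$odi_mobile, threshold),
    poly_csa = build_table(res$diagnosis == "CSA", res$odi_poly, threshold),
    poly_any = build_table(res$diagnosis != "none", res$odi_poly, threshold)
  )
  new_study_report(
    tables = tables,
    stats = lapply(tables, diagnostic_metrics, method = method),
    prevalence = cohort_prevalence(res$diagnosis),
    power_n = mcnemar_sample_size(alpha = 0.05, beta = 0.20,
                                  psi = 12, pdisc = 0.39),
    provenance = list(source = "synthetic cohort", seed = seed,
                      n_patients = n_patients,
                      prevalence_csa = prevalence_csa,
                      prevalence_osa = prevalence_osa,
                      threshold = threshold, method = method,
                      patients = res),
    exclusions = exclusions
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Sleep-apnea screening study report (", x$provenance$source, ")\n",
      sep = "")
  cat(sprintf("  cohort prevalence: any SA %d%%, CSA %d%%, OSA %d%%\n",
              x$prevalence[["any_sa"]], x$prevalence[["csa"]],
              x$prevalence[["osa"]]))
  for (nm in names(x$tables)) {
    tb <- x$tables[[nm]]
    st <- x$stats[[nm]]
    pct <- function(p) if (is.na(p)) "-" else sprintf("%d%%", round_half_up(100 * p))
    cat(sprintf("  %-10s (a,b,c,d)=(%d,%d,%d,%d)  sens %s spec %s ppv %s npv %s  McNemar p=%.2f\n",
                nm, tb$a, tb$b, tb$c, tb$d, pct(st$sensitivity),
                pct(st$specificity), pct(st$ppv), pct(st$npv), st$mcnemar_p))
  }
  cat(sprintf("  design sample size (paired McNemar): %d pairs\n", x$power_n))
  if (nrow(x$exclusions)) {
    cat(sprintf("  excluded patients: %d\n", nrow(x$exclusions)))
  }
  invisible(x)
}

#' Read a cohort configuration file
#'
#' Reads a YAML (or JSON) cohort specification with fields `n_patients`,
#' `prevalence_csa`, `prevalence_osa` and optional `threshold` and
#' `method`, validated and ready to splice into [run_synthetic_study()].
#' The seed is deliberately not part of the file: reproducibility is the
#' caller's explicit responsibility.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of arguments for [run_synthetic_study()].
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  required <- c("n_patients", "prevalence_csa", "prevalence_osa")
  problems <- character(0)
  for (f in required) {
    if (is.null(cfg[[f]])) problems <- c(problems, paste("missing field:", f))
  }
  if (!is.null(cfg$n_patients) && (!is.numeric(cfg$n_patients) ||
                                   cfg$n_patients < 1)) {
    problems <- c(problems, "n_patients must be >= 1")
  }
  for (f in c("prevalence_csa", "prevalence_osa")) {
    v <- cfg[[f]]
    if (!is.null(v) && (!is.numeric(v) || v < 0 || v > 1)) {
      problems <- c(problems, paste(f, "must lie in [0, 1]"))
    }
  }
  if (!is.null(cfg$method) &&
      !cfg$method %in% c("exact", "continuity_corrected")) {
    problems <- c(problems, "method must be exact or continuity_corrected")
  }
  if (length(problems)) {
    stop("invalid cohort config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  cfg[intersect(names(cfg), c(required, "threshold", "method"))]
}
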