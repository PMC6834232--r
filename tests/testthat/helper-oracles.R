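# Independent reference implementations used to cross-check the package.
# These stay deliberately naive: straight scans and combinatorial sums.

# Brute-force dip scan: walk every sample, growing runs of valid samples at
# or below baseline - min_drop; emit each maximal run spanning >= min_duration.
oracle_detect_dips <- function(values, fs, baseline, min_drop = 3,
                               min_duration = 10) {
  below <- function(i) !is.na(values[i]) && values[i] <= baseline - min_drop
  out <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                    nadir = numeric(0), depth = numeric(0))
  i <- 1
  n <- length(values)
  while (i <= n) {
    if (below(i)) {
      j <- i
      while (j < n && below(j + 1)) j <- j + 1
      if ((j - i + 1) / fs >= min_duration) {
        nad <- min(values[i:j])
        out <- rbind(out, data.frame(onset_s = (i - 1) / fs,
                                     duration_s = (j - i + 1) / fs,
                                     nadir = nad, depth = baseline - nad))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# Exact McNemar two-sided p by direct combinatorial enumeration of all
# outcomes of the b + c discordant pairs under the null (fair coin).
oracle_mcnemar_exact <- function(b, c) {
  nd <- b + c
  if (nd == 0) return(1)
  m <- min(b, c)
  tail_prob <- sum(choose(nd, 0:m)) / 2^nd
  min(1, 2 * tail_prob)
}

# Random trace for property tests: mixed valid/invalid integer samples.
random_test_trace <- function(rng_unused = NULL) {
  fs <- sample(c(1, 8), 1)
  n <- sample(60:400, 1)
  vals <- sample(85:100, n, replace = TRUE)
  vals[stats::runif(n) < 0.05] <- NA
  list(trace = spo2_trace(vals, fs = fs), fs = fs, values = vals)
}

quiet_profile <- function(phenotype) {
  patient_profile(phenotype,
                  baseline_spo2 = sample(94:97, 1),
                  sleep_hours = stats::runif(1, 6, 7.5),
                  noise_sd = 0, artifact_rate = 0)
}
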