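test_that("baseline conventions behave as specified", {
  tr <- spo2_trace(rep(96, 700), fs = 1)
  expect_equal(compute_baseline(tr, baseline_spec("eleventh_minute")), 96)
  # fixed baseline is a pass-through regardless of the trace
  expect_equal(compute_baseline(tr, baseline_spec("fixed", fixed_value = 95)), 95)

  # alternating 94/96 across the 60 window samples averages to 95
  v <- rep(96, 700)
  v[601:660] <- rep(c(94, 96), 30)  # onsets 600..659 s at 1 Hz
  expect_equal(compute_baseline(spo2_trace(v, fs = 1),
                                baseline_spec("eleventh_minute")), 95)

  # shorter than 11 min: explicit error, no fallback
  expect_error(compute_baseline(spo2_trace(rep(96, 500), fs = 1),
                                baseline_spec("eleventh_minute")),
               "11 min")
  # window fully invalid: error
  v2 <- rep(96, 700); v2[601:660] <- NA
  expect_error(compute_baseline(spo2_trace(v2, fs = 1),
                                baseline_spec("eleventh_minute")),
               "11th minute")
  expect_error(baseline_spec("fixed"), "fixed_value")
})

test_that("dip detection honours depth and duration thresholds inclusively", {
  base <- rep(96, 3600)
  expect_equal(nrow(detect_dips(spo2_trace(base, fs = 1), 96)), 0)

  v <- base; v[1001:1030] <- 92
  d <- detect_dips(spo2_trace(v, fs = 1), 96)
  expect_equal(nrow(d), 1)
  expect_equal(d$depth, 4)
  expect_equal(d$duration_s, 30)
  expect_equal(d$onset_s, 1000)

  # 9 s fails the >=10 s duration criterion
  v <- base; v[1001:1009] <- 92
  expect_equal(nrow(detect_dips(spo2_trace(v, fs = 1), 96)), 0)

  # boundary inclusivity: exactly baseline - 3 for exactly 10.0 s qualifies
  v <- base; v[1001:1010] <- 93
  d <- detect_dips(spo2_trace(v, fs = 1), 96)
  expect_equal(nrow(d), 1)
  expect_equal(d$depth, 3)
  expect_equal(d$duration_s, 10)
  # one point shallower does not
  v <- base; v[1001:1010] <- 94
  expect_equal(nrow(detect_dips(spo2_trace(v, fs = 1), 96)), 0)
})

test_that("invalid samples split runs unless explicitly bridged", {
  v <- rep(96, 600)
  v[101:130] <- 92
  v[115] <- NA  # dropout inside the excursion
  tr <- spo2_trace(v, fs = 1)
  d0 <- detect_dips(tr, 96)
  expect_equal(nrow(d0), 2)  # 14 s + 15 s halves both qualify
  d1 <- detect_dips(tr, 96, bridge_gap_s = 2)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$duration_s, 30)

  # all-invalid trace warns and returns no dips
  allna <- spo2_trace(rep(NA_real_, 50), fs = 1)
  expect_warning(d <- detect_dips(allna, 96), "no valid samples")
  expect_equal(nrow(d), 0)
})

test_that("dip detector matches the brute-force oracle on random traces", {
  set.seed(501)
  for (i in 1:300) {
    tt <- random_test_trace()
    baseline <- sample(90:98, 1)
    min_drop <- sample(2:4, 1)
    min_dur <- sample(c(5, 8, 10), 1)
    got <- detect_dips(tt$trace, baseline, min_drop, min_dur)
    want <- oracle_detect_dips(tt$values, tt$fs, baseline, min_drop, min_dur)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$onset_s, want$onset_s)
      expect_equal(got$duration_s, want$duration_s)
      expect_equal(got$nadir, want$nadir)
    }
  }
})

test_that("dip count is monotone in both thresholds", {
  set.seed(502)
  for (i in 1:50) {
    tt <- random_test_trace()
    n1 <- nrow(detect_dips(tt$trace, 96, min_drop = 2, min_duration = 5))
    n2 <- nrow(detect_dips(tt$trace, 96, min_drop = 3, min_duration = 5))
    n3 <- nrow(detect_dips(tt$trace, 96, min_drop = 3, min_duration = 10))
    expect_lte(n2, n1)
    expect_lte(n3, n2)
  }
})

test_that("sampling rate does not change dip counts for second-aligned signals", {
  set.seed(503)
  for (i in 1:20) {
    # piecewise-constant signal changing on whole seconds, runs >= 10 s
    secs <- 900
    v1 <- rep(96, secs)
    n_exc <- sample(1:5, 1)
    starts <- sort(sample(seq(1, secs - 40, by = 40), n_exc))
    for (s in starts) v1[s:(s + sample(10:25, 1))] <- sample(88:93, 1)
    v8 <- rep(v1, each = 8)
    d1 <- detect_dips(spo2_trace(v1, fs = 1), 96)
    d8 <- detect_dips(spo2_trace(v8, fs = 8), 96)
    expect_equal(nrow(d1), nrow(d8))
    if (nrow(d1)) expect_equal(d1$duration_s, d8$duration_s)
  }
})

test_that("summary equals first-principles recomputation and ODI is scale invariant", {
  set.seed(504)
  v <- rep(96, 7200)
  for (s in seq(800, 6800, by = 600)) v[s:(s + 29)] <- 92
  v[50:60] <- NA
  v[3000:3010] <- 89  # 11 s below 90 and 4+ below baseline
  tr <- spo2_trace(v, fs = 1)
  sm <- compute_summary(tr, baseline_spec("fixed", fixed_value = 96))

  valid <- v[!is.na(v)]
  expect_equal(sm$mean_spo2, mean(valid))
  expect_equal(sm$lowest_spo2, min(valid))
  expect_equal(sm$pct_time_below_90, 100 * sum(valid < 90) / length(valid))
  expect_equal(sm$recording_hours, 2)
  expect_equal(sm$total_dips,
               nrow(oracle_detect_dips(v, 1, 96)))
  expect_equal(sm$odi, sm$total_dips / 2)

  # 2 h trace with 3 qualifying dips -> ODI 1.5
  v3 <- rep(96, 7200)
  for (s in c(1000, 3000, 5000)) v3[s:(s + 19)] <- 92
  sm3 <- compute_summary(spo2_trace(v3, fs = 1),
                         baseline_spec("fixed", fixed_value = 96))
  expect_equal(sm3$total_dips, 3)
  expect_equal(sm3$odi, 1.5)

  # concatenating a trace with itself leaves ODI unchanged
  sm2 <- compute_summary(spo2_trace(c(v3, v3), fs = 1),
                         baseline_spec("fixed", fixed_value = 96))
  expect_equal(sm2$odi, sm3$odi)

  # valid-time denominator shrinks the denominator, never the dip count
  v4 <- v3; v4[6000:7200] <- NA
  smv <- compute_summary(spo2_trace(v4, fs = 1),
                         baseline_spec("fixed", fixed_value = 96),
                         use_valid_time = TRUE)
  expect_equal(smv$total_dips, 3)
  expect_gt(smv$odi, 1.5)
})
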