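test_that("2x2 construction and screening threshold are inclusive at 15", {
  tb <- build_table(c(TRUE, TRUE, FALSE, FALSE), c(15, 14.9, 15, 0))
  expect_equal(c(tb$a, tb$b, tb$c, tb$d), c(1, 1, 1, 1))

  # all reference-positive, all screening positive
  tb <- build_table(rep(TRUE, 5), rep(20, 5))
  expect_equal(c(tb$a, tb$b, tb$c, tb$d), c(5, 0, 0, 0))

  # degenerate threshold 0 with positive ODI everywhere: no screen negatives
  tb <- build_table(c(TRUE, FALSE, TRUE), c(1, 2, 3), threshold = 0)
  expect_equal(tb$c + tb$d, 0)

  expect_error(build_table(logical(0), numeric(0)), "no pairs")
  expect_error(contingency_2x2(1, -1, 0, 0), "non-negative")
  expect_error(contingency_2x2(0, 0, 0, 0), "at least one")
})

test_that("exact McNemar equals combinatorial enumeration for all b+c <= 20", {
  for (nd in 1:20) {
    for (b in 0:nd) {
      cc <- nd - b
      p <- mcnemar_test(contingency_2x2(2, b, cc, 3), method = "exact")
      expect_equal(p, oracle_mcnemar_exact(b, cc), tolerance = 1e-12)
      # symmetry in the discordant cells
      p_sym <- mcnemar_test(contingency_2x2(2, cc, b, 3), method = "exact")
      expect_equal(p, p_sym)
      # concordant cells never matter
      p_conc <- mcnemar_test(contingency_2x2(50, b, cc, 0), method = "exact")
      expect_equal(p, p_conc)
    }
  }
  # b = c: perfect symmetry, p = 1 exactly
  expect_equal(mcnemar_test(contingency_2x2(1, 6, 6, 1)), 1)
  expect_message(p0 <- mcnemar_test(contingency_2x2(4, 0, 0, 4)),
                 "no discordant")
  expect_equal(p0, 1)
})

test_that("continuity-corrected McNemar matches the standard chi-square test", {
  set.seed(801)
  for (i in 1:50) {
    b <- sample(0:15, 1); cc <- sample(0:15, 1)
    if (b + cc == 0) next
    tb <- contingency_2x2(sample(0:10, 1), b, cc, sample(0:10, 1))
    got <- mcnemar_test(tb, "continuity_corrected")
    ref <- stats::mcnemar.test(matrix(c(tb$a, tb$c, tb$b, tb$d), 2, 2),
                               correct = TRUE)$p.value
    if (b == cc) {
      # the (|b-c|-1)^2 correction at b = c: chi-square stat 1/(b+c)
      expect_equal(got, stats::pchisq(1 / (b + cc), 1, lower.tail = FALSE))
    } else {
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("diagnostic metrics use the standard 2x2 formulas with NA when undefined", {
  st <- diagnostic_metrics(contingency_2x2(3, 7, 4, 8))
  expect_equal(st$sensitivity, 3 / 7)
  expect_equal(st$specificity, 8 / 15)
  expect_equal(st$ppv, 3 / 10)
  expect_equal(st$npv, 8 / 12)

  st0 <- diagnostic_metrics(contingency_2x2(0, 0, 0, 9))
  expect_true(is.na(st0$sensitivity))
  expect_true(is.na(st0$ppv))
  expect_equal(st0$specificity, 1)

  # Bayes identity: PPV from (sens, spec, prevalence) equals the count ratio
  set.seed(802)
  for (i in 1:50) {
    cells <- sample(0:12, 4, replace = TRUE)
    if (sum(cells) == 0 || cells[1] + cells[3] == 0 ||
        cells[2] + cells[4] == 0 || cells[1] + cells[2] == 0) next
    tb <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    st <- diagnostic_metrics(tb)
    prev <- (tb$a + tb$c) / (tb$a + tb$b + tb$c + tb$d)
    bayes <- st$sensitivity * prev /
      (st$sensitivity * prev + (1 - st$specificity) * (1 - prev))
    expect_equal(st$ppv, bayes, tolerance = 1e-12)
  }
})

test_that("paired sample-size formula reproduces the design and is monotone", {
  expect_equal(mcnemar_sample_size(0.05, 0.20, psi = 12, pdisc = 0.39), 26L)
  n_base <- mcnemar_sample_size(0.05, 0.20, 12, 0.39)
  # doubling the total discordance at fixed ratio strengthens the effect
  expect_lt(mcnemar_sample_size(0.05, 0.20, 12, 0.78), n_base)
  # stricter alpha or higher power require more pairs
  expect_gte(mcnemar_sample_size(0.01, 0.20, 12, 0.39), n_base)
  expect_gte(mcnemar_sample_size(0.05, 0.10, 12, 0.39), n_base)
  expect_error(mcnemar_sample_size(0.05, 0.20, 1, 0.39), "psi = 1")
  expect_error(mcnemar_sample_size(0.05, 0.20, -2, 0.39), "positive")
  expect_error(mcnemar_sample_size(0.05, 0.20, 12, 1.5), "pdisc")
})

test_that("Bland-Altman bias and limits match direct recomputation", {
  ba <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ba$bias, ba$loa_low, ba$loa_high), c(0, 0, 0))

  ba <- bland_altman(c(5, 7, 9), c(2, 4, 6))  # constant difference 3
  expect_equal(c(ba$bias, ba$loa_low, ba$loa_high), c(3, 3, 3))

  set.seed(803)
  x <- rnorm(40, 15, 8); y <- rnorm(40, 13, 8)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, mean(x - y))
  expect_equal(ba$loa_high, mean(x - y) + 1.96 * sd(x - y))
  expect_equal(ba$plot_data$x, x)
  expect_equal(ba$plot_data$diff, x - y)

  # LoA contain ~95% of differences for large Gaussian samples
  x <- rnorm(4000); y <- rnorm(4000)
  ba <- bland_altman(x, y)
  inside <- mean(x - y >= ba$loa_low & x - y <= ba$loa_high)
  expect_lt(abs(inside - 0.95), 3 * sqrt(0.95 * 0.05 / 4000))

  expect_error(bland_altman(1:3, 1:2), "length")
  expect_error(bland_altman(1, 1), "2 pairs")
})

test_that("median/IQR reporting follows the interpolated quantile convention", {
  expect_equal(paired_median_iqr(5), c(median = 5, q25 = 5, q75 = 5))
  expect_equal(paired_median_iqr(c(1, 2, 3, 4))[["median"]], 2.5)
  set.seed(804)
  z <- rnorm(37)
  expect_equal(unname(paired_median_iqr(z)),
               unname(stats::quantile(z, c(0.5, 0.25, 0.75), type = 7)))
  expect_error(paired_median_iqr(numeric(0)), "empty")
})
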