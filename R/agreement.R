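#' Paired 2x2 screen-versus-reference table
#'
#' Cell layout follows the usual diagnostic convention:
#' `a` reference-positive & screen-positive, `b` reference-negative &
#' screen-positive, `c` reference-positive & screen-negative, `d`
#' reference-negative & screen-negative.
#'
#' @param a,b,c,d Non-negative integer counts; `a+b+c+d >= 1`.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("table must contain at least one pair", call. = FALSE)
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(screen = c("positive", "negative"),
                              reference = c("positive", "negative")))
  cat("<contingency_2x2> n =", x$a + x$b + x$c + x$d, "\n")
  print(m)
  invisible(x)
}

#' Build a 2x2 table from paired reference calls and screening ODI values
#'
#' The screen is positive when the oxygen desaturation index reaches the
#' threshold (default 15 dips/hour, inclusive).
#'
#' @param reference_positive Logical vector: reference diagnosis per patient.
#' @param screen_odi Numeric vector of ODI values, same length.
#' @param threshold Screen-positivity cutoff in dips/hour (screen positive
#'   iff `odi >= threshold`).
#' @return A [contingency_2x2()].
#' @examples
#' build_table(c(TRUE, TRUE, FALSE), c(22, 4, 17))
#' @export
build_table <- function(reference_positive, screen_odi, threshold = 15) {
  if (length(reference_positive) == 0) stop("no pairs supplied", call. = FALSE)
  if (length(reference_positive) != length(screen_odi)) {
    stop("reference and screen vectors differ in length", call. = FALSE)
  }
  if (anyNA(reference_positive) || anyNA(screen_odi)) {
    stop("missing values in pairs; exclude incomplete patients first",
         call. = FALSE)
  }
  sp <- screen_odi >= threshold
  contingency_2x2(
    a = sum(reference_positive & sp),
    b = sum(!reference_positive & sp),
    c = sum(reference_positive & !sp),
    d = sum(!reference_positive & !sp)
  )
}

#' McNemar test for paired 2x2 agreement
#'
#' Tests marginal homogeneity using only the discordant cells `b` and `c`.
#' The exact method doubles the binomial tail
#' `P(X <= min(b, c))` with `X ~ Binomial(b + c, 1/2)`, capped at 1; the
#' continuity-corrected method refers `(|b - c| - 1)^2 / (b + c)` to
#' chi-square with 1 df. The concordant cells `a` and `d` never affect the
#' p-value. With `b = c = 0` there is no discordance and the p-value is 1
#' (with a message).
#'
#' @param table A [contingency_2x2()].
#' @param method `"exact"` (default; appropriate for small discordant
#'   counts) or `"continuity_corrected"`.
#' @return The two-sided p-value.
#' @examples
#' mcnemar_test(contingency_2x2(3, 7, 4, 8))
#' @export
mcnemar_test <- function(table, method = c("exact", "continuity_corrected")) {
  stopifnot(inherits(table, "contingency_2x2"))
  method <- match.arg(method)
  b <- table$b; cc <- table$c
  nd <- b + cc
  if (nd == 0) {
    message("no discordant pairs (b = c = 0): p = 1")
    return(1)
  }
  if (method == "exact") {
    min(1, 2 * stats::pbinom(min(b, cc), nd, 0.5))
  } else {
    stat <- (abs(b - cc) - 1)^2 / nd
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

#' Diagnostic accuracy metrics of a 2x2 table
#'
#' Sensitivity `a/(a+c)`, specificity `d/(b+d)`, positive predictive value
#' `a/(a+b)` and negative predictive value `d/(c+d)`, as proportions in
#' `[0, 1]`. A metric whose denominator is zero is `NA` (undefined), never
#' coerced to 0. The McNemar p-value for the same table is included.
#'
#' @param table A [contingency_2x2()].
#' @param method McNemar method, passed to [mcnemar_test()].
#' @return An object of class `agreement_stats`: list with `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `mcnemar_p`, `method`, `table`.
#' @examples
#' diagnostic_metrics(contingency_2x2(3, 7, 4, 8))
#' @export
diagnostic_metrics <- function(table, method = c("exact", "continuity_corrected")) {
  stopifnot(inherits(table, "contingency_2x2"))
  method <- match.arg(method)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(
      sensitivity = ratio(table$a, table$a + table$c),
      specificity = ratio(table$d, table$b + table$d),
      ppv = ratio(table$a, table$a + table$b),
      npv = ratio(table$d, table$c + table$d),
      mcnemar_p = suppressMessages(mcnemar_test(table, method)),
      method = method,
      table = table
    ),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  pct <- function(p) if (is.na(p)) "undefined" else sprintf("%d%%", round_half_up(100 * p))
  cat(sprintf(paste0(
    "Paired diagnostic agreement (n = %d)\n",
    "  sensitivity %s, specificity %s\n",
    "  PPV %s, NPV %s\n",
    "  McNemar p = %.2f (%s)\n"),
    x$table$a + x$table$b + x$table$c + x$table$d,
    pct(x$sensitivity), pct(x$specificity), pct(x$ppv), pct(x$npv),
    x$mcnemar_p, x$method))
  invisible(x)
}

#' Sample size for the McNemar test
#'
#' Conditional normal-approximation sample size for a paired-proportions
#' design, parameterised by the discordant-pair probabilities: `psi` is the
#' ratio `p01/p10` (false positives to false negatives) and `pdisc` their
#' sum. Internally `p10 = pdisc/(psi+1)` and `p01 = psi*pdisc/(psi+1)`; the
#' required number of pairs is
#' \deqn{n = \left\lceil \frac{\left[z_{1-\alpha/2}\sqrt{p_{01}+p_{10}}
#'   + z_{1-\beta}\sqrt{p_{01}+p_{10}-(p_{01}-p_{10})^2}\right]^2}
#'   {(p_{01}-p_{10})^2} \right\rceil}
#'
#' @param alpha Two-sided significance level.
#' @param beta Type-II error (power = `1 - beta`).
#' @param psi Discordance ratio `p01/p10`, positive and not 1.
#' @param pdisc Total discordance probability `p01 + p10`, in `(0, 1]`.
#' @return Required number of pairs (integer).
#' @examples
#' mcnemar_sample_size(alpha = 0.05, beta = 0.20, psi = 12, pdisc = 0.39)
#' @export
mcnemar_sample_size <- function(alpha = 0.05, beta = 0.20, psi, pdisc) {
  if (!is.numeric(psi) || psi <= 0) stop("psi must be positive", call. = FALSE)
  if (psi == 1) {
    stop("psi = 1 means no marginal difference: required n is infinite",
         call. = FALSE)
  }
  if (!is.numeric(pdisc) || pdisc <= 0 || pdisc > 1) {
    stop("pdisc must lie in (0, 1]", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1) {
    stop("alpha and beta must lie in (0, 1)", call. = FALSE)
  }
  p10 <- pdisc / (psi + 1)
  p01 <- psi * pdisc / (psi + 1)
  diff <- p01 - p10
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(1 - beta)
  n <- (za * sqrt(pdisc) + zb * sqrt(pdisc - diff^2))^2 / diff^2
  as.integer(ceiling(n - 1e-9))
}

#' Bland-Altman agreement between two paired measurements
#'
#' Bias is the mean of the paired differences `x - y`; the limits of
#' agreement are `bias +/- 1.96 * SD` of the differences (sample SD, n-1
#' denominator). The plot data use the first measurement `x` as abscissa
#' and the difference `x - y` as ordinate (the first-night-vs-difference
#' variant used for night-to-night ODI reproducibility), rather than the
#' pairwise mean.
#'
#' @param x,y Numeric vectors of equal length >= 2 (e.g. first- and
#'   second-night ODI per patient).
#' @return An object of class `bland_altman`: list with `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `pairs`, and `plot_data` (`data.frame` with
#'   columns `x`, `diff`).
#' @examples
#' ba <- bland_altman(c(10, 20, 15, 8), c(12, 18, 15, 5))
#' ba$bias
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         sd_diff = s, pairs = length(x),
         plot_data = data.frame(x = x, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> %d pairs: bias %.2f, limits of agreement [%.2f, %.2f]\n",
              x$pairs, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "first measurement",
                              ylab = "difference (first - second)", ...) {
  graphics::plot(x$plot_data$x, x$plot_data$diff, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high),
                   lty = c(2, 1, 2), col = "grey40")
  invisible(x)
}

#' Median and interquartile range of paired differences
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7, the mainstream default), fixed as this
#' package's reporting convention.
#'
#' @param differences Nonempty numeric vector.
#' @return Named numeric vector `c(median, q25, q75)`.
#' @export
paired_median_iqr <- function(differences) {
  if (length(differences) == 0) stop("empty input", call. = FALSE)
  if (anyNA(differences)) stop("missing values in differences", call. = FALSE)
  q <- stats::quantile(differences, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q25 = q[2], q75 = q[3])
}
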