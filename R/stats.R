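## Statistical battery: contingency tests, t tests from raw data or
## summary statistics, Pearson correlation, and alpha/n-corrected
## pairwise comparisons.

new_lpd_test <- function(method, statistic = NA_real_, df = NA_real_,
                         p_value, estimate = NULL, alpha_effective = NA_real_,
                         note = NULL) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(min(p_value, 1)),
                 estimate = estimate, alpha_effective = alpha_effective,
                 note = note),
            class = "lpd_test")
}

#' @export
print.lpd_test <- function(x, ...) {
  cat(sprintf("<lpd_test> %s\n", x$method))
  if (!is.na(x$statistic))
    cat(sprintf("  statistic = %.6g%s\n", x$statistic,
                if (!is.na(x$df)) sprintf(", df = %.6g", x$df) else ""))
  if (!is.null(x$estimate))
    cat(sprintf("  estimate  = %.6g\n", x$estimate))
  cat(sprintf("  p value   = %s\n", format_p(x$p_value)))
  if (!is.na(x$alpha_effective))
    cat(sprintf("  corrected significance level = %.6g -> %s\n",
                x$alpha_effective,
                if (x$p_value < x$alpha_effective) "significant" else "not significant"))
  if (!is.null(x$note)) cat(sprintf("  note: %s\n", x$note))
  invisible(x)
}

as_count_matrix <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m)) || anyNA(m))
    stopf("contingency counts must be non-negative integers")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stopf("contingency table must be at least 2x2")
  storage.mode(m) <- "double"
  m
}

#' Pearson chi-square test of independence
#'
#' Pearson's chi-square without continuity correction by default, with
#' df = (r-1)(c-1) and a two-sided p-value from the chi-square
#' distribution. The uncorrected statistic is the package default because
#' it reproduces the reference cohort's printed sex and laterality
#' p-values; the Yates-corrected variant is available for 2x2 tables via
#' `correct = TRUE`.
#'
#' @param counts Contingency table of non-negative integer counts, at
#'   least 2x2.
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @return An `lpd_test` with the statistic, df and p-value.
#' @examples
#' chi2_test(matrix(c(28, 26, 9, 34), nrow = 2, byrow = TRUE))
#' @export
chi2_test <- function(counts, correct = FALSE) {
  m <- as_count_matrix(counts)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stopf(paste("chi-square is undefined for a table with a zero margin;",
                "consider fisher_exact_test()"))
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  new_lpd_test("pearson_chi2", statistic = ct$statistic, df = ct$parameter,
               p_value = ct$p.value)
}

## p-values for every possible first cell given fixed 2x2 margins:
## margins (m = row-1 total, n = row-2 total, k = column-1 total).
## Two-tailed p for observed a = sum of hypergeometric probabilities not
## exceeding the observed table's probability (with a relative tolerance
## for ties, as is conventional).
fisher_p_all <- function(m, n, k, tol = 1e-7) {
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  pr <- dhyper(support, m, n, k)
  vapply(seq_along(support),
         function(i) min(1, sum(pr[pr <= pr[i] * (1 + tol)])),
         numeric(1))
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Computes the exact two-tailed p-value by summing, over all 2x2 tables
#' with the observed margins, the hypergeometric probabilities that do not
#' exceed the probability of the observed table (the standard two-tailed
#' definition). Tables with a zero margin admit a single configuration and
#' return p = 1.
#'
#' @param counts A 2x2 table of non-negative integer counts.
#' @return An `lpd_test` with the p-value and, as `estimate`, the sample
#'   odds ratio (cross-product; `Inf`/`NaN` possible with zero cells).
#' @examples
#' fisher_exact_test(matrix(c(1, 53, 1, 27), nrow = 2, byrow = TRUE))
#' @export
fisher_exact_test <- function(counts) {
  m <- as_count_matrix(counts)
  if (nrow(m) != 2L || ncol(m) != 2L)
    stopf("fisher_exact_test() requires a 2x2 table (got %dx%d)",
          nrow(m), ncol(m))
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  a <- m[1, 1]
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2]) == 0) {
    p <- 1
  } else {
    lo <- max(0, c1 - r2)
    p <- fisher_p_all(r1, r2, c1)[a - lo + 1]
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  new_lpd_test("fisher_exact", p_value = p, estimate = unname(or))
}

#' Group summary statistics
#'
#' Container for a group's sample size, mean and standard deviation, as
#' printed in clinical summary tables ("mean +/- standard deviation").
#'
#' @param n Sample size (>= 2).
#' @param mean Sample mean.
#' @param sd Sample standard deviation (>= 0).
#' @return A `summary_stats` list.
#' @export
summary_stats <- function(n, mean, sd) {
  if (n < 2) stopf("summary statistics require n >= 2")
  if (sd < 0) stopf("sd must be non-negative")
  structure(list(n = n, mean = mean, sd = sd), class = "summary_stats")
}

as_summary <- function(x) {
  if (inherits(x, "summary_stats")) return(x)
  if (is.numeric(x) && length(x) >= 2)
    return(summary_stats(length(x), mean(x), sd(x)))
  if (is.list(x) && all(c("n", "mean", "sd") %in% names(x)))
    return(summary_stats(x$n, x$mean, x$sd))
  stopf("cannot interpret input as a sample or as summary statistics")
}

#' Two-sample t test from summary statistics
#'
#' Unpaired two-sided t test computed directly from each group's (n, mean,
#' sd). The `student` variant pools the variances with
#' df = n_a + n_b - 2; the `welch` variant uses the Welch-Satterthwaite
#' approximation. This is the path used to test printed summary tables,
#' where raw values are unavailable.
#'
#' @param a,b `summary_stats` objects (or lists with `n`, `mean`, `sd`).
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return An `lpd_test`.
#' @examples
#' t_test_from_summary(summary_stats(54, 55.92, 12.85),
#'                     summary_stats(43, 64.95, 12.16))
#' @export
t_test_from_summary <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as_summary(a); b <- as_summary(b)
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean)
    stopf("t statistic undefined: both groups have zero variance and equal means")
  if (variant == "student") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    method <- "student_t"
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    method <- "welch_t"
  }
  if (se == 0)
    stopf("t statistic undefined: zero standard error")
  t <- (a$mean - b$mean) / se
  new_lpd_test(method, statistic = t, df = df,
               p_value = 2 * pt(-abs(t), df),
               estimate = a$mean - b$mean)
}

#' Two-sample t test from raw values
#'
#' Unpaired two-sided t test on raw samples. Exactly equivalent to
#' [t_test_from_summary()] applied to the samples' computed summary
#' statistics; internally delegates to [stats::t.test()], which provides
#' an independent implementation of the same formulas.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return An `lpd_test`.
#' @export
t_test_from_raw <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2)
    stopf("each group needs at least two observations")
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
    stopf("t statistic undefined: both groups constant and equal")
  tt <- stats::t.test(x, y, var.equal = (variant == "student"))
  new_lpd_test(if (variant == "student") "student_t" else "welch_t",
               statistic = tt$statistic, df = tt$parameter,
               p_value = tt$p.value, estimate = mean(x) - mean(y))
}

#' Pearson correlation test
#'
#' Pearson's r with the usual two-sided p-value from the t transform with
#' n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return An `lpd_test`; `estimate` holds r.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("correlation requires at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stopf("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  new_lpd_test("pearson_correlation", statistic = ct$statistic,
               df = ct$parameter, p_value = ct$p.value,
               estimate = unname(ct$estimate))
}

#' One-way ANOVA from summary statistics
#'
#' F test for equality of group means computed from per-group (n, mean,
#' sd), used for the overall comparison of a numeric row in a summary
#' table.
#'
#' @param summaries List of `summary_stats` (>= 2 groups).
#' @return An `lpd_test` with the F statistic; `df` holds the numerator
#'   df and `note` records the denominator df.
#' @export
anova_from_summary <- function(summaries) {
  summaries <- lapply(summaries, as_summary)
  k <- length(summaries)
  if (k < 2) stopf("ANOVA needs at least 2 groups")
  n <- vapply(summaries, `[[`, numeric(1), "n")
  m <- vapply(summaries, `[[`, numeric(1), "mean")
  s <- vapply(summaries, `[[`, numeric(1), "sd")
  N <- sum(n)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- k - 1; df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  new_lpd_test("anova_lsd", statistic = f, df = df1,
               p_value = pf(f, df1, df2, lower.tail = FALSE),
               note = sprintf("denominator df = %d", df2))
}

#' Pairwise LSD (least-significant-difference) tests
#'
#' Fisher's LSD post hoc: every pairwise comparison is a pooled t test
#' whose variance is the one-way ANOVA residual mean square over all
#' groups, with the residual degrees of freedom.
#'
#' @param summaries Named list of `summary_stats` (or raw numeric
#'   samples), one per group.
#' @return Named list of `lpd_test` objects, one per group pair
#'   (`"A vs B"`).
#' @export
lsd_pairwise <- function(summaries) {
  summaries <- lapply(summaries, as_summary)
  k <- length(summaries)
  if (k < 2) stopf("need at least 2 groups")
  n <- vapply(summaries, `[[`, numeric(1), "n")
  s <- vapply(summaries, `[[`, numeric(1), "sd")
  m <- vapply(summaries, `[[`, numeric(1), "mean")
  df2 <- sum(n) - k
  msw <- sum((n - 1) * s^2) / df2
  pairs <- combn(seq_len(k), 2, simplify = FALSE)
  out <- lapply(pairs, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(msw * (1 / n[i] + 1 / n[j]))
    t <- (m[i] - m[j]) / se
    new_lpd_test("anova_lsd", statistic = t, df = df2,
                 p_value = 2 * pt(-abs(t), df2), estimate = m[i] - m[j])
  })
  names(out) <- vapply(pairs, function(ij)
    paste(names(summaries)[ij], collapse = " vs "), character(1))
  out
}

#' All pairwise comparisons at the alpha/n corrected level
#'
#' Runs the chosen two-group test on every pair of groups and attaches to
#' each result the corrected significance level alpha / n, where n is the
#' number of pairwise comparisons (for three groups, alpha/3): a
#' comparison is flagged significant only when p < alpha/n.
#'
#' @param groups Named list with one element per group: numeric samples or
#'   `summary_stats` for the t variants; rows of counts (numeric vectors
#'   of per-level counts) for `"chi2"` / `"fisher"`.
#' @param test `"student_t"`, `"welch_t"`, `"chi2"`, or `"fisher"`.
#' @param alpha Nominal significance level (default 0.05).
#' @return Named list of `lpd_test` objects with `alpha_effective` set.
#' @examples
#' pairwise_with_correction(
#'   list(RFH = c(28, 26), ALH = c(9, 19), MALToma = c(9, 34)),
#'   test = "chi2")
#' @export
pairwise_with_correction <- function(groups,
                                     test = c("student_t", "welch_t",
                                              "chi2", "fisher"),
                                     alpha = 0.05) {
  test <- match.arg(test)
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  pairs <- combn(seq_along(groups), 2, simplify = FALSE)
  alpha_eff <- alpha / length(pairs)
  out <- lapply(pairs, function(ij) {
    a <- groups[[ij[1]]]; b <- groups[[ij[2]]]
    res <- switch(test,
      student_t = t_test_from_summary(as_summary(a), as_summary(b), "student"),
      welch_t   = t_test_from_summary(as_summary(a), as_summary(b), "welch"),
      chi2      = chi2_test(rbind(a, b)),
      fisher    = fisher_exact_test(rbind(a, b)))
    res$alpha_effective <- alpha_eff
    res
  })
  names(out) <- vapply(pairs, function(ij)
    paste(names(groups)[ij], collapse = " vs "), character(1))
  out
}
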