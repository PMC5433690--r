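random_table <- function(nr = 2, nc = 2, max_n = 30) {
  matrix(sample(0:max_n, nr * nc, replace = TRUE), nr, nc)
}

test_that("chi-square reproduces independence and rejects zero margins", {
  res <- chi2_test(matrix(c(10, 10, 20, 20), 2, byrow = TRUE))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1)
  expect_error(chi2_test(matrix(c(0, 0, 5, 7), 2, byrow = TRUE)),
               "fisher_exact_test")
  expect_error(chi2_test(matrix(c(1.5, 2, 3, 4), 2)), "non-negative integers")
  # 3x2 df = 2
  expect_equal(chi2_test(matrix(c(22, 32, 4, 24, 5, 38), 3, byrow = TRUE))$df, 2)
})

test_that("contingency tests are invariant under row/column permutation", {
  set.seed(77)
  for (i in 1:20) {
    m <- random_table(2, 2) + 1   # avoid zero margins
    pc <- chi2_test(m)$p_value
    pf_ <- fisher_exact_test(m)$p_value
    for (perm in list(m[2:1, ], m[, 2:1], m[2:1, 2:1])) {
      expect_equal(chi2_test(perm)$p_value, pc)
      expect_equal(fisher_exact_test(perm)$p_value, pf_)
    }
  }
  m <- matrix(sample(1:20, 6), 3, 2)
  expect_equal(chi2_test(m[c(2, 3, 1), ])$p_value, chi2_test(m)$p_value)
})

test_that("Fisher exact matches hypergeometric enumeration and the reference implementation", {
  # symmetric table
  expect_equal(fisher_exact_test(matrix(5, 2, 2))$p_value, 1)
  # degenerate: zero margin admits a single table
  expect_equal(fisher_exact_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$p_value, 1)

  # brute-force oracle: enumerate all tables with the observed margins via
  # binomial coefficients and sum probabilities <= the observed one
  fisher_oracle <- function(m) {
    r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); N <- sum(m)
    supp <- max(0, c1 - r2):min(c1, r1)
    pr <- choose(r1, supp) * choose(r2, c1 - supp) / choose(N, c1)
    obs <- pr[supp == m[1, 1]]
    min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  }
  anti <- matrix(c(0, 10, 10, 0), 2, byrow = TRUE)
  expect_equal(fisher_exact_test(anti)$p_value, fisher_oracle(anti))
  # the antidiagonal table attains the smallest two-tailed p for its margins
  ps <- sapply(0:10, function(a)
    fisher_exact_test(matrix(c(a, 10 - a, 10 - a, a), 2, byrow = TRUE))$p_value)
  expect_equal(fisher_exact_test(anti)$p_value, min(ps))

  set.seed(90)
  for (i in 1:50) {
    m <- random_table(2, 2, max_n = 15)
    if (sum(m) == 0) next
    p <- fisher_exact_test(m)$p_value
    expect_equal(p, fisher_oracle(m))
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-10)
  }
  expect_error(fisher_exact_test(matrix(1, 3, 2)), "2x2")
})

test_that("summary-statistic t tests implement pooled and Welch formulas", {
  a <- summary_stats(54, 55.92, 12.85)
  b <- summary_stats(43, 64.95, 12.16)
  res <- t_test_from_summary(a, b)
  expect_equal(res$df, 95)
  expect_lt(res$p_value, 0.001)

  same <- t_test_from_summary(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  w <- t_test_from_summary(a, b, variant = "welch")
  expect_equal(w$method, "welch_t")
  expect_lt(w$df, 95)

  expect_error(t_test_from_summary(summary_stats(5, 1, 0), summary_stats(5, 1, 0)),
               "zero variance")
  expect_error(summary_stats(1, 0, 1), "n >= 2")
})

test_that("raw-data and summary-statistic t paths agree exactly", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  expect_equal(t_test_from_raw(x, y)$p_value, 1)
  expect_equal(t_test_from_raw(x, y)$statistic,
               t_test_from_summary(summary_stats(3, mean(x), sd(x)),
                                   summary_stats(3, mean(y), sd(y)))$statistic)
  set.seed(14)
  for (variant in c("student", "welch")) {
    for (i in 1:10) {
      x <- rnorm(sample(5:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
      y <- rnorm(sample(5:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
      raw <- t_test_from_raw(x, y, variant)
      summ <- t_test_from_summary(
        summary_stats(length(x), mean(x), sd(x)),
        summary_stats(length(y), mean(y), sd(y)), variant)
      expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
      expect_equal(raw$df, summ$df, tolerance = 1e-12)
      expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
    }
  }
  expect_error(t_test_from_raw(1, c(1, 2)), "at least two")
})

test_that("Pearson correlation matches the definition and its invariances", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_correlation(x, -x)$estimate, -1)

  set.seed(8)
  y <- 0.6 * x + rnorm(10)
  res <- pearson_correlation(x, y)
  # from-definition oracle
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, r_def, tolerance = 1e-12)
  t_def <- r_def * sqrt(8 / (1 - r_def^2))
  expect_equal(res$p_value, 2 * pt(-abs(t_def), 8), tolerance = 1e-12)

  # invariant under positive affine transforms; sign flips under negation
  expect_equal(pearson_correlation(3 * x + 2, y)$estimate, res$estimate)
  expect_equal(pearson_correlation(x, 0.1 * y - 7)$estimate, res$estimate)
  expect_equal(pearson_correlation(-x, y)$estimate, -res$estimate)

  expect_error(pearson_correlation(x, rep(1, 10)), "zero variance")
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
})

test_that("summary ANOVA and LSD pairwise agree with aov on raw data", {
  set.seed(21)
  g <- list(a = rnorm(12, 0), b = rnorm(9, 0.8), c = rnorm(15, -0.4))
  sums <- lapply(g, function(v) summary_stats(length(v), mean(v), sd(v)))
  res <- anova_from_summary(sums)
  raw <- data.frame(y = unlist(g), grp = rep(names(g), lengths(g)))
  fit <- anova(aov(y ~ grp, data = raw))
  expect_equal(res$statistic, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, fit$`Pr(>F)`[1], tolerance = 1e-10)

  lsd <- lsd_pairwise(sums)
  expect_named(lsd, c("a vs b", "a vs c", "b vs c"))
  # oracle: pooled-t with the ANOVA residual mean square
  msw <- fit$`Mean Sq`[2]
  t_ab <- (mean(g$a) - mean(g$b)) / sqrt(msw * (1 / 12 + 1 / 9))
  expect_equal(lsd$`a vs b`$statistic, t_ab, tolerance = 1e-10)
  expect_equal(lsd$`a vs b`$df, fit$Df[2])
})

test_that("pairwise comparisons carry the alpha/n corrected level", {
  g3 <- list(RFH = c(28, 26), ALH = c(9, 19), MALToma = c(9, 34))
  res <- pairwise_with_correction(g3, test = "chi2")
  expect_length(res, 3)
  expect_equal(res[[1]]$alpha_effective, 0.05 / 3, tolerance = 1e-12)
  expect_named(res, c("RFH vs ALH", "RFH vs MALToma", "ALH vs MALToma"))
  expect_equal(res[["RFH vs MALToma"]]$p_value, 0.002, tolerance = 0.1)

  g2 <- g3[1:2]
  expect_equal(pairwise_with_correction(g2, test = "fisher")[[1]]$alpha_effective,
               0.05)
  g4 <- c(g3, list(extra = c(10, 10)))
  res4 <- pairwise_with_correction(g4, test = "chi2")
  expect_length(res4, 6)
  expect_equal(res4[[1]]$alpha_effective, 0.05 / 6)

  set.seed(3)
  gt <- list(a = rnorm(10), b = rnorm(12), c = rnorm(8))
  rest <- pairwise_with_correction(gt, test = "student_t")
  expect_equal(rest[["a vs b"]]$p_value,
               t_test_from_raw(gt$a, gt$b)$p_value, tolerance = 1e-12)

  expect_error(pairwise_with_correction(list(a = 1:3)), "at least 2")
})
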