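test_that("mean positive rate is the five-field average with strict validation", {
  expect_equal(mean_positive_rate(c(55, 60, 50, 45, 65)), 55)
  expect_equal(mean_positive_rate(rep(0, 5)), 0)
  expect_equal(mean_positive_rate(rep(100, 5)), 100)
  expect_error(mean_positive_rate(c(10, 20, 30, 40)), "five high-power-field")
  expect_error(mean_positive_rate(c(10, 20, 30, 40, NA)), "five high-power-field")
  expect_error(mean_positive_rate(c(10, 20, 30, 40, 101)), "\\[0, 100\\]")
})

test_that("scorer concordance uses a strict 5-point absolute bound", {
  expect_equal(scorer_concordance(20, 24), "concordant")
  expect_equal(scorer_concordance(20, 26), "discordant")
  expect_equal(scorer_concordance(20, 25), "discordant")  # |diff| = 5 is out
  for (x in c(0, 3.7, 50, 100))
    expect_equal(scorer_concordance(x, x), "concordant")
  expect_error(scorer_concordance(-1, 10), "\\[0, 100\\]")
})

test_that("expression score matches the published rubric bins", {
  expect_equal(expression_score(0), 0L)
  expect_equal(expression_score(15), 2L)
  expect_equal(expression_score(25), 3L)
  expect_equal(expression_score(0.5), 1L)  # continuous-bin reading
  expect_equal(expression_score(c(10, 10.5, 20, 20.5, 100)),
               c(1L, 2L, 2L, 3L, 3L))
  expect_error(expression_score(-1), "\\[0, 100\\]")
  expect_error(expression_score(100.5), "\\[0, 100\\]")
})

test_that("expression score equals a brute-force bin lookup and is monotone", {
  # independent oracle: explicit bin table searched row by row
  bins <- data.frame(score = 0:3, lower = c(-Inf, 0, 10, 20),
                     upper = c(0, 10, 20, Inf))
  oracle <- function(rate)
    bins$score[which(rate > bins$lower & rate <= bins$upper)[1]]
  grid <- seq(0, 100, by = 0.5)
  got <- expression_score(grid)
  expect_equal(got, vapply(grid, oracle, numeric(1)))
  expect_true(all(diff(got) >= 0))
})

test_that("LF score maps categories and rubric descriptions", {
  expect_equal(lf_score(0:3), 0:3)
  expect_equal(lf_score("No staining or few scattered positively stained cells"), 0L)
  expect_equal(lf_score("Some intact lymphoid follicles and scattered FDC/MZ fragments"), 2L)
  expect_equal(
    lf_score("Most lymphoid follicles are intact, accompanied by some disrupted fragments"),
    3L)
  expect_error(lf_score(4), "0, 1, 2, 3")
  expect_error(lf_score("follicles everywhere"), "unknown lymphoid-follicle")
})

test_that("combination score panels follow expression + LF with the mean combiner", {
  p <- combination_score(25, 25, 3)
  expect_equal(unlist(p), c(cd23_score = 3, igd_score = 3, expression_score = 3,
                            lf_score = 3, combination_score = 6))
  p <- combination_score(0, 0, 0)
  expect_equal(p$combination_score, 0)
  p <- combination_score(15, 5, 1)
  expect_equal(unlist(p), c(cd23_score = 2, igd_score = 1, expression_score = 1.5,
                            lf_score = 1, combination_score = 2.5))
  expect_equal(combination_score(15, 5, 1, combiner = "min")$expression_score, 1)
  expect_equal(combination_score(15, 5, 1, combiner = "max")$expression_score, 2)
  expect_equal(combination_score(15, 5, 1, combiner = "sum")$combination_score, 4)
})

test_that("combination score is bounded, zero only at the null panel, monotone", {
  set.seed(401)
  rates <- c(0, 0.5, runif(40, 0, 100), 100)
  for (lf in 0:3) {
    p <- combination_score(sample(rates), sample(rates), lf)
    expect_true(all(p$combination_score >= 0 & p$combination_score <= 6))
    zero <- p$combination_score == 0
    expect_equal(zero, p$cd23_score == 0 & p$igd_score == 0 & lf == 0)
  }
  # monotone in each argument, others held fixed
  grid <- seq(0, 100, by = 2.5)
  expect_true(all(diff(combination_score(grid, 15, 2)$combination_score) >= 0))
  expect_true(all(diff(combination_score(15, grid, 2)$combination_score) >= 0))
  expect_true(all(diff(combination_score(15, 15, 0:3)$combination_score) >= 0))
})

test_that("cohort scoring averages scorers, flags discordance, keeps NA absent", {
  df <- make_cohort_df(3)
  # record 2: scorer B differs by 6 points on cd23 -> discordant
  df[2, paste0("cd23_hpf", 1:5, "_b")] <- df[2, paste0("cd23_hpf", 1:5)] + 6
  # record 3: no scorer B at all, no LF category
  df[3, paste0("cd23_hpf", 1:5, "_b")] <- NA_real_
  df[3, paste0("igd_hpf", 1:5, "_b")] <- NA_real_
  df$lf_category[3] <- NA_real_
  sc <- score_cohort(as_lpd_cohort(df))

  rate_a <- mean(unlist(df[1, paste0("cd23_hpf", 1:5)]))
  rate_b <- mean(unlist(df[1, paste0("cd23_hpf", 1:5, "_b")]))
  expect_equal(sc$cd23_rate[1], (rate_a + rate_b) / 2)
  expect_true(sc$scorer_concordant[1])
  expect_false(sc$scorer_concordant[2])
  expect_equal(sc$cd23_rate[3], rate_a)   # scorer A alone
  expect_true(is.na(sc$lf_score[3]) && is.na(sc$combination_score[3]))

  # deterministic and order-independent
  sc2 <- score_cohort(as_lpd_cohort(df[3:1, ]))
  expect_equal(sc2$combination_score, rev(sc$combination_score))
})
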