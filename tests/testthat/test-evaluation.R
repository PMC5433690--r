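test_that("classifier bands are half-open with boundaries in the lower band", {
  spec <- classifier_spec(c(2, 4.5))
  expect_equal(classify(0, spec), "MALToma")
  expect_equal(classify(2, spec), "MALToma")    # boundary -> lower band
  expect_equal(classify(2.01, spec), "ALH")
  expect_equal(classify(4.5, spec), "ALH")
  expect_equal(classify(6, spec), "RFH")
  expect_equal(classify(c(1, 3, 5), spec), c("MALToma", "ALH", "RFH"))
  expect_error(classifier_spec(c(4, 2)), "strictly increasing")
  expect_error(classifier_spec(c(2, 7)), "max_score")
})

test_that("sensitivity arithmetic reproduces the printed percentages", {
  expect_equal(round(sensitivity_from_counts(18, 21), 1), 85.7)
  expect_equal(round(sensitivity_from_counts(6, 17), 1), 35.3)
  for (n in c(1, 7, 21)) expect_equal(sensitivity_from_counts(0, n), 0)
  expect_equal(sensitivity_from_counts(17, 17), 100)
  expect_error(sensitivity_from_counts(1, 0), "positive")
  expect_error(sensitivity_from_counts(5, 4), "n_tested")
})

test_that("threshold fitting separates a separable cohort perfectly", {
  sc <- make_separable_scored()
  spec <- fit_thresholds(sc)
  expect_equal(attr(spec, "balanced_accuracy"), 1)
  expect_equal(classify(0, spec), "MALToma")
  expect_equal(classify(3, spec), "ALH")
  expect_equal(classify(6, spec), "RFH")
  # tie-break: widest MALToma-like band, then widest ALH-like band
  expect_equal(spec$cuts, c(2.5, 5.5))
})

test_that("threshold fitting matches an independent exhaustive oracle", {
  set.seed(55)
  n <- 60
  sc <- data.frame(
    diagnosis = sample(c("RFH", "ALH", "MALToma"), n, replace = TRUE),
    combination_score = sample(seq(0, 6, 0.5), n, replace = TRUE))
  spec <- fit_thresholds(sc)

  # oracle: naive double loop over the same grid, recomputing balanced
  # accuracy from scratch and applying the documented tie-break
  grid <- seq(0, 5.5, by = 0.5)
  best <- NULL; best_ba <- -1
  for (c1 in grid) for (c2 in grid) {
    if (c2 <= c1) next
    pred <- ifelse(sc$combination_score <= c1, "MALToma",
                   ifelse(sc$combination_score <= c2, "ALH", "RFH"))
    recalls <- sapply(c("MALToma", "ALH", "RFH"), function(g)
      mean(pred[sc$diagnosis == g] == g))
    ba <- mean(recalls)
    if (ba > best_ba + 1e-12 ||
        (abs(ba - best_ba) <= 1e-12 &&
         (c1 > best[1] || (c1 == best[1] && c2 > best[2])))) {
      best <- c(c1, c2); best_ba <- ba
    }
  }
  expect_equal(spec$cuts, best)
  expect_equal(attr(spec, "balanced_accuracy"), best_ba, tolerance = 1e-12)
})

test_that("degenerate threshold fits are flagged", {
  sc <- data.frame(diagnosis = rep(c("RFH", "ALH"), each = 4),
                   combination_score = rep(3, 8))
  expect_warning(spec <- fit_thresholds(sc), "identical")
  expect_s3_class(spec, "classifier_spec")
  expect_error(fit_thresholds(data.frame(diagnosis = "RFH",
                                         combination_score = 1)),
               "two diagnosis classes")
})

test_that("widening the positive band never decreases sensitivity", {
  set.seed(9)
  sc <- data.frame(
    diagnosis = rep("MALToma", 40),
    combination_score = sample(seq(0, 6, 0.5), 40, replace = TRUE),
    igh_result = sample(c("clonal", "polyclonal"), 40, replace = TRUE))
  cuts1 <- seq(0.5, 5, by = 0.5)
  sens <- vapply(cuts1, function(c1) {
    ev <- evaluate_against_clonality(sc, classifier_spec(c(c1, 5.5)))
    ev$per_group$sensitivity_percent
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("clonality evaluation excludes uninformative records and tallies correctly", {
  sc <- make_separable_scored(n = 7)
  # add records that must never enter any denominator
  extra <- data.frame(diagnosis = c("MALToma", "ALH", "RFH"),
                      combination_score = c(0, 3, 6),
                      igh_result = c("qc_failed", "not_tested", NA),
                      patient_id = c("X-1", "X-2", "X-3"))
  spec <- classifier_spec(c(1.5, 4.5))
  ev <- evaluate_against_clonality(rbind(sc, extra), spec)
  base <- evaluate_against_clonality(sc, spec)
  expect_equal(ev$per_group, base$per_group)
  expect_equal(ev$n_evaluable, nrow(sc))

  # brute-force per-record tally oracle
  rule <- list(MALToma = "MALToma", ALH = c("MALToma", "ALH"), RFH = "RFH")
  for (g in c("RFH", "ALH", "MALToma")) {
    sub <- sc[sc$diagnosis == g & sc$igh_result %in% c("clonal", "polyclonal"), ]
    n_pos <- 0L
    for (i in seq_len(nrow(sub))) {
      cls <- if (sub$combination_score[i] <= 1.5) "MALToma"
             else if (sub$combination_score[i] <= 4.5) "ALH" else "RFH"
      if (cls %in% rule[[g]]) n_pos <- n_pos + 1L
    }
    row <- ev$per_group[ev$per_group$group == g, ]
    expect_equal(row$n_positive, n_pos)
    expect_equal(row$n_tested, nrow(sub))
    expect_equal(row$n_clonal, sum(sub$igh_result == "clonal"))
    expect_equal(row$sensitivity_percent, 100 * n_pos / nrow(sub))
  }

  # a cohort where every MALToma case sits in the lowest band
  all_pos <- data.frame(diagnosis = "MALToma", combination_score = rep(0.5, 6),
                        igh_result = rep(c("clonal", "polyclonal"), 3))
  ev2 <- evaluate_against_clonality(all_pos, spec)
  expect_equal(ev2$per_group$sensitivity_percent, 100)

  expect_error(
    evaluate_against_clonality(
      data.frame(diagnosis = "ALH", combination_score = 1,
                 igh_result = "qc_failed"), spec),
    "no evaluable")
})

test_that("synthetic clonality counts flow through evaluation unchanged", {
  co <- generate_cohort(generator_config(seed = 31))
  sc <- score_cohort(co)
  ev <- evaluate_against_clonality(sc, classifier_spec(c(1.5, 4)))
  df <- as.data.frame(sc)
  for (g in ev$per_group$group) {
    idx <- df$diagnosis == g & df$igh_result %in% c("clonal", "polyclonal") &
      !is.na(df$combination_score)
    expect_equal(ev$per_group$n_clonal[ev$per_group$group == g],
                 sum(df$igh_result[idx] == "clonal"))
  }
})
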