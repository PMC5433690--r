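## Clinical-features summary: counts, percentages, and the test battery
## laid out as in the published cohort table.

expected_counts <- function(m) outer(rowSums(m), colSums(m)) / sum(m)

## auto method selection for a counts matrix: exact test when any expected
## cell is below 5, else Pearson chi-square ("as appropriate")
categorical_test <- function(m, method = "auto", chi2_correct = FALSE,
                             alpha_effective = NA_real_) {
  m <- as_count_matrix(m)
  zero_margin <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  if (method == "auto")
    method <- if (zero_margin || any(expected_counts(m) < 5)) "fisher" else "chi2"
  res <- if (method == "chi2") {
    chi2_test(m, correct = chi2_correct)
  } else if (nrow(m) == 2L && ncol(m) == 2L) {
    fisher_exact_test(m)
  } else {
    ## exact test on an RxC table: delegate to the network algorithm
    p <- if (zero_margin) 1 else stats::fisher.test(m)$p.value
    new_lpd_test("fisher_exact", p_value = p)
  }
  res$alpha_effective <- alpha_effective
  res
}

test_row <- function(variable, level, comparison, res) {
  data.frame(variable = variable, level = level, comparison = comparison,
             method = res$method, statistic = res$statistic %||% NA_real_,
             p = res$p_value, alpha_effective = res$alpha_effective,
             significant = if (is.na(res$alpha_effective)) NA
                           else res$p_value < res$alpha_effective,
             stringsAsFactors = FALSE)
}

#' Summarise a count structure as a clinical-features report
#'
#' Produces the cohort-table-shaped report from an `lpd_counts` structure
#' (packaged reference counts or counts derived from a cohort): per-group
#' counts with percentages recomputed against group size, age summaries,
#' the overall test across all groups, and all pairwise tests at the
#' alpha/n corrected level (alpha/3 for three groups).
#'
#' Test selection per categorical row follows the "as appropriate" rule:
#' Pearson chi-square without continuity correction unless any expected
#' cell count is below 5, in which case the two-tailed Fisher exact test
#' is used. Age rows use the pooled-variance Student t from the printed
#' summary statistics (Welch via `t_variant`); the overall age comparison
#' is a one-way ANOVA from summaries.
#'
#' @param x An `lpd_counts` structure, e.g. [reference_counts()] or the
#'   `counts` computed by [summarize_cohort()].
#' @param alpha Nominal significance level (default 0.05).
#' @param correction `"bonferroni_pairs"` (default: pairwise significance
#'   is judged against alpha divided by the number of pairs) or `"none"`.
#' @param chi2_correct Apply the Yates continuity correction in 2x2
#'   chi-square tests (default `FALSE`).
#' @param t_variant `"student"` (default) or `"welch"` for numeric rows.
#' @param method Per-row categorical test: `"auto"` (default), `"chi2"`,
#'   or `"fisher"`.
#' @return A `cohort_summary` list with data-frame elements `categorical`
#'   (variable, level, group, count, n, percent), `numeric` (age
#'   summaries), `tests` (one row per overall/pairwise test), `overall`
#'   (whole-cohort percentages), and `notes`.
#' @examples
#' s <- summarize_counts(reference_counts())
#' subset(s$categorical, variable == "sex" & level == "female")
#' @export
summarize_counts <- function(x, alpha = 0.05,
                             correction = c("bonferroni_pairs", "none"),
                             chi2_correct = FALSE,
                             t_variant = c("student", "welch"),
                             method = c("auto", "chi2", "fisher")) {
  stopifnot(inherits(x, "lpd_counts"))
  correction <- match.arg(correction)
  t_variant <- match.arg(t_variant)
  method <- match.arg(method)

  groups <- names(x$groups)
  nonempty <- groups[x$groups > 0]
  pairs <- if (length(nonempty) >= 2) combn(nonempty, 2, simplify = FALSE) else list()
  alpha_eff <- if (correction == "bonferroni_pairs" && length(pairs) > 0)
    alpha / length(pairs) else alpha
  notes <- character(0)
  if (length(setdiff(groups, nonempty)) > 0)
    notes <- c(notes, sprintf("empty group(s) excluded from tests: %s",
                              paste(setdiff(groups, nonempty), collapse = ", ")))

  cat_rows <- list(); test_rows <- list()

  add_tests <- function(variable, level, tab) {
    ## tab: groups x levels counts for the overall test; rows of `nonempty`
    rows <- list()
    run <- function(m, comparison, a_eff) {
      res <- tryCatch(categorical_test(m, method, chi2_correct, a_eff),
                      error = function(e) NULL)
      if (is.null(res)) {
        notes <<- c(notes, sprintf("%s/%s [%s]: test skipped (degenerate table)",
                                   variable, level, comparison))
        return(NULL)
      }
      test_row(variable, level, comparison, res)
    }
    if (length(nonempty) >= 2)
      rows <- c(rows, list(run(tab[nonempty, , drop = FALSE], "overall", NA_real_)))
    for (pr in pairs)
      rows <- c(rows, list(run(tab[pr, , drop = FALSE],
                               paste(pr, collapse = " vs "), alpha_eff)))
    rows
  }

  ## mutually exclusive variables: the level table is the variable itself
  for (v in intersect(c("sex", "laterality"), names(x$categorical))) {
    m <- x$categorical[[v]]
    for (lv in colnames(m))
      cat_rows <- c(cat_rows, list(data.frame(
        variable = v, level = lv, group = groups,
        count = m[groups, lv], n = unname(x$groups[groups]),
        percent = 100 * m[groups, lv] / unname(x$groups[groups]),
        stringsAsFactors = FALSE)))
    test_rows <- c(test_rows, add_tests(v, "(all)", m))
  }

  ## binary involvement variables: one yes/no table per level
  for (v in intersect(c("site", "symptom"), names(x$categorical))) {
    m <- x$categorical[[v]]
    for (lv in colnames(m)) {
      yes <- m[groups, lv]
      tab <- cbind(yes = yes, no = unname(x$groups[groups]) - yes)
      rownames(tab) <- groups
      cat_rows <- c(cat_rows, list(data.frame(
        variable = v, level = lv, group = groups, count = yes,
        n = unname(x$groups[groups]),
        percent = 100 * yes / unname(x$groups[groups]),
        stringsAsFactors = FALSE)))
      test_rows <- c(test_rows, add_tests(v, lv, tab))
    }
  }

  ## clonality bookkeeping (no tests: the gold standard, not a comparison)
  if ("clonality" %in% names(x$categorical)) {
    m <- x$categorical[["clonality"]]
    cat_rows <- c(cat_rows, list(data.frame(
      variable = "clonality", level = "clonal", group = groups,
      count = m[groups, "clonal"], n = m[groups, "tested"],
      percent = 100 * m[groups, "clonal"] / m[groups, "tested"],
      stringsAsFactors = FALSE)))
  }

  ## numeric rows: age (and duration when summary moments are available)
  numeric_vars <- list(age = x$age)
  if (!is.null(x$duration) && all(c("mean", "sd") %in% names(x$duration))) {
    dur <- x$duration
    dur$n <- x$groups[dur$group]
    numeric_vars$duration_months <- dur
  } else if (!is.null(x$duration)) {
    notes <- c(notes, "duration: only ranges available; t tests skipped")
  }
  for (v in names(numeric_vars)) {
    df <- numeric_vars[[v]]
    usable <- df$group %in% nonempty & df$n >= 2 & !is.na(df$sd)
    sums <- lapply(df$group[usable], function(g) {
      r <- df[df$group == g, ]
      summary_stats(r$n, r$mean, r$sd)
    })
    names(sums) <- df$group[usable]
    if (length(sums) >= 2) {
      test_rows <- c(test_rows, list(
        test_row(v, "(mean)", "overall", anova_from_summary(sums))))
      for (pr in pairs) {
        if (!all(pr %in% names(sums))) next
        res <- t_test_from_summary(sums[[pr[1]]], sums[[pr[2]]], t_variant)
        res$alpha_effective <- alpha_eff
        test_rows <- c(test_rows,
                       list(test_row(v, "(mean)", paste(pr, collapse = " vs "), res)))
      }
    }
  }

  overall <- NULL
  if (!is.null(x$overall) && "multi_compartment" %in% names(x$overall)) {
    overall <- data.frame(
      quantity = c("multi_compartment"),
      count = unname(x$overall[["multi_compartment"]]),
      n = x$total, stringsAsFactors = FALSE)
  }
  if ("site" %in% names(x$categorical)) {
    site_tot <- colSums(x$categorical$site)
    overall <- rbind(overall, data.frame(
      quantity = paste0(names(site_tot), "_overall"),
      count = unname(site_tot), n = x$total, stringsAsFactors = FALSE))
  }
  if (!is.null(overall)) overall$percent <- 100 * overall$count / overall$n

  structure(list(
    groups = x$groups,
    categorical = do.call(rbind, cat_rows),
    numeric = x$age,
    duration = x$duration,
    tests = do.call(rbind, test_rows[!vapply(test_rows, is.null, logical(1))]),
    overall = overall,
    alpha = alpha,
    alpha_effective = alpha_eff,
    notes = notes
  ), class = "cohort_summary")
}

#' Summarise a per-patient cohort
#'
#' Builds the count structure (group sizes, category counts, age and
#' duration summaries, clonality counts, multi-compartment involvement)
#' from an `lpd_cohort` and passes it to [summarize_counts()].
#'
#' @param cohort An `lpd_cohort`.
#' @param ... Passed to [summarize_counts()].
#' @return A `cohort_summary`; the derived counts are attached as
#'   `$counts`.
#' @export
summarize_cohort <- function(cohort, ...) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  voc <- lpd_vocab()
  present <- intersect(voc$diagnosis, unique(cohort$diagnosis))
  if (length(present) == 0) stopf("cohort has no recognised diagnosis labels")
  d <- factor(cohort$diagnosis, levels = present)
  gn <- table(d)

  level_mat <- function(col, levels) {
    m <- sapply(levels, function(lv)
      tapply(!is.na(cohort[[col]]) & cohort[[col]] == lv, d, sum))
    m <- matrix(m, nrow = length(present),
                dimnames = list(present, levels))
    storage.mode(m) <- "integer"
    m
  }
  token_mat <- function(col, levels) {
    m <- sapply(levels, function(lv)
      tapply(has_token(cohort[[col]], lv), d, sum))
    m <- matrix(m, nrow = length(present), dimnames = list(present, levels))
    storage.mode(m) <- "integer"
    m
  }

  tested <- !is.na(cohort$igh_result) & cohort$igh_result %in% c("clonal", "polyclonal")
  clonal <- !is.na(cohort$igh_result) & cohort$igh_result == "clonal"
  clon <- cbind(tested = tapply(tested, d, sum), clonal = tapply(clonal, d, sum))
  storage.mode(clon) <- "integer"

  num_summary <- function(col) {
    do.call(rbind, lapply(present, function(g) {
      v <- cohort[[col]][d == g & !is.na(cohort[[col]])]
      data.frame(group = g, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) sd(v) else NA_real_,
                 min = if (length(v)) min(v) else NA_real_,
                 max = if (length(v)) max(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }

  n_compartments <- n_tokens(cohort$sites)
  counts <- structure(list(
    groups = setNames(as.integer(gn), present),
    total = nrow(cohort),
    categorical = list(
      sex = level_mat("sex", voc$sex),
      laterality = level_mat("laterality", voc$laterality),
      site = token_mat("sites", voc$sites),
      symptom = token_mat("symptoms", voc$symptoms),
      clonality = clon
    ),
    age = num_summary("age"),
    duration = num_summary("duration_months"),
    overall = c(total_patients = nrow(cohort),
                multi_compartment = sum(n_compartments >= 2),
                igh_qc_failed = sum(!is.na(cohort$igh_result) &
                                      cohort$igh_result == "qc_failed")),
    provenance = attr(cohort, "provenance") %||% "cohort"
  ), class = "lpd_counts")

  out <- summarize_counts(counts, ...)
  out$counts <- counts
  out
}

#' @export
print.cohort_summary <- function(x, digits = 2, ...) {
  groups <- names(x$groups)
  cat(sprintf("Clinical features of %d patients (%s)\n\n", sum(x$groups),
              paste(sprintf("%s n = %d", groups, x$groups), collapse = ", ")))

  fmt_cell <- function(count, pct) sprintf("%d (%.*f)", count, digits, pct)
  p_of <- function(variable, level, comparison) {
    if (is.null(x$tests)) return("-")
    r <- x$tests[x$tests$variable == variable & x$tests$level == level &
                   x$tests$comparison == comparison, ]
    if (nrow(r) == 0) "-" else format_p(r$p[1])
  }
  comparisons <- c("overall",
                   if (length(groups) >= 2)
                     vapply(combn(groups, 2, simplify = FALSE),
                            paste, character(1), collapse = " vs "))

  header <- c("parameter", groups, "P", if (length(comparisons) > 1)
    paste0("P ", comparisons[-1]))
  cat(paste(header, collapse = "\t"), "\n")

  nm <- x$numeric
  cat(paste(c("Age mean +/- SD",
              sprintf("%.2f +/- %.2f", nm$mean, nm$sd),
              vapply(comparisons, function(cc) p_of("age", "(mean)", cc),
                     character(1))), collapse = "\t"), "\n")
  cat(paste(c("Age range", sprintf("%g-%g", nm$min, nm$max),
              rep("", length(comparisons))), collapse = "\t"), "\n")

  cdf <- x$categorical
  seen <- character(0)
  for (key in unique(paste(cdf$variable, cdf$level, sep = "/"))) {
    sub <- cdf[paste(cdf$variable, cdf$level, sep = "/") == key, ]
    sub <- sub[match(groups, sub$group), ]
    ## variable-level tests (sex, laterality) print on the variable's
    ## first row; per-level tests (site, symptom) print on their own row
    lvl <- sub$level[1]
    if (!any(x$tests$variable == sub$variable[1] & x$tests$level == lvl))
      lvl <- "(all)"
    ps <- if (lvl == "(all)" && sub$variable[1] %in% seen) {
      rep("", length(comparisons))
    } else {
      vapply(comparisons, function(cc) p_of(sub$variable[1], lvl, cc),
             character(1))
    }
    seen <- c(seen, sub$variable[1])
    cat(paste(c(key, fmt_cell(sub$count, sub$percent), ps), collapse = "\t"),
        "\n")
  }
  if (!is.null(x$overall)) {
    cat("\nWhole-cohort quantities:\n")
    for (i in seq_len(nrow(x$overall)))
      cat(sprintf("  %s: %d/%d (%.1f%%)\n", x$overall$quantity[i],
                  x$overall$count[i], x$overall$n[i], x$overall$percent[i]))
  }
  if (length(x$notes))
    cat("\nNotes:\n", paste(" -", x$notes, collapse = "\n"), "\n")
  cat(sprintf("\nPairwise significance level: alpha = %g / %d pairs = %.4g\n",
              x$alpha, max(1, choose(sum(x$groups > 0), 2)), x$alpha_effective))
  invisible(x)
}
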