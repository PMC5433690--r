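## Diagnostic evaluation of the combination score against the
## IgH-clonality gold standard.

lpd_classes <- c("MALToma", "ALH", "RFH")

#' Score-band classifier specification
#'
#' A three-band classifier on the combination-score axis. Bands are
#' half-open with boundaries belonging to the lower band: scores in
#' \[0, cut1\] are called MALToma-like, (cut1, cut2\] ALH-like, and
#' (cut2, max\] RFH-like. Lower scores indicate greater malignancy
#' likelihood (disrupted follicles score low), so the lowest band is the
#' malignant-like one.
#'
#' @param cuts Numeric vector of two strictly increasing cut-points within
#'   `(0, max_score)`.
#' @param max_score Upper end of the score axis (6 with the default mean
#'   marker combiner).
#' @return A `classifier_spec` list.
#' @examples
#' classifier_spec(c(1.5, 4))
#' @export
classifier_spec <- function(cuts, max_score = 6) {
  cuts <- as.numeric(cuts)
  if (length(cuts) != 2 || anyNA(cuts) || diff(cuts) <= 0)
    stopf("cuts must be two strictly increasing numbers")
  if (cuts[1] < 0 || cuts[2] >= max_score)
    stopf("cuts must lie within [0, max_score)")
  structure(list(cuts = cuts, classes = lpd_classes, max_score = max_score),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> bands on [0, %g]:\n", x$max_score))
  cat(sprintf("  [0, %g]  -> %s-like\n", x$cuts[1], x$classes[1]))
  cat(sprintf("  (%g, %g] -> %s-like\n", x$cuts[1], x$cuts[2], x$classes[2]))
  cat(sprintf("  (%g, %g] -> %s-like\n", x$cuts[2], x$max_score, x$classes[3]))
  if (!is.null(attr(x, "balanced_accuracy")))
    cat(sprintf("  fit balanced accuracy: %.4f\n", attr(x, "balanced_accuracy")))
  invisible(x)
}

#' Classify combination scores into diagnosis-like bands
#'
#' @param score Numeric combination score(s).
#' @param spec A [classifier_spec()]. Boundary scores belong to the lower
#'   band.
#' @return Character vector of predicted classes (`"MALToma"`, `"ALH"`,
#'   `"RFH"`).
#' @export
classify <- function(score, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  ifelse(score <= spec$cuts[1], spec$classes[1],
         ifelse(score <= spec$cuts[2], spec$classes[2], spec$classes[3]))
}

balanced_accuracy <- function(pred, truth, classes) {
  mean(vapply(classes, function(g) {
    idx <- truth == g
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] == g)
  }, numeric(1)), na.rm = TRUE)
}

#' Fit classifier cut-points by exhaustive grid search
#'
#' Searches every pair of cut-points on the discrete combination-score
#' grid and returns the specification maximising balanced accuracy (mean
#' per-class recall) against the cohort's diagnosis labels. Ties are
#' broken toward the widest MALToma-like (lowest) band, then the widest
#' ALH-like band, making the fit deterministic.
#'
#' @param scored_cohort A cohort with `combination_score` and `diagnosis`
#'   columns (see [score_cohort()]); rows with missing scores are ignored.
#' @param grid Candidate cut-points; defaults to half-integer steps on
#'   \[0, `max_score`), the native resolution of the mean-combined score.
#' @param max_score Upper end of the score axis.
#' @return A `classifier_spec` with attribute `balanced_accuracy`.
#' @export
fit_thresholds <- function(scored_cohort, grid = NULL, max_score = 6) {
  df <- as.data.frame(scored_cohort)
  stopifnot(all(c("combination_score", "diagnosis") %in% names(df)))
  df <- df[!is.na(df$combination_score) & !is.na(df$diagnosis), ]
  present <- intersect(lpd_classes, unique(df$diagnosis))
  if (length(present) < 2)
    stopf("threshold fitting requires at least two diagnosis classes")
  if (length(unique(df$combination_score)) == 1L) {
    warnf("all combination scores identical; returning a degenerate spec")
    sc <- df$combination_score[1]
    return(structure(classifier_spec(c(max(sc, 0.25), max(sc + 0.5, 0.75)),
                                     max_score),
                     balanced_accuracy = NA_real_))
  }
  if (is.null(grid)) grid <- seq(0, max_score - 0.5, by = 0.5)

  best <- NULL; best_ba <- -Inf
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      if (grid[j] <= grid[i]) next
      pred <- ifelse(df$combination_score <= grid[i], lpd_classes[1],
                     ifelse(df$combination_score <= grid[j], lpd_classes[2],
                            lpd_classes[3]))
      ba <- balanced_accuracy(pred, df$diagnosis, present)
      better <- ba > best_ba + 1e-12 ||
        (abs(ba - best_ba) <= 1e-12 &&
           (grid[i] > best[1] || (grid[i] == best[1] && grid[j] > best[2])))
      if (is.null(best) || better) {
        best <- c(grid[i], grid[j]); best_ba <- ba
      }
    }
  }
  structure(classifier_spec(best, max_score), balanced_accuracy = best_ba)
}

#' Sensitivity from positive and tested counts
#'
#' Sensitivity of the scoring method in a group: score-positive cases
#' divided by evaluable cases, as a percentage. Reports round to one
#' decimal (e.g. 18 of 21 gives 85.7).
#'
#' @param n_positive Number of score-positive cases (0 <= n_positive <=
#'   n_tested).
#' @param n_tested Number of evaluable cases (> 0).
#' @return Sensitivity percentage (full precision; display rounding is
#'   applied by report printers).
#' @examples
#' round(sensitivity_from_counts(18, 21), 1)  # 85.7
#' round(sensitivity_from_counts(6, 17), 1)   # 35.3
#' @export
sensitivity_from_counts <- function(n_positive, n_tested) {
  if (any(n_tested <= 0)) stopf("n_tested must be positive")
  if (any(n_positive < 0) || any(n_positive > n_tested))
    stopf("n_positive must lie in [0, n_tested]")
  100 * n_positive / n_tested
}

default_positivity_rule <- function() {
  list(MALToma = "MALToma", ALH = c("MALToma", "ALH"), RFH = "RFH")
}

#' Evaluate the combination score against IgH clonality
#'
#' Compares score-band classification with the IgH gene clonal
#' rearrangement gold standard. Only records with an informative clonality
#' result (`clonal` or `polyclonal`) enter the denominators; `qc_failed`
#' and `not_tested` records are excluded, never imputed, mirroring the
#' quality-control exclusions of degraded archival DNA. Per diagnosis
#' group the evaluation reports the evaluable count, the clonal count, the
#' score-positive count under the positivity rule, and the sensitivity.
#'
#' The default positivity rule counts a MALToma case positive when it is
#' classified in the lowest (MALToma-like) band, and an ALH case positive
#' when classified in either non-benign band; this reconstruction of the
#' unpublished decision rule is documented in the package vignette.
#'
#' @param scored_cohort A scored cohort (see [score_cohort()]) with
#'   `igh_result`.
#' @param spec A [classifier_spec()].
#' @param positivity_rule Named list mapping each diagnosis group to the
#'   predicted classes that count as score-positive for it.
#' @return An `lpd_diagnostic` list with a per-group data frame
#'   (`n_tested`, `n_clonal`, `n_positive`, `sensitivity_percent`) and the
#'   inputs used.
#' @export
evaluate_against_clonality <- function(scored_cohort, spec,
                                       positivity_rule = default_positivity_rule()) {
  df <- as.data.frame(scored_cohort)
  stopifnot(all(c("combination_score", "diagnosis", "igh_result") %in% names(df)))
  evaluable <- !is.na(df$igh_result) &
    df$igh_result %in% c("clonal", "polyclonal") &
    !is.na(df$combination_score)
  if (!any(evaluable))
    stopf("no evaluable records: every record lacks an informative clonality result")
  df <- df[evaluable, ]
  df$pred <- classify(df$combination_score, spec)

  groups <- intersect(lpd_classes, unique(df$diagnosis))
  per_group <- do.call(rbind, lapply(groups, function(g) {
    sub <- df[df$diagnosis == g, ]
    n_pos <- sum(sub$pred %in% (positivity_rule[[g]] %||% g))
    data.frame(group = g, n_tested = nrow(sub),
               n_clonal = sum(sub$igh_result == "clonal"),
               n_positive = n_pos,
               sensitivity_percent = sensitivity_from_counts(n_pos, nrow(sub)),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_group = per_group, spec = spec,
                 positivity_rule = positivity_rule,
                 gold_standard = "igh_clonality",
                 n_evaluable = nrow(df)),
            class = "lpd_diagnostic")
}

#' @export
print.lpd_diagnostic <- function(x, ...) {
  cat(sprintf("<lpd_diagnostic> gold standard: %s (%d evaluable records)\n",
              x$gold_standard, x$n_evaluable))
  pg <- x$per_group
  for (i in seq_len(nrow(pg)))
    cat(sprintf("  %-8s tested %3d, clonal %3d, score-positive %3d, sensitivity %.1f%%\n",
                pg$group[i], pg$n_tested[i], pg$n_clonal[i], pg$n_positive[i],
                pg$sensitivity_percent[i]))
  cat(sprintf("  bands: MALToma-like [0, %g], ALH-like (%g, %g], RFH-like (%g, %g]\n",
              x$spec$cuts[1], x$spec$cuts[1], x$spec$cuts[2], x$spec$cuts[2],
              x$spec$max_score))
  invisible(x)
}
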