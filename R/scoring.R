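## Expression score, LF structure score, and their combination.

#' Mean percent-positive rate over five high-power fields
#'
#' The per-section positivity rate for a marker is defined as the
#' arithmetic mean of the percent-positive values counted in exactly five
#' high-power fields (HPF, x400).
#'
#' @param hpf_values Numeric vector of exactly five percentages in
#'   \[0, 100\].
#' @return The mean rate, a percentage in \[0, 100\].
#' @examples
#' mean_positive_rate(c(55, 60, 50, 45, 65))
#' @export
mean_positive_rate <- function(hpf_values) {
  if (length(hpf_values) != 5L || anyNA(hpf_values))
    stopf(paste("exactly five high-power-field values are required",
                "(got %d non-missing of %d); rates are averaged over five",
                "high-power fields"),
          sum(!is.na(hpf_values)), length(hpf_values))
  if (any(hpf_values < 0 | hpf_values > 100))
    stopf("high-power-field percentages must lie in [0, 100]")
  mean(hpf_values)
}

#' Two-scorer concordance check
#'
#' Sections are scored twice, blinded, by two independent scorers; the
#' readings are treated as concordant when the absolute difference of the
#' two mean rates is below 5 percentage points (strict inequality). The
#' panel-level rate used downstream is the mean of the two scorers' rates.
#'
#' @param rate_a,rate_b Mean percent-positive rates in \[0, 100\] from the
#'   two scorers. Vectorised.
#' @param tolerance Concordance bound in percentage points (default 5).
#' @return Character vector, `"concordant"` or `"discordant"`.
#' @examples
#' scorer_concordance(20, 24)  # concordant, |diff| = 4 < 5
#' scorer_concordance(20, 26)  # discordant
#' @export
scorer_concordance <- function(rate_a, rate_b, tolerance = 5) {
  if (any(c(rate_a, rate_b) < 0 | c(rate_a, rate_b) > 100, na.rm = TRUE))
    stopf("rates must lie in [0, 100]")
  ifelse(abs(rate_a - rate_b) < tolerance, "concordant", "discordant")
}

#' CD23/IgD expression score
#'
#' Grades a marker's percent-positive rate on the ordinal 0-3 rubric:
#' score 0 for 0%, 1 for rates in (0, 10\], 2 for (10, 20\], and 3 above
#' 20%. The published rubric lists integer bins (0; 1-10; 11-20; >= 21);
#' because HPF averaging produces real-valued rates, the bins are read as
#' half-open continuous intervals, which reproduces the integer behaviour
#' exactly and maps every real rate to exactly one score.
#'
#' @param rate Percent-positive rate(s) in \[0, 100\]. Vectorised.
#' @return Integer score(s) in `0:3`.
#' @examples
#' expression_score(c(0, 0.5, 15, 25))
#' @export
expression_score <- function(rate) {
  if (anyNA(rate) || any(rate < 0 | rate > 100))
    stopf("rate must lie in [0, 100]")
  ifelse(rate <= 0, 0L, ifelse(rate <= 10, 1L, ifelse(rate <= 20, 2L, 3L)))
}

lf_descriptions <- c(
  "0" = "No staining or few scattered positively stained cells",
  "1" = "Some scattered disrupted fragments with no intact lymphoid follicles",
  "2" = "Some intact lymphoid follicles and scattered FDC/MZ fragments",
  "3" = "Most lymphoid follicles are intact, accompanied by some disrupted fragments"
)

#' Lymphoid-follicle structure score
#'
#' Grades follicle integrity on the ordinal 0-3 rubric: 0, no staining or
#' few scattered positive cells; 1, scattered disrupted fragments with no
#' intact follicles; 2, some intact follicles plus scattered FDC/MZ
#' fragments; 3, most follicles intact with some disrupted fragments.
#' Accepts either the stored category code (0-3) or the rubric's verbatim
#' description (case-insensitive).
#'
#' @param category Integer code(s) in `0:3`, or character description(s).
#' @return Integer score(s) in `0:3`.
#' @examples
#' lf_score(2)
#' lf_score("Some intact lymphoid follicles and scattered FDC/MZ fragments")
#' @export
lf_score <- function(category) {
  if (is.character(category)) {
    idx <- match(tolower(trimws(category)), tolower(lf_descriptions))
    if (anyNA(idx))
      stopf("unknown lymphoid-follicle category '%s'; permitted: codes 0-3 or\n  %s",
            category[which(is.na(idx))[1]],
            paste(sprintf("[%s] %s", names(lf_descriptions), lf_descriptions),
                  collapse = "\n  "))
    return(as.integer(names(lf_descriptions))[idx])
  }
  if (anyNA(category) || !all(category %in% 0:3))
    stopf("lymphoid-follicle category must be one of 0, 1, 2, 3")
  as.integer(category)
}

combine_marker_scores <- function(cd23, igd, combiner) {
  switch(combiner,
         mean = (cd23 + igd) / 2,
         min  = pmin(cd23, igd),
         max  = pmax(cd23, igd),
         sum  = cd23 + igd,
         stopf("unknown combiner '%s'; use mean, min, max or sum", combiner))
}

#' Combination score panel
#'
#' Computes the full score panel for one section: per-marker expression
#' scores for CD23 and IgD, the combined expression score (by default the
#' mean of the two marker scores, keeping it on the 0-3 scale), the LF
#' structure score, and the combination score, defined as expression score
#' plus LF score. With the default combiner the combination score lies in
#' \[0, 6\]; lower values indicate more disrupted follicles and a greater
#' likelihood of malignancy.
#'
#' @param cd23_rate,igd_rate Percent-positive rates in \[0, 100\].
#'   Vectorised.
#' @param lf_category LF structure category, code 0-3 or description.
#' @param combiner How the two marker scores merge into one expression
#'   score: `"mean"` (default), `"min"`, `"max"`, or `"sum"` (the latter
#'   extends the combination range to \[0, 9\]).
#' @return A `score_panel` data frame with columns `cd23_score`,
#'   `igd_score`, `expression_score`, `lf_score`, `combination_score`.
#' @examples
#' combination_score(15, 5, 1)   # panel (2, 1, 1.5, 1, 2.5)
#' combination_score(25, 25, 3)  # maximal panel, combination score 6
#' @export
combination_score <- function(cd23_rate, igd_rate, lf_category,
                              combiner = c("mean", "min", "max", "sum")) {
  combiner <- match.arg(combiner)
  cd23 <- expression_score(cd23_rate)
  igd <- expression_score(igd_rate)
  lf <- lf_score(lf_category)
  expr <- combine_marker_scores(cd23, igd, combiner)
  panel <- data.frame(cd23_score = cd23, igd_score = igd,
                      expression_score = expr, lf_score = lf,
                      combination_score = expr + lf)
  class(panel) <- c("score_panel", "data.frame")
  panel
}

#' Score every record of a cohort
#'
#' Applies the scoring pipeline to an `lpd_cohort`: per marker, the mean
#' positive rate of each scorer's five HPF values is computed; where both
#' scorers are present the panel rate is their mean and the record is
#' flagged concordant when both markers' scorer differences are below 5
#' percentage points; where only scorer A is present its rate is used and
#' the flag is `NA`. Records lacking a marker or the LF category receive
#' `NA` scores.
#'
#' @param cohort An `lpd_cohort`.
#' @param combiner Marker-score combiner, see [combination_score()].
#' @return The cohort with appended columns `cd23_rate`, `igd_rate`,
#'   `cd23_score`, `igd_score`, `expression_score`, `lf_score`,
#'   `combination_score`, `scorer_concordant`.
#' @export
score_cohort <- function(cohort, combiner = c("mean", "min", "max", "sum")) {
  combiner <- match.arg(combiner)
  stopifnot(is.data.frame(cohort))
  out <- as.data.frame(cohort)

  marker_rate <- function(marker) {
    a <- rowMeans(out[, hpf_cols(marker, "a")])
    b <- rowMeans(out[, hpf_cols(marker, "b")])
    rate <- ifelse(is.na(b), a, (a + b) / 2)
    diff <- abs(a - b)
    list(rate = rate, diff = diff)
  }
  cd23 <- marker_rate("cd23")
  igd <- marker_rate("igd")

  score_or_na <- function(rate) {
    s <- rep(NA_integer_, length(rate))
    ok <- !is.na(rate)
    s[ok] <- expression_score(rate[ok])
    s
  }
  out$cd23_rate <- cd23$rate
  out$igd_rate <- igd$rate
  out$cd23_score <- score_or_na(cd23$rate)
  out$igd_score <- score_or_na(igd$rate)
  out$expression_score <- combine_marker_scores(out$cd23_score, out$igd_score,
                                                combiner)
  lf <- rep(NA_integer_, nrow(out))
  ok <- !is.na(out$lf_category)
  lf[ok] <- lf_score(out$lf_category[ok])
  out$lf_score <- lf
  out$combination_score <- out$expression_score + out$lf_score
  out$scorer_concordant <- pmax(cd23$diff, igd$diff) < 5
  attr(out, "provenance") <- attr(cohort, "provenance")
  attr(out, "combiner") <- combiner
  class(out) <- c("lpd_cohort", "data.frame")
  out
}
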