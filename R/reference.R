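## Packaged reference counts of the 125-patient cohort.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "lpdscore")
  if (!nzchar(p)) stopf("packaged fixture '%s' not found", file)
  p
}

#' Reference cohort counts
#'
#' Returns the packaged count structure transcribed from the published
#' clinical-features table of the 125-patient ocular adnexal LPD cohort
#' (54 RFH, 28 ALH, 43 MALToma): per-group counts for sex, laterality,
#' anatomical sites and symptoms; age summary statistics (mean, SD,
#' range); disease-duration ranges; IgH clonality counts (35/17/21 tested,
#' 0/8/18 clonal); and overall quantities (125 patients, 59 with
#' multi-compartment involvement, 52 quality-control failures).
#'
#' Counts, not printed percentages, are authoritative: every percentage in
#' a [summarize_counts()] report is recomputed from these counts.
#'
#' @return An object of class `lpd_counts`: a list with elements `groups`
#'   (named integer vector of group sizes), `total`, `categorical` (named
#'   list of group-by-level count matrices for `sex`, `laterality`, `site`,
#'   `symptom`, `clonality`), `age` and `duration` (data frames of summary
#'   statistics), and `overall` (named vector of whole-cohort counts).
#' @seealso [group_n()], [level_count()], [summarize_counts()]
#' @examples
#' rc <- reference_counts()
#' group_n(rc, "RFH")
#' level_count(rc, "MALToma", "sex", "female")
#' @export
reference_counts <- function() {
  counts <- read.csv(ref_path("reference_counts.csv"), stringsAsFactors = FALSE)
  nums <- read.csv(ref_path("reference_numeric.csv"), stringsAsFactors = FALSE)
  overall <- read.csv(ref_path("reference_overall.csv"), stringsAsFactors = FALSE)
  groups <- lpd_vocab()$diagnosis

  n_row <- counts[counts$variable == "group" & counts$level == "n", groups]
  group_n <- setNames(as.integer(n_row), groups)

  cat_mat <- function(var) {
    sub <- counts[counts$variable == var, ]
    m <- t(as.matrix(sub[, groups]))
    dimnames(m) <- list(groups, sub$level)
    storage.mode(m) <- "integer"
    m
  }
  num_df <- function(var) {
    sub <- nums[nums$variable == var, ]
    out <- data.frame(group = groups,
                      t(as.matrix(sub[, groups])),
                      row.names = NULL, check.names = FALSE)
    names(out) <- c("group", sub$stat)
    out
  }

  age <- num_df("age")
  age$n <- group_n[age$group]
  structure(list(
    groups = group_n,
    total = sum(group_n),
    categorical = list(
      sex = cat_mat("sex"),
      laterality = cat_mat("laterality"),
      site = cat_mat("site"),
      symptom = cat_mat("symptom"),
      clonality = cat_mat("clonality")
    ),
    age = age[, c("group", "n", "mean", "sd", "min", "max")],
    duration = num_df("duration_months"),
    overall = setNames(overall$value, overall$quantity),
    provenance = "fixture_reference"
  ), class = "lpd_counts")
}

#' Group size of a count structure
#'
#' @param x An `lpd_counts` object (see [reference_counts()]).
#' @param group Diagnosis group, one of `"RFH"`, `"ALH"`, `"MALToma"`.
#' @return Integer group size.
#' @export
group_n <- function(x, group) {
  stopifnot(inherits(x, "lpd_counts"))
  check_enum(group, names(x$groups), "group")
  unname(x$groups[[group]])
}

#' Count of one category level in one group
#'
#' @inheritParams group_n
#' @param variable One of `"sex"`, `"laterality"`, `"site"`, `"symptom"`,
#'   `"clonality"`.
#' @param level A level of `variable` (e.g. `"female"`, `"bilateral"`).
#' @return Integer count.
#' @export
level_count <- function(x, group, variable, level) {
  stopifnot(inherits(x, "lpd_counts"))
  check_enum(group, names(x$groups), "group")
  check_enum(variable, names(x$categorical), "variable")
  m <- x$categorical[[variable]]
  check_enum(level, colnames(m), sprintf("level of '%s'", variable))
  unname(m[group, level])
}

#' @export
print.lpd_counts <- function(x, ...) {
  cat(sprintf("<lpd_counts> %d patients (%s); provenance: %s\n", x$total,
              paste(sprintf("%s %d", names(x$groups), x$groups), collapse = ", "),
              x$provenance))
  invisible(x)
}
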