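## Cohort data model: one row per patient, plain-text CSV interchange.

#' Controlled vocabularies of the cohort data model
#'
#' Returns the permitted values for every categorical field of a patient
#' record: diagnosis groups, sex, laterality, anatomical sites, clinical
#' symptoms, lymphoid-follicle (LF) structure categories, and IgH
#' clonality results. The "other" site collapses eyelid, nasolacrimal duct
#' and nerve involvement into a single category.
#'
#' @return Named list of character (or integer, for `lf_category`) vectors.
#' @examples
#' lpd_vocab()$diagnosis
#' @export
lpd_vocab <- function() {
  list(
    diagnosis  = c("RFH", "ALH", "MALToma"),
    sex        = c("female", "male"),
    laterality = c("unilateral", "bilateral"),
    sites      = c("orbital_soft_tissue", "conjunctiva", "lachrymal_gland",
                   "extraocular_muscle", "other"),
    symptoms   = c("periorbital_swelling", "proptosis", "impaired_vision",
                   "epiphora", "pain", "motility_impairment", "ptosis"),
    lf_category = 0:3,
    igh_result = c("clonal", "polyclonal", "qc_failed", "not_tested")
  )
}

hpf_cols <- function(marker, scorer = c("a", "b")) {
  scorer <- match.arg(scorer)
  suffix <- if (scorer == "b") "_b" else ""
  paste0(marker, "_hpf", 1:5, suffix)
}

#' Column schema of the cohort CSV
#'
#' The interchange format is a UTF-8 CSV with a mandatory header. Scorer A
#' high-power-field (HPF) percent-positive columns carry no suffix; scorer
#' B columns carry the `_b` suffix. `sites` and `symptoms` hold
#' semicolon-delimited tokens from [lpd_vocab()]. Empty cells denote absent
#' values; absence is never coded as zero.
#'
#' @return Character vector of column names, in file order.
#' @export
cohort_columns <- function() {
  c("patient_id", "diagnosis", "age", "sex", "duration_months", "sites",
    "laterality", "symptoms",
    hpf_cols("cd23", "a"), hpf_cols("igd", "a"),
    hpf_cols("cd23", "b"), hpf_cols("igd", "b"),
    "lf_category", "igh_result")
}

split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

## vectorised membership test: does each semicolon-delimited string
## contain `token`?
has_token <- function(x, token) {
  !is.na(x) & grepl(paste0("(^|;)", token, "(;|$)"), x)
}

## vectorised count of tokens per string (0 for absent)
n_tokens <- function(x) {
  out <- integer(length(x))
  nz <- !is.na(x) & nzchar(x)
  out[nz] <- nchar(x[nz]) - nchar(gsub(";", "", x[nz], fixed = TRUE)) + 1L
  out
}

#' Construct a validated cohort table
#'
#' Validates a data frame against the cohort schema (see
#' [cohort_columns()]) and returns it classed as `lpd_cohort`. Validation
#' enforces the controlled vocabularies, the plausibility window on age,
#' strictly positive disease duration, percent ranges on HPF values, and
#' the five-HPF rule: each marker/scorer block must contain either all
#' five high-power-field values or none (a partially filled block is an
#' error, because the mean positive rate is defined as the average over
#' exactly five fields).
#'
#' @param df Data frame with the columns of [cohort_columns()].
#' @param provenance One of `"user_csv"`, `"synthetic"`,
#'   `"fixture_reference"`; stored as an attribute.
#' @param age_range Plausibility window for age in years.
#' @return `df`, classed `lpd_cohort`, with a `provenance` attribute.
#' @seealso [read_cohort()], [write_cohort()]
#' @export
as_lpd_cohort <- function(df, provenance = "user_csv",
                          age_range = c(0, 120)) {
  cols <- cohort_columns()
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L)
    stopf("cohort is missing column(s): %s", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, cols]
  voc <- lpd_vocab()

  errors <- character(0)
  ## vectorised checks: `bad` is a logical row index; the first few
  ## offending rows are reported with their values
  flag <- function(bad, col, msg_fmt, values = df[[col]]) {
    idx <- which(bad)
    if (length(idx) == 0L) return(invisible(NULL))
    shown <- utils::head(idx, 5L)
    errors <<- c(errors, sprintf(
      "row %d, column '%s': %s", shown, col,
      sprintf(msg_fmt, values[shown])))
    if (length(idx) > 5L)
      errors <<- c(errors, sprintf("  ... and %d more row(s) with invalid '%s'",
                                   length(idx) - 5L, col))
  }

  if (anyDuplicated(df$patient_id))
    stopf("duplicate patient_id value(s): %s",
          paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))

  flag(is.na(df$patient_id) | !nzchar(df$patient_id), "patient_id",
       "must be non-empty")
  flag(is.na(df$diagnosis) | !df$diagnosis %in% voc$diagnosis, "diagnosis",
       sprintf("value '%%s' not permitted; permitted values: {%s}",
               paste(voc$diagnosis, collapse = ", ")))
  for (fld in c("sex", "laterality", "igh_result"))
    flag(!is.na(df[[fld]]) & !df[[fld]] %in% voc[[fld]], fld,
         sprintf("value '%%s' not in {%s}", paste(voc[[fld]], collapse = ", ")))
  flag(!is.na(df$age) & (df$age < age_range[1] | df$age > age_range[2]), "age",
       sprintf("value %%s outside plausibility window [%s, %s]",
               age_range[1], age_range[2]))
  flag(!is.na(df$duration_months) & df$duration_months <= 0, "duration_months",
       "value %s; must be > 0")
  flag(!is.na(df$lf_category) & !df$lf_category %in% voc$lf_category,
       "lf_category", "value '%s' not in {0, 1, 2, 3}")
  for (fld in c("sites", "symptoms")) {
    ## strip every known token; anything left is an unknown literal
    x <- df[[fld]]
    stripped <- x
    for (tok in voc[[fld]])
      stripped <- gsub(paste0("(^|;)", tok, "(?=;|$)"), "\\1", stripped,
                       perl = TRUE)
    stripped <- gsub(";+", ";", stripped)
    stripped <- gsub("^;|;$", "", stripped)
    flag(!is.na(x) & nzchar(x) & nzchar(stripped), fld,
         sprintf("unknown token(s) '%%s'; permitted: {%s}",
                 paste(voc[[fld]], collapse = ", ")), values = stripped)
  }
  for (marker in c("cd23", "igd")) for (scorer in c("a", "b")) {
    block <- as.matrix(df[hpf_cols(marker, scorer)])
    n_present <- rowSums(!is.na(block))
    col_lab <- paste0(marker, "_hpf*", if (scorer == "b") "_b")
    flag(n_present > 0L & n_present < 5L, col_lab,
         paste("%s of 5 high-power-field values present; positive rates are",
               "averaged over exactly five high-power fields, so a block must",
               "be complete or entirely absent"), values = n_present)
    flag(rowSums(!is.na(block) & (block < 0 | block > 100)) > 0, col_lab,
         "value(s) outside [0, 100]%.0s", values = n_present)
  }
  if (length(errors) > 0L)
    stopf("invalid cohort (%d problem%s):\n%s", length(errors),
          if (length(errors) > 1L) "s" else "", paste("  -", errors, collapse = "\n"))

  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("lpd_cohort", "data.frame")
  df
}

#' Read a cohort CSV
#'
#' Reads and validates a per-patient cohort file in the documented schema
#' (see [cohort_columns()]). Empty cells become `NA` ("absent"), never
#' zero. Malformed rows produce an error that names the row, the column
#' and the offending value; unknown categorical literals produce an error
#' naming the permitted values.
#'
#' @param path Path to a cohort CSV file.
#' @param age_range Plausibility window for age, passed to
#'   [as_lpd_cohort()].
#' @return An `lpd_cohort` data frame.
#' @export
read_cohort <- function(path, age_range = c(0, 120)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  cols <- cohort_columns()
  char_cols <- c("patient_id", "diagnosis", "sex", "sites", "laterality",
                 "symptoms", "igh_result")
  classes <- setNames(ifelse(cols %in% char_cols, "character", "numeric"), cols)
  df <- read.csv(path, colClasses = NA, na.strings = "", check.names = FALSE,
                 stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(df), cols))
    stopf("header mismatch: expected columns\n  %s\nbut found\n  %s",
          paste(cols, collapse = ","), paste(names(df), collapse = ","))
  for (cc in cols) {
    if (classes[[cc]] == "character") {
      df[[cc]] <- as.character(df[[cc]])
    } else {
      v <- suppressWarnings(as.numeric(df[[cc]]))
      bad <- which(is.na(v) & !is.na(df[[cc]]) & nzchar(as.character(df[[cc]])))
      if (length(bad) > 0L)
        stopf("row %d, column '%s': value '%s' is not numeric",
              bad[1], cc, df[[cc]][bad[1]])
      df[[cc]] <- v
    }
  }
  ## normalise token fields so that "" means absent
  df$sites[!is.na(df$sites) & !nzchar(df$sites)] <- NA_character_
  df$symptoms[!is.na(df$symptoms) & !nzchar(df$symptoms)] <- NA_character_
  as_lpd_cohort(df, provenance = "user_csv", age_range = age_range)
}

#' Write a cohort CSV
#'
#' Writes an `lpd_cohort` (or schema-compatible data frame) to CSV in the
#' documented column order. Absent values are written as empty cells, so
#' that `read_cohort(write_cohort(x))` reproduces `x` field for field.
#'
#' @param x Cohort table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  df <- as.data.frame(x)[, cohort_columns()]
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
              fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("could not write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' @export
print.lpd_cohort <- function(x, ...) {
  cat(sprintf("<lpd_cohort> %d patient record(s), provenance: %s\n",
              nrow(x), attr(x, "provenance") %||% "unknown"))
  tab <- table(factor(x$diagnosis, lpd_vocab()$diagnosis))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  NextMethod()
}
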