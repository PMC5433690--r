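# builders for small in-code fixtures

# one fully specified valid record as a 1-row data frame
make_record <- function(patient_id = "P-001", diagnosis = "RFH", age = 55,
                        sex = "female", duration_months = 12,
                        sites = "orbital_soft_tissue", laterality = "unilateral",
                        symptoms = "proptosis",
                        cd23 = c(25, 30, 20, 28, 27), igd = c(22, 26, 24, 20, 28),
                        cd23_b = cd23 + 1, igd_b = igd - 1,
                        lf_category = 3, igh_result = "polyclonal") {
  df <- data.frame(patient_id = patient_id, diagnosis = diagnosis, age = age,
                   sex = sex, duration_months = duration_months, sites = sites,
                   laterality = laterality, symptoms = symptoms,
                   stringsAsFactors = FALSE)
  df[paste0("cd23_hpf", 1:5)] <- as.list(cd23)
  df[paste0("igd_hpf", 1:5)] <- as.list(igd)
  df[paste0("cd23_hpf", 1:5, "_b")] <- as.list(cd23_b)
  df[paste0("igd_hpf", 1:5, "_b")] <- as.list(igd_b)
  df$lf_category <- lf_category
  df$igh_result <- igh_result
  df
}

make_cohort_df <- function(n = 3, diagnosis = "RFH", ...) {
  do.call(rbind, lapply(seq_len(n), function(i)
    make_record(patient_id = sprintf("P-%03d", i), diagnosis = diagnosis, ...)))
}

# a scored cohort with perfectly separated combination scores
make_separable_scored <- function(n = 5) {
  df <- data.frame(
    diagnosis = rep(c("RFH", "ALH", "MALToma"), each = n),
    combination_score = rep(c(6, 3, 0), each = n),
    igh_result = rep(c("polyclonal", "clonal", "clonal"), each = n),
    stringsAsFactors = FALSE)
  df$patient_id <- sprintf("S-%03d", seq_len(nrow(df)))
  df
}
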