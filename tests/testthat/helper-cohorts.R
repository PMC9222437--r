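# Small cohort builders shared across test files.

# A bare-bones subject table with full control over haplotype and SER.
subjects_df <- function(hap, ser, percent_l = NA_real_) {
  data.frame(subject_id = sprintf("T%03d", seq_along(hap)),
             sex = "M", european = TRUE, cv_normal = TRUE, surgery = FALSE,
             single_opn1lw = TRUE, opn1lw_hap = hap,
             percent_l = rep_len(percent_l, length(hap)),
             calculated_ser = ser, stringsAsFactors = FALSE)
}

# Two well-separated haplotype groups (panel-valid haplotype strings).
two_group_cohort <- function(n_per = 6, mean1 = -3, mean2 = 0, sd = 0.1,
                             seed = 42) {
  haps <- c("AACGGTGG", "GCGGGCAT")
  set.seed(seed)
  subjects_df(rep(haps, each = n_per),
              stats::rnorm(2 * n_per, rep(c(mean1, mean2), each = n_per), sd))
}

table1_fixture <- function() read_table1_fixture()
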