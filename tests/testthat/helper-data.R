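# Small handmade study tables written to temp files for I/O tests.

example_study_df <- function() {
  data.frame(
    study_id = c("smith2005", "li2003", "kim2004"),
    year = c(2005L, 2003L, 2004L),
    ethnicity = c("Caucasian", "asian", "Asian"),
    locus_id = "rs1234567",
    case_AA = c(70L, 55L, 60L), case_Aa = c(20L, 35L, 30L),
    case_aa = c(10L, 10L, 10L),
    ctrl_AA = c(80L, 60L, 65L), ctrl_Aa = c(15L, 32L, 28L),
    ctrl_aa = c(5L, 8L, 7L),
    stringsAsFactors = FALSE)
}

write_study_file <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
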