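# Fixture builders shared across test files.

# A minimal in-memory peptide table; abundances given as a named list of
# sample vectors.
make_peptides <- function(sequence, modifications = rep("", length(sequence)),
                          accession = rep("P1", length(sequence)),
                          mass_error_ppm = rep(0, length(sequence)),
                          score = seq_along(sequence),
                          charge = rep(2L, length(sequence)),
                          abundances = list(s1 = rep(1, length(sequence)),
                                            s2 = rep(1, length(sequence)))) {
  df <- data.frame(sequence = sequence, charge = charge, score = score,
                   mass_error_ppm = mass_error_ppm, accession = accession,
                   stringsAsFactors = FALSE)
  df$modifications <- acylsite::parse_modifications(modifications)
  df <- df[, c("sequence", "modifications", "charge", "score",
               "mass_error_ppm", "accession")]
  for (s in names(abundances)) df[[s]] <- abundances[[s]]
  structure(df, sample_ids = names(abundances),
            class = c("peptide_table", "data.frame"))
}

# Write a peptide CSV from plain character/numeric columns.
write_peptide_csv <- function(path, rows, samples = c("s1", "s2")) {
  header <- c("sequence", "modifications", "charge", "score",
              "mass_error_ppm", "accession", samples)
  writeLines(c(paste(header, collapse = ","),
               vapply(rows, paste, "", collapse = ",")), path)
  path
}

# Four-group co-treatment design with n replicates per group.
make_cotreat_design <- function(n = 3L) {
  groups <- c("vehicle1", "vehicle2", "model", "treatment")
  acylsite::study_design(
    data.frame(sample_id = paste0(rep(c("V1_", "V2_", "MK_", "CO_"),
                                      each = n), seq_len(n)),
               group_id = rep(groups, each = n),
               stringsAsFactors = FALSE),
    roles = setNames(groups, groups))
}
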