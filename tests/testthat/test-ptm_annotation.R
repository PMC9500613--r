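# Independent elemental-mass oracle: monoisotopic masses summed directly
# from IUPAC atomic masses, separate from the package's lookup.
oracle_mass <- function(nC, nH, nO) {
  nC * 12 + nH * 1.0078250319 + nO * 15.9949146221
}

test_that("acyl mass deltas match the elemental-composition oracle", {
  expect_equal(ptm_mass_delta("succinyl"), oracle_mass(4, 4, 3),
               tolerance = 1e-10)
  expect_equal(ptm_mass_delta("malonyl"), oracle_mass(3, 2, 3),
               tolerance = 1e-10)
  expect_equal(ptm_mass_delta("succinyl"), 100.01604, tolerance = 1e-5)
  expect_equal(ptm_mass_delta("malonyl"), 86.00039, tolerance = 1e-5)
  # the two moieties differ by exactly one CH2
  expect_equal(ptm_mass_delta("succinyl") - ptm_mass_delta("malonyl"),
               oracle_mass(1, 2, 0), tolerance = 1e-10)
  expect_equal(ptm_mass_delta("Succinyl"), ptm_mass_delta("succinyl"))
  expect_error(ptm_mass_delta("acetyl"), "supported")
})

test_that("missed cleavages follow the tryptic rule with the modified-K exclusion", {
  expect_equal(count_missed_cleavages("AKLYK"), 1L)            # internal K2
  expect_equal(count_missed_cleavages("AKLYK", modified_k = 2), 0L)
  expect_equal(count_missed_cleavages("AKPLR"), 0L)            # K before P
  expect_equal(count_missed_cleavages("AKPLR", kp_rule = FALSE), 1L)
  expect_equal(count_missed_cleavages("AKLRYK"), 2L)
  expect_equal(count_missed_cleavages("K"), 0L)                # C-terminal only
  expect_error(count_missed_cleavages("AKA", modified_k = 1), "lysine")
})

test_that("fully acylated peptides count only internal R (not before P)", {
  set.seed(11)
  alphabet <- strsplit("ACDEFGHILMNQSTVWY", "")[[1L]]
  for (i in 1:25) {
    body <- sample(c(alphabet, "K", "R", "P"), 12, replace = TRUE)
    seqn <- paste(c(body, "K"), collapse = "")
    kpos <- which(strsplit(seqn, "")[[1L]] == "K")
    aa <- strsplit(seqn, "")[[1L]]
    internal <- seq_len(nchar(seqn) - 1L)
    expected <- sum(aa[internal] == "R" & aa[internal + 1L] != "P")
    expect_equal(count_missed_cleavages(seqn, modified_k = kpos), expected)
  }
})

test_that("sites map onto protein lysines with offset arithmetic", {
  pep <- make_peptides(c("AKC", "AAA"),
                       modifications = c("Succinyl(K2)", "Oxidation(A1)"),
                       accession = c("P1", "P1"))
  sites <- map_sites(pep, c(P1 = "MAKC"))
  expect_equal(nrow(sites), 1L)  # the oxidation-only peptide emits nothing
  expect_equal(sites$accession, "P1")
  expect_equal(sites$position, 3L)
  expect_equal(sites$ptm, "succinyl")

  # peptide absent from the protein
  expect_error(map_sites(make_peptides("AKC", "Succinyl(K2)"),
                         c(P1 = "MAAA")), "not found")
  # ambiguous match needs the flag
  expect_error(map_sites(make_peptides("AKC", "Succinyl(K2)"),
                         c(P1 = "AKCAKC")), "first_match")
  s2 <- map_sites(make_peptides("AKC", "Succinyl(K2)"),
                  c(P1 = "AKCAKC"), first_match = TRUE)
  expect_equal(s2$position, 2L)
  # missing accession
  expect_error(map_sites(make_peptides("AKC", "Succinyl(K2)"),
                         c(Q9 = "MAKC")), "not in proteome")
})

test_that("sites supported by several peptides merge and positions are lysines", {
  pep <- make_peptides(c("AKC", "MAKC"),
                       modifications = c("Succinyl(K2)", "Succinyl(K3)"),
                       accession = c("P1", "P1"))
  sites <- map_sites(pep, c(P1 = "MAKC"))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$n_peptides, 2L)
  expect_equal(sites$peptide_rows, "1,2")
  expect_equal(substring("MAKC", sites$position, sites$position), "K")
})

test_that("quality filter partitions the table and labels every rejection", {
  # 20-row fixture exercising all filter rules: 5 mass-error rejections
  # (|ppm| >= 20 including boundary and negative), 4 missed-cleavage
  # rejections (>1 after excluding modified K), 11 kept.
  seqs <- c("AAAGK",    # 0 mc, ppm 0            -> kept
            "ACDEK",    # ppm 25                 -> mass_error
            "ADEFK",    # ppm -25                -> mass_error
            "AEFGK",    # ppm 20 (boundary)      -> mass_error
            "AFGHK",    # ppm -20 (boundary)     -> mass_error
            "AGHIK",    # ppm 19.9               -> kept
            "AHILK",    # ppm -19.9              -> kept
            "AKLYK",    # 1 mc                   -> kept
            "AKLRYK",   # 2 mc                   -> missed_cleavages
            "CKLRYK",   # 2 mc, acyl K2 -> 1 mc  -> kept
            "DKTKLYK",  # 2 mc, acyl K2,K4 -> 0  -> kept
            "EKTKLYRK", # 3 mc, acyl K2 -> 2     -> missed_cleavages
            "AKPLR",    # KP rule -> 0 mc        -> kept
            "FKPLRTK",  # K2 before P, R5 -> 1   -> kept
            "GRLRYK",   # 2 internal R           -> missed_cleavages
            "HKLYK",    # acyl K2 -> 0 mc        -> kept
            "ILMNK",    # 0 mc                   -> kept
            "LMNQK",    # ppm 30, also 0 mc      -> mass_error
            "MKRKLK",   # acyl K2 only -> 2 mc   -> missed_cleavages
            "NQSTK")    # 0 mc                   -> kept
  mods <- rep("", 20)
  mods[10] <- "Succinyl(K2)"
  mods[11] <- "Succinyl(K2);Malonyl(K4)"
  mods[12] <- "Succinyl(K2)"
  mods[16] <- "Malonyl(K2)"
  mods[19] <- "Succinyl(K2)"
  ppm <- rep(0, 20)
  ppm[c(2, 3, 4, 5, 6, 7, 18)] <- c(25, -25, 20, -20, 19.9, -19.9, 30)
  tab <- make_peptides(seqs, mods, mass_error_ppm = ppm)

  res <- filter_peptides(tab)
  expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(tab))
  expect_equal(res$rejected$row, c(2, 3, 4, 5, 9, 12, 15, 18, 19))
  expect_equal(res$rejected$reason,
               c("mass_error", "mass_error", "mass_error", "mass_error",
                 "missed_cleavages", "missed_cleavages", "missed_cleavages",
                 "mass_error", "missed_cleavages"))
  expect_equal(res$kept$sequence, seqs[-res$rejected$row])
  expect_s3_class(res$kept, "peptide_table")
})
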