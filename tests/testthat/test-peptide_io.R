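test_that("peptide tables parse with modifications, preserve order, round-trip", {
  f <- tempfile(fileext = ".csv")
  write_peptide_csv(f, list(
    c("AKLCK", "Succinyl(K2)", 2, 30, 1.5, "P1", 100, 110),
    c("LMNQS", "", 3, 20, -2, "P2", 5, 6),
    c("TVWYA", "Oxidation(W3)", 2, 10, 0, "P1", 7, 8)))
  tab <- read_peptide_table(f)
  expect_s3_class(tab, "peptide_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(vapply(tab$modifications, nrow, 1L) > 0), 2L)
  expect_equal(sum(is_modified(tab)), 1L)  # only the succinylated row is acyl
  expect_equal(tab$sequence, c("AKLCK", "LMNQS", "TVWYA"))  # file order

  out <- tempfile(fileext = ".csv")
  write_peptide_table(tab, out)
  back <- read_peptide_table(out)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(attr(back, "sample_ids"), attr(tab, "sample_ids"))
})

test_that("header-only file gives an empty table, missing columns error", {
  f <- tempfile(fileext = ".csv")
  write_peptide_csv(f, list())
  expect_equal(nrow(read_peptide_table(f)), 0L)

  g <- tempfile(fileext = ".csv")
  writeLines(c("modifications,charge,score,mass_error_ppm,accession,s1",
               ",2,1,0,P1,5"), g)
  expect_error(read_peptide_table(g), "sequence")
})

test_that("abundance problems are reported per row, not silently dropped", {
  f <- tempfile(fileext = ".csv")
  write_peptide_csv(f, list(
    c("AAAAK", "", 2, 1, 0, "P1", 10, 20),
    c("CCCCK", "", 2, 1, 0, "P1", "oops", 20)))
  expect_error(read_peptide_table(f), "row.*2|2")

  g <- tempfile(fileext = ".csv")
  write_peptide_csv(g, list(
    c("AAAAK", "", 2, 1, 0, "P1", "", 20),
    c("CCCCK", "", 2, 1, 0, "P1", 10, 20)))
  expect_warning(tab <- read_peptide_table(g), "missing")
  expect_equal(nrow(tab), 2L)          # zero-filled, nothing dropped
  expect_equal(tab$s1, c(0, 10))
  expect_error(read_peptide_table(g, strict = TRUE), "missing")
})

test_that("modification strings must be well-formed and consistent", {
  expect_equal(parse_modifications("Succinyl(K3);Oxidation(M7)")[[1L]]$pos,
               c(3L, 7L))
  expect_equal(format_modifications(parse_modifications("Succinyl(K3)")),
               "Succinyl(K3)")
  expect_error(parse_modifications("Succinyl[K3]"), "malformed")
  # out-of-range positions and acyl on non-K are rejected at table level
  f <- tempfile(fileext = ".csv")
  write_peptide_csv(f, list(c("AKA", "Succinyl(K9)", 2, 1, 0, "P1", 1, 1)))
  expect_error(read_peptide_table(f), "position")
  g <- tempfile(fileext = ".csv")
  write_peptide_csv(g, list(c("AKA", "Succinyl(A1)", 2, 1, 0, "P1", 1, 1)))
  expect_error(read_peptide_table(g), "")
})

test_that("FASTA accessions follow UniProt conventions and must be unique", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|X", "MKK"), f)
  expect_equal(read_fasta(f), c(P1 = "MKK"))

  g <- tempfile(fileext = ".fasta")
  writeLines(c(">A1 some description", "macd", ">B2", "WYV"), g)
  fa <- read_fasta(g)
  expect_equal(length(fa), 2L)
  expect_equal(fa[["A1"]], "MACD")  # uppercased

  h <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|X", "MKK", ">P1", "MAA"), h)
  expect_error(read_fasta(h), "duplicated")

  rt <- tempfile(fileext = ".fasta")
  write_fasta(c(Q1 = "MKKAC", Q2 = "MW"), rt)
  expect_equal(read_fasta(rt), c(Q1 = "MKKAC", Q2 = "MW"))
})

test_that("GMT sets are deduplicated and empty sets rejected", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB", "S2\tdesc\tA\tA\tC"), f)
  sets <- read_gmt(f)
  expect_equal(sets$S1, c("A", "B"))
  expect_equal(sets$S2, c("A", "C"))  # duplicate member collapsed

  g <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA", "S2\tdesc"), g)
  expect_error(read_gmt(g), "no members")
})

test_that("study designs enforce roles and group sizes", {
  d <- study_design(data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                               group_id = c("A", "A", "B", "B")),
                    roles = c(vehicle1 = "A", vehicle2 = "B"))
  expect_s3_class(d, "study_design")
  expect_error(study_design(data.frame(sample_id = c("a1", "a1"),
                                       group_id = c("A", "A"))),
               "duplicated")
  expect_error(study_design(data.frame(sample_id = c("a1", "b1"),
                                       group_id = c("A", "B")),
                            roles = c(vehicle1 = "A", vehicle2 = "A")),
               "different")
  expect_error(study_design(data.frame(sample_id = "a1", group_id = "A"),
                            roles = c(vehicle1 = "Z")), "absent")

  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,group_id,role",
               "a1,A,vehicle1", "a2,A,", "b1,B,vehicle2", "b2,B,"), f)
  dd <- read_study_design(f)
  expect_equal(dd$roles[["vehicle1"]], "A")
  out <- tempfile(fileext = ".csv")
  write_study_design(dd, out)
  expect_equal(read_study_design(out), dd)

  tab <- make_peptides("AAAK", abundances = list(a1 = 1, a2 = 1, b1 = 1))
  expect_error(validate_design(dd, tab), "b2")
  tab2 <- make_peptides("AAAK", abundances = list(a1 = 1, a2 = 1,
                                                  b1 = 1, b2 = 1))
  expect_true(validate_design(dd, tab2))
  expect_error(validate_design(dd, tab2, require_roles = "model"),
               "model")
})
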