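# Independently coded scalar truth table for the attenuation rules, written
# directly from the verbal rules rather than sharing code with the package:
# severity from |model dev| against 10/25/50% (boundary in the milder
# class), attenuation = return back over the crossed threshold toward
# control, residual bands with the same boundary convention, one asterisk
# per extra threshold passed on the way back.
truth_classify <- function(md, td) {
  amd <- abs(md); atd <- abs(td)
  severity <- if (amd > 0.50) "severe" else if (amd > 0.25) "moderate"
  else if (amd > 0.10) "mild" else "none"
  crossed <- switch(severity, none = NA_real_, mild = 0.10,
                    moderate = 0.25, severe = 0.50)
  attenuated <- !is.na(crossed) && atd < crossed && atd < amd
  residual <- if (!attenuated) "none"
  else if (atd < 0.10) "lt10" else if (atd < 0.25) "10to25" else "25to50"
  sev_i <- match(severity, c("none", "mild", "moderate", "severe")) - 1L
  res_i <- match(residual, c("lt10", "10to25", "25to50"))
  asterisks <- if (attenuated) (sev_i - 1L) - (res_i - 1L) else 0L
  list(severity = severity, residual = residual,
       asterisks = asterisks, attenuated = attenuated)
}

test_that("vehicle concordance uses the symmetric relative difference", {
  expect_true(vehicle_concordance(100, 100))
  expect_true(vehicle_concordance(100, 110))   # gap 10/105 ~ 9.52%
  expect_false(vehicle_concordance(100, 111))  # gap 11/105.5 ~ 10.43%
  expect_equal(vehicle_concordance(100, 110), vehicle_concordance(110, 100))
  expect_error(vehicle_concordance(0, 10), "positive")
  expect_equal(vehicle_concordance(c(100, 100), c(110, 120)), c(TRUE, FALSE))
})

test_that("worked attenuation cases land in the documented bands", {
  # unchanged
  r <- classify_attenuation(100, 100, 100)
  expect_equal(r$severity, "none"); expect_false(r$attenuated)
  expect_equal(r$asterisks, 0L)
  # severe (+60%) returning to within 10%: the double-asterisk case
  r <- classify_attenuation(100, 160, 105)
  expect_equal(r$severity, "severe")
  expect_equal(r$residual_band, "lt10")
  expect_true(r$attenuated); expect_equal(r$asterisks, 2L)
  # moderate (-30%) returning to -15%
  r <- classify_attenuation(100, 70, 85)
  expect_equal(r$severity, "moderate")
  expect_equal(r$residual_band, "10to25")
  expect_true(r$attenuated); expect_equal(r$asterisks, 0L)
  # moderate (+40%) with |treated| = 38% >= 25%: no attenuation
  r <- classify_attenuation(100, 140, 138)
  expect_equal(r$severity, "moderate"); expect_false(r$attenuated)
  # mild (+12%) to +4%
  r <- classify_attenuation(100, 112, 104)
  expect_equal(r$severity, "mild")
  expect_equal(r$residual_band, "lt10")
  expect_true(r$attenuated); expect_equal(r$asterisks, 0L)
  # boundary values fall in the milder class
  expect_equal(classify_attenuation(100, 110, 100)$severity, "none")
  expect_equal(classify_attenuation(100, 150, 120)$residual_band, "10to25")
  expect_error(classify_attenuation(0, 1, 1), "positive")
})

test_that("classification is symmetric under sign flip of both deviations", {
  set.seed(401)
  md <- runif(200, -1, 1); td <- runif(200, -1, 1)
  a <- classify_attenuation(100, 100 * (1 + md), 100 * (1 + td))
  b <- classify_attenuation(100, 100 * (1 - md), 100 * (1 - td))
  expect_equal(a$severity, b$severity)
  expect_equal(a$residual_band, b$residual_band)
  expect_equal(a$asterisks, b$asterisks)
  expect_equal(a$attenuated, b$attenuated)
})

test_that("shrinking |treated| never reduces asterisks nor revokes attenuation", {
  md_grid <- seq(-1, 1, by = 0.07)
  td_grid <- seq(0, 1, by = 0.01)
  for (md in md_grid) {
    r <- classify_attenuation(100, 100 * (1 + md), 100 * (1 + td_grid))
    # traverse treated deviations from large to small
    o <- order(td_grid, decreasing = TRUE)
    expect_true(all(diff(r$asterisks[o]) >= 0))
    expect_true(all(diff(r$attenuated[o]) >= 0))  # FALSE -> TRUE only
  }
})

test_that("grid classification matches the independent truth table", {
  md <- rep(seq(-1, 1, by = 0.05), each = 41)
  td <- rep(seq(-1, 1, by = 0.05), times = 41)
  got <- classify_attenuation(1000, 1000 * (1 + md), 1000 * (1 + td))
  for (i in seq_along(md)) {
    # classify the deviations as the classifier recomputed them, so both
    # routes see bit-identical inputs at the band boundaries
    want <- truth_classify(got$model_deviation[i], got$treated_deviation[i])
    expect_equal(got$severity[i], want$severity)
    expect_equal(got$residual_band[i], want$residual)
    expect_equal(got$asterisks[i], want$asterisks)
    expect_equal(got$attenuated[i], want$attenuated)
  }
})

test_that("attenuation tables filter discordant vehicles and flag multi-peptide genes", {
  design <- make_cotreat_design(2L)
  sids <- design$samples$sample_id
  val <- function(v1, v2, mk, co)
    setNames(rep(c(v1, v2, mk, co), each = 2L), sids)
  feats <- rbind(
    val(100, 100, 160, 105),   # severe -> lt10 (**)          [P1]
    val(100, 100, 170, 104),   # severe -> lt10 (**)          [P1] again
    val(100, 130, 150, 100),   # discordant vehicles: excluded
    val(100, 100, 140, 120),   # moderate -> 10to25           [P2]
    val(100, 100, 105, 104))   # not dysregulated             [P2]
  ab <- lapply(setNames(sids, sids), function(s) feats[, s])
  tab <- make_peptides(c("AAKQA", "CCKDC", "DDKED", "EEKFE", "FFKGF"),
                       modifications = c("Succinyl(K3)", "Succinyl(K3)",
                                         "Succinyl(K3)", "Malonyl(K3)",
                                         "Malonyl(K3)"),
                       accession = c("P1", "P1", "P1", "P2", "P2"),
                       abundances = ab)
  at <- attenuation_table(tab, design)
  expect_s3_class(at, "attenuation_table")
  expect_equal(nrow(at), 4L)                       # one excluded
  expect_equal(attr(at, "excluded")$reason, "vehicle_discordant")
  expect_equal(sum(at$attenuated), 3L)
  expect_equal(at$asterisks[at$feature == 1L], 2L)
  expect_equal(at$asterisks[at$feature == 2L], 2L)
  expect_equal(at$residual_band[at$feature == 4L], "10to25")
  expect_equal(at$severity[at$feature == 5L], "none")
  # P1 contributed two attenuated peptides, P2 only one
  expect_true(all(at$multi_peptide[at$feature %in% c(1L, 2L)]))
  expect_false(any(at$multi_peptide[at$feature %in% c(4L, 5L)]))
  # every concordant site sits in exactly one partition cell
  part <- (at$severity == "none") + (at$severity != "none" & !at$attenuated) +
    (at$attenuated & at$residual_band != "none")
  expect_equal(part, rep(1L, nrow(at)))
  # banded export carries the asterisk strings
  fmt <- format_attenuation_table(at)
  expect_equal(sort(fmt$asterisks[fmt$gene == "P1"]), c("**", "**"))
  # missing roles are a configuration error
  d2 <- study_design(design$samples, roles = c(vehicle1 = "vehicle1",
                                               vehicle2 = "vehicle2"))
  expect_error(attenuation_table(tab, d2), "model")
  # all sites discordant -> empty table
  feats2 <- feats; feats2[, sids[3:4]] <- feats2[, sids[1:2]] * 1.5
  ab2 <- lapply(setNames(sids, sids), function(s) feats2[, s])
  tab2 <- tab
  for (s in sids) tab2[[s]] <- ab2[[s]]
  at2 <- attenuation_table(tab2, design)
  expect_equal(nrow(at2), 0L)
})
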