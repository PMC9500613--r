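.SEVERITY_LEVELS <- c("none", "mild", "moderate", "severe")
.RESIDUAL_LEVELS <- c("lt10", "10to25", "25to50", "none")

#' Vehicle concordance filter
#'
#' A feature enters the attenuation analysis only when its two vehicle-group
#' means agree to within the tolerance.  Agreement is measured as the
#' symmetric relative difference `|v1 - v2| / ((v1 + v2) / 2)`, which is
#' independent of the order of the two vehicles.
#'
#' @param mean_v1,mean_v2 positive vehicle-group means (vectorized).
#' @param tolerance maximum allowed relative difference (default 0.10).
#' @return Logical vector: `TRUE` where the pair is concordant.
#' @examples
#' vehicle_concordance(100, 110)  # TRUE  (gap ~ 9.5%)
#' vehicle_concordance(100, 111)  # FALSE (gap ~ 10.4%)
#' @export
vehicle_concordance <- function(mean_v1, mean_v2, tolerance = 0.10) {
  if (any(mean_v1 <= 0) || any(mean_v2 <= 0))
    stop("vehicle means must be positive")
  abs(mean_v1 - mean_v2) / ((mean_v1 + mean_v2) / 2) <= tolerance
}

#' Classify dysregulation severity and co-treatment attenuation
#'
#' Implements the threshold-band attenuation classifier.  Deviations of the
#' insult ("model") and co-treatment ("treated") group means from the
#' baseline (the average of the two vehicle controls) are expressed as
#' signed fractions.  Severity follows the magnitude of the model
#' deviation: `none` at or below the first band (10%), then `mild`,
#' `moderate`, and `severe` above the last band (50%), in either direction.
#' A site is attenuated when it was dysregulated and the co-treatment
#' deviation returns back over the threshold its severity crossed
#' (`|treated| < band[severity]`) while moving toward control
#' (`|treated| < |model|`).  Attenuated sites fall into a residual band
#' (`lt10`, `10to25`, `25to50`) and earn one asterisk for each additional
#' threshold passed on the way back: `asterisks = severity index - residual
#' index`, so `**` marks exactly the severe (>±50%) disturbances that
#' return to within ±10% of control.
#'
#' Boundary values land in the milder class: a model deviation of exactly
#' 10% is not dysregulated, and a residual of exactly 10% is not `lt10`.
#'
#' @param baseline positive baseline values (average of the two vehicle
#'   means); vectorized.
#' @param model_mean,treated_mean group means of the insult and co-treatment
#'   conditions.
#' @param bands strictly increasing thresholds (default `c(0.10, 0.25,
#'   0.50)`).
#' @return Data frame with columns `baseline`, `model_deviation`,
#'   `treated_deviation`, `severity`, `residual_band`, `asterisks`,
#'   `attenuated`.  `residual_band` is `"none"` for non-attenuated rows.
#' @examples
#' classify_attenuation(100, 160, 105)  # severe -> lt10: attenuated, **
#' classify_attenuation(100, 70, 85)    # moderate -> 10to25: attenuated
#' classify_attenuation(100, 140, 138)  # moderate, not attenuated
#' @export
classify_attenuation <- function(baseline, model_mean, treated_mean,
                                 bands = c(0.10, 0.25, 0.50)) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  stopifnot(length(bands) == 3L, !is.unsorted(bands, strictly = TRUE))
  k <- max(length(baseline), length(model_mean), length(treated_mean))
  baseline <- rep_len(baseline, k)
  model_mean <- rep_len(model_mean, k)
  treated_mean <- rep_len(treated_mean, k)
  md <- (model_mean - baseline) / baseline
  td <- (treated_mean - baseline) / baseline
  ## severity index: number of bands strictly exceeded by |model deviation|
  sev_idx <- rowSums(outer(abs(md), bands, `>`))
  ## residual index: number of bands at or below |treated deviation|
  res_idx <- rowSums(outer(abs(td), bands, `>=`))
  attenuated <- sev_idx > 0L &
    abs(td) < bands[pmax(sev_idx, 1L)] &
    abs(td) < abs(md)
  asterisks <- ifelse(attenuated, (sev_idx - 1L) - res_idx, 0L)
  residual <- ifelse(attenuated, .RESIDUAL_LEVELS[res_idx + 1L], "none")
  data.frame(baseline = baseline,
             model_deviation = md,
             treated_deviation = td,
             severity = .SEVERITY_LEVELS[sev_idx + 1L],
             residual_band = residual,
             asterisks = as.integer(asterisks),
             attenuated = attenuated,
             stringsAsFactors = FALSE)
}

#' Attenuation table for a co-treatment experiment
#'
#' Applies the full attenuation procedure to every acyl-modified peptide:
#' the two vehicle groups are checked for concordance
#' ([vehicle_concordance()]), their average becomes the baseline, and the
#' model (insult) and treatment (co-treatment) group means are classified
#' by [classify_attenuation()].  Group means are taken on the linear scale
#' of the normalized abundances.  When a proteome is supplied, peptide
#' modifications are mapped to protein site coordinates; proteins
#' contributing more than one attenuated peptide are flagged.
#'
#' @param peptides a filtered, normalized `peptide_table`.
#' @param design a [study_design] declaring the roles `vehicle1`,
#'   `vehicle2`, `model`, `treatment`.
#' @param thresholds an [acyl_thresholds].
#' @param proteome optional accession -> sequence vector for site mapping.
#' @param anova_filter additionally require ANOVA significance across the
#'   four role groups (default `FALSE`: pure threshold rules).
#' @return An `attenuation_table` data frame, one row per concordant
#'   modified peptide: `feature`, `accession`, `position` (protein site, NA
#'   without proteome), `ptm`, `sequence`, the [classify_attenuation()]
#'   columns, and `multi_peptide` (`TRUE` where the protein has more than
#'   one attenuated peptide).  Discordant or non-positive-mean features are
#'   recorded in `attr(x, "excluded")`.
#' @export
attenuation_table <- function(peptides, design,
                              thresholds = acyl_thresholds(),
                              proteome = NULL,
                              anova_filter = FALSE) {
  validate_design(design, peptides,
                  require_roles = c("vehicle1", "vehicle2", "model",
                                    "treatment"))
  roles <- design$roles
  mat <- abundance_matrix(peptides)
  gm <- group_means(mat, design)
  idx <- which(is_modified(peptides))
  if (anova_filter && length(idx)) {
    dd <- call_differential(peptides, design, thresholds,
                            reference_group = roles[["vehicle1"]])
    idx <- intersect(idx, dd$feature[dd$significant])
  }
  v1 <- gm[idx, roles[["vehicle1"]]]
  v2 <- gm[idx, roles[["vehicle2"]]]
  positive <- v1 > 0 & v2 > 0
  conc <- rep(FALSE, length(idx))
  conc[positive] <- vehicle_concordance(v1[positive], v2[positive],
                                        thresholds$vehicle_tolerance)
  excluded <- data.frame(feature = idx[!conc],
                         reason = ifelse(positive[!conc],
                                         "vehicle_discordant",
                                         "nonpositive_vehicle_mean"),
                         stringsAsFactors = FALSE)
  keep <- idx[conc]
  cls <- classify_attenuation(baseline = (gm[keep, roles[["vehicle1"]]] +
                                            gm[keep, roles[["vehicle2"]]]) / 2,
                              model_mean = gm[keep, roles[["model"]]],
                              treated_mean = gm[keep, roles[["treatment"]]],
                              bands = thresholds$bands)
  pos <- rep(NA_integer_, length(keep))
  if (!is.null(proteome) && length(keep)) {
    sub <- peptides[keep, , drop = FALSE]
    attr(sub, "sample_ids") <- attr(peptides, "sample_ids")
    class(sub) <- class(peptides)
    sites <- map_sites(sub, proteome, first_match = TRUE)
    first_site <- function(j) {
      mods <- peptides$modifications[[keep[j]]]
      p <- acyl_positions(mods)[1L]
      hit <- regexpr(peptides$sequence[keep[j]],
                     proteome[[peptides$accession[keep[j]]]], fixed = TRUE)
      as.integer(hit + p - 1L)
    }
    pos <- vapply(seq_along(keep), first_site, 0L)
  }
  out <- data.frame(feature = keep,
                    accession = peptides$accession[keep],
                    position = pos,
                    ptm = acyl_type(peptides)[keep],
                    sequence = peptides$sequence[keep],
                    stringsAsFactors = FALSE)
  out <- cbind(out, cls)
  n_att <- table(out$accession[out$attenuated])
  out$multi_peptide <- out$attenuated &
    out$accession %in% names(n_att)[n_att > 1L]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "thresholds") <- thresholds
  class(out) <- c("attenuation_table", "data.frame")
  out
}

#' @export
print.attenuation_table <- function(x, ...) {
  cat(sprintf("Attenuation table: %d concordant modified peptides (%d excluded), %d dysregulated, %d attenuated\n",
              nrow(x), nrow(attr(x, "excluded")),
              sum(x$severity != "none"), sum(x$attenuated)))
  att <- x[x$attenuated, , drop = FALSE]
  for (band in c("lt10", "10to25", "25to50")) {
    rows <- att[att$residual_band == band, , drop = FALSE]
    label <- c(lt10 = "<10%", `10to25` = "10-25%", `25to50` = "25-50%")[band]
    if (!nrow(rows)) next
    cat(sprintf("  returned to %s of control:\n", label))
    for (i in seq_len(nrow(rows)))
      cat(sprintf("    %s%s (%s%s)\n", rows$accession[i],
                  strrep("*", rows$asterisks[i]), rows$ptm[i],
                  if (rows$multi_peptide[i]) ", multiple peptides" else ""))
  }
  invisible(x)
}

#' Render an attenuation table in the banded layout
#'
#' Produces the long-format export with one row per attenuated peptide:
#' columns `ptm`, `band`, `gene` (accession), `asterisks`,
#' `multi_peptide`.
#'
#' @param x an `attenuation_table`.
#' @param path optional TSV output file.
#' @return The long-format data frame, invisibly if written to `path`.
#' @export
format_attenuation_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "attenuation_table"))
  att <- x[x$attenuated, , drop = FALSE]
  out <- data.frame(ptm = att$ptm,
                    band = att$residual_band,
                    gene = att$accession,
                    position = att$position,
                    asterisks = strrep("*", att$asterisks),
                    multi_peptide = att$multi_peptide,
                    stringsAsFactors = FALSE)
  out <- out[order(out$ptm, match(out$band, .RESIDUAL_LEVELS), out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
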