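## Residues used to build peptide bodies: no K/R (cleavage sites) and no P
## (would trigger the KP exception), so missed-cleavage counts are exactly
## what the construction plants.
.BODY_ALPHABET <- setdiff(strsplit("ACDEFGHILMNQSTVWY", "")[[1L]], character())

random_body <- function(len) {
  paste(sample(.BODY_ALPHABET, len, replace = TRUE), collapse = "")
}

draw_in_band <- function(n, lo, hi) runif(n, lo, hi)

#' Simulate a co-treatment acylation proteomics experiment
#'
#' Generates a peptide-level quantitation table with the statistical
#' structure the pipeline assumes, together with the matching protein FASTA
#' sequences, study design, and a ground-truth table for recovery
#' benchmarking.  The design mirrors a cell-culture co-treatment study:
#' two vehicle control groups, an insult ("model", e.g. MK-801) group, and
#' a co-treatment ("treatment") group, each with `n_replicates_per_group`
#' samples.
#'
#' Each protein is a concatenation of tryptic peptides (bodies free of
#' K/R/P, terminated by K or R); modified peptides carry one succinyl or
#' malonyl mark on an internal lysine, so every generated peptide has zero
#' missed cleavages under the modified-lysine convention.  Peptide baseline
#' intensities are drawn log-uniformly over four decades.  For a modified
#' peptide the four planted group means are `baseline * (1 + deviation)`
#' with deviations drawn per planted class: concordant vehicle pairs are
#' identical (discordant pairs differ by a planted gap above the
#' tolerance), dysregulated sites draw their model deviation uniformly
#' inside the planted severity band (keeping `boundary_margin` away from
#' the thresholds), and attenuated sites draw a residual deviation inside a
#' feasible residual band; non-attenuated dysregulated sites keep the model
#' deviation under co-treatment.  Observed abundances are the planted means
#' times `2^N(0, noise_sigma)`.
#'
#' @param n_proteins number of proteins.
#' @param peptides_per_protein inclusive integer range, peptides drawn
#'   uniformly per protein.
#' @param frac_modified_peptides fraction of peptides carrying an acyl
#'   modification.
#' @param ptm_mix named proportions for `succinyl`/`malonyl` (sum 1).
#' @param n_replicates_per_group replicates per group (>= 2).
#' @param noise_sigma log2-scale standard deviation of the multiplicative
#'   noise.
#' @param frac_dysregulated fraction of modified (concordant) peptides
#'   planted as dysregulated by the insult.
#' @param effect_band_mix proportions of mild/moderate/severe among
#'   dysregulated sites.
#' @param frac_attenuated_given_dysregulated probability that a
#'   dysregulated site is attenuated by the co-treatment.
#' @param residual_band_mix proportions of lt10/10to25/25to50 residual
#'   bands (renormalized over the bands feasible for the site's severity).
#' @param vehicle_discordance_rate fraction of modified peptides whose
#'   vehicle pair violates the concordance tolerance.
#' @param bands dysregulation thresholds (default 10/25/50%).
#' @param boundary_margin minimum distance of planted deviations from band
#'   boundaries.
#' @param severe_max upper limit of planted severe deviations.
#' @param baseline_log10_range range of log10 baseline intensities.
#' @param seed integer seed; the output is deterministic given the seed.
#' @return List of class `acyl_simulation` with elements `peptides` (a
#'   `peptide_table`), `proteome` (named character vector), `design` (a
#'   [study_design] with all four roles), `truth` (data frame, one row per
#'   modified peptide: `feature`, `accession`, `position`, `ptm`,
#'   `vehicle_gap`, `concordant`, `model_deviation`, `treated_deviation`,
#'   `severity`, `residual_band`, `asterisks`, `attenuated`,
#'   `differential`), and `protein_direction` (named vector of planted
#'   Up/Down/Both per protein with dysregulated sites).
#' @export
simulate_acyl_experiment <- function(n_proteins = 500,
                                     peptides_per_protein = c(4L, 10L),
                                     frac_modified_peptides = 0.07,
                                     ptm_mix = c(succinyl = 0.6,
                                                 malonyl = 0.4),
                                     n_replicates_per_group = 3L,
                                     noise_sigma = 0.1,
                                     frac_dysregulated = 0.30,
                                     effect_band_mix = c(mild = 1, moderate = 1,
                                                         severe = 1) / 3,
                                     frac_attenuated_given_dysregulated = 0.5,
                                     residual_band_mix = c(lt10 = 1,
                                                           `10to25` = 1,
                                                           `25to50` = 1) / 3,
                                     vehicle_discordance_rate = 0.10,
                                     bands = c(0.10, 0.25, 0.50),
                                     boundary_margin = 0.02,
                                     severe_max = 1.0,
                                     baseline_log10_range = c(4, 8),
                                     seed = NULL) {
  stopifnot(n_proteins >= 1L, length(peptides_per_protein) == 2L,
            peptides_per_protein[1L] >= 1L,
            peptides_per_protein[2L] >= peptides_per_protein[1L],
            frac_modified_peptides >= 0, frac_modified_peptides <= 1,
            n_replicates_per_group >= 2L,
            noise_sigma >= 0,
            frac_dysregulated >= 0, frac_dysregulated <= 1,
            frac_attenuated_given_dysregulated >= 0,
            frac_attenuated_given_dysregulated <= 1,
            vehicle_discordance_rate >= 0, vehicle_discordance_rate <= 1,
            boundary_margin > 0, boundary_margin < min(diff(c(0, bands))) / 2,
            severe_max > bands[3L] + boundary_margin)
  stopifnot(abs(sum(ptm_mix) - 1) < 1e-8, abs(sum(effect_band_mix) - 1) < 1e-8,
            abs(sum(residual_band_mix) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)

  groups <- c("vehicle1", "vehicle2", "model", "treatment")
  samples <- data.frame(
    sample_id = paste0(rep(c("V1_", "V2_", "MK_", "CO_"),
                           each = n_replicates_per_group),
                       seq_len(n_replicates_per_group)),
    group_id = rep(groups, each = n_replicates_per_group),
    stringsAsFactors = FALSE)
  design <- study_design(samples, roles = setNames(groups, groups))

  band_lims <- list(mild = c(bands[1L], bands[2L]),
                    moderate = c(bands[2L], bands[3L]),
                    severe = c(bands[3L], severe_max))
  res_lims <- list(lt10 = c(0, bands[1L]),
                   `10to25` = c(bands[1L], bands[2L]),
                   `25to50` = c(bands[2L], bands[3L]))
  feasible_res <- list(mild = "lt10",
                       moderate = c("lt10", "10to25"),
                       severe = c("lt10", "10to25", "25to50"))

  truth_rows <- list()
  proteome <- character(n_proteins)
  accs <- sprintf("SYN%04d", seq_len(n_proteins))
  pep_range <- seq.int(peptides_per_protein[1L], peptides_per_protein[2L])
  npep_all <- pep_range[sample.int(length(pep_range), n_proteins,
                                   replace = TRUE)]
  n_total <- sum(npep_all)
  col <- list(sequence = character(n_total), modifications = character(n_total),
              charge = integer(n_total), score = numeric(n_total),
              mass_error_ppm = numeric(n_total), accession = character(n_total))
  ab_mat <- matrix(0, n_total, nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
  row_id <- 0L

  for (pi in seq_len(n_proteins)) {
    npep <- npep_all[pi]
    repeat {
      seqs <- character(npep)
      mod_pos <- rep(NA_integer_, npep)
      modified <- runif(npep) < frac_modified_peptides
      for (j in seq_len(npep)) {
        if (modified[j]) {
          left <- random_body(sample(4:8, 1L))
          right <- random_body(sample(3:6, 1L))
          seqs[j] <- paste0(left, "K", right, "R")
          mod_pos[j] <- nchar(left) + 1L
        } else {
          seqs[j] <- paste0(random_body(sample(6:12, 1L)),
                            sample(c("K", "R"), 1L))
        }
      }
      prot <- paste0("M", paste(seqs, collapse = ""))
      ## each peptide must occur exactly once for unambiguous site mapping
      ok <- !anyDuplicated(seqs) &&
        all(vapply(seqs, function(s)
          length(gregexpr(s, prot, fixed = TRUE)[[1L]]) == 1L, NA))
      if (ok) break
    }
    proteome[pi] <- prot
    offset <- cumsum(c(2L, nchar(seqs)))[seq_len(npep)]  # peptide starts

    for (j in seq_len(npep)) {
      row_id <- row_id + 1L
      B <- 10^runif(1L, baseline_log10_range[1L], baseline_log10_range[2L])
      if (modified[j]) {
        ptm <- sample(names(ptm_mix), 1L, prob = ptm_mix)
        discordant <- runif(1L) < vehicle_discordance_rate
        gap <- if (discordant)
          runif(1L, 0.10 + boundary_margin, 0.30) else 0
        gap_sign <- sample(c(-1, 1), 1L)
        md <- 0; td <- 0
        severity <- "none"; res_band <- "none"; ast <- 0L; att <- FALSE
        if (!discordant && runif(1L) < frac_dysregulated) {
          severity <- sample(names(effect_band_mix), 1L,
                             prob = effect_band_mix)
          lim <- band_lims[[severity]]
          md <- sample(c(-1, 1), 1L) *
            draw_in_band(1L, lim[1L] + boundary_margin,
                         lim[2L] - if (severity == "severe") 0 else
                           boundary_margin)
          if (runif(1L) < frac_attenuated_given_dysregulated) {
            att <- TRUE
            feas <- feasible_res[[severity]]
            w <- residual_band_mix[feas] / sum(residual_band_mix[feas])
            res_band <- sample(feas, 1L, prob = w)
            rl <- res_lims[[res_band]]
            td <- sample(c(-1, 1), 1L) *
              draw_in_band(1L, if (res_band == "lt10") 0 else
                rl[1L] + boundary_margin, rl[2L] - boundary_margin)
            ast <- match(severity, names(band_lims)) - match(res_band, names(res_lims))
          } else {
            td <- md
          }
        }
        means <- c(vehicle1 = B * (1 + gap_sign * gap / 2),
                   vehicle2 = B * (1 - gap_sign * gap / 2),
                   model = B * (1 + md),
                   treatment = B * (1 + td))
        mods_str <- sprintf("%s(K%d)",
                            c(succinyl = "Succinyl",
                              malonyl = "Malonyl")[[ptm]], mod_pos[j])
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          feature = row_id, accession = accs[pi],
          position = offset[j] + mod_pos[j] - 1L, ptm = ptm,
          vehicle_gap = gap, concordant = !discordant,
          model_deviation = md, treated_deviation = td,
          severity = severity, residual_band = res_band,
          asterisks = as.integer(ast), attenuated = att,
          differential = discordant || md != 0 || td != 0,
          stringsAsFactors = FALSE)
      } else {
        ptm <- ""
        mods_str <- ""
        means <- c(vehicle1 = B, vehicle2 = B, model = B, treatment = B)
      }
      ## scale standard normals so the same seed plants the same truth at
      ## every noise level (sd = 0 draws would skip the RNG stream)
      noise <- 2^(noise_sigma * rnorm(nrow(samples)))
      ab_mat[row_id, ] <- means[samples$group_id] * noise
      col$sequence[row_id] <- seqs[j]
      col$modifications[row_id] <- mods_str
      col$charge[row_id] <- sample(2:4, 1L)
      col$score[row_id] <- round(runif(1L, 5, 60), 2L)
      col$mass_error_ppm[row_id] <- round(runif(1L, -10, 10), 3L)
      col$accession[row_id] <- accs[pi]
    }
  }

  df <- data.frame(sequence = col$sequence,
                   charge = col$charge,
                   score = col$score,
                   mass_error_ppm = col$mass_error_ppm,
                   accession = col$accession,
                   stringsAsFactors = FALSE)
  df$modifications <- parse_modifications(col$modifications)
  df <- df[, c("sequence", "modifications", "charge", "score",
               "mass_error_ppm", "accession")]
  for (s in samples$sample_id) df[[s]] <- ab_mat[, s]
  peptides <- new_peptide_table(df, samples$sample_id)
  validate_peptide_table(peptides)

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(feature = integer(), accession = character(),
               position = integer(), ptm = character(),
               vehicle_gap = numeric(), concordant = logical(),
               model_deviation = numeric(), treated_deviation = numeric(),
               severity = character(), residual_band = character(),
               asterisks = integer(), attenuated = logical(),
               differential = logical(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  dys <- truth[truth$severity != "none", , drop = FALSE]
  protein_direction <- if (nrow(dys)) {
    vapply(split(sign(dys$model_deviation), dys$accession), function(s) {
      u <- unique(s)
      if (length(u) > 1L) "Both" else if (u > 0) "Up" else "Down"
    }, "")
  } else setNames(character(), character())

  structure(list(peptides = peptides,
                 proteome = setNames(proteome, accs),
                 design = design,
                 truth = truth,
                 protein_direction = protein_direction),
            class = "acyl_simulation")
}

#' @export
print.acyl_simulation <- function(x, ...) {
  cat(sprintf("Simulated acylation experiment: %d peptides / %d proteins / %d samples\n",
              nrow(x$peptides), length(x$proteome),
              nrow(x$design$samples)))
  cat(sprintf("  modified peptides : %d (%d concordant, %d dysregulated, %d attenuated)\n",
              nrow(x$truth), sum(x$truth$concordant),
              sum(x$truth$severity != "none"), sum(x$truth$attenuated)))
  invisible(x)
}

#' Write a simulated experiment to files
#'
#' Emits the canonical inputs: peptide-table CSV, protein FASTA, design CSV
#' and a truth JSON.
#'
#' @param sim an `acyl_simulation`.
#' @param dir output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "acyl_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(peptides = file.path(dir, "peptides.csv"),
             fasta = file.path(dir, "proteins.fasta"),
             design = file.path(dir, "design.csv"),
             truth = file.path(dir, "truth.json"))
  write_peptide_table(sim$peptides, paths[["peptides"]])
  write_fasta(sim$proteome, paths[["fasta"]])
  write_study_design(sim$design, paths[["design"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], digits = NA,
                       dataframe = "rows")
  paths
}

f1_score <- function(truth, pred) {
  tp <- sum(truth & pred)
  prec <- if (sum(pred) == 0L) NA_real_ else tp / sum(pred)
  rec <- if (sum(truth) == 0L) NA_real_ else tp / sum(truth)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

#' Compare pipeline outputs with planted ground truth
#'
#' Matches attenuation calls and differential results with the simulator's
#' truth table by site key (accession, position, PTM) and reports
#' exact-band accuracies and precision/recall/F1 per task.  Band accuracies
#' are computed over the sites present in both the truth (concordant on
#' planted means) and the pipeline's table (concordant on observed means);
#' for the binary tasks, truth-positive sites missing from the pipeline
#' table count as misses.
#'
#' @param attenuation an `attenuation_table` (with `position` mapped).
#' @param differential an `acyl_differential` or `NULL` to skip the
#'   differential task.
#' @param truth the simulator's truth data frame.
#' @return A `recovery_metrics` list: `n_matched`, `severity_accuracy`,
#'   `residual_accuracy`, `asterisk_accuracy`, and rows `attenuated`,
#'   `double_asterisk`, `differential` each with precision/recall/F1.
#' @export
evaluate_recovery <- function(attenuation, differential = NULL, truth) {
  stopifnot(inherits(attenuation, "attenuation_table"),
            is.data.frame(truth))
  if (any(is.na(attenuation$position)))
    stop("attenuation table lacks mapped positions; run with a proteome")
  tkey <- paste(truth$accession, truth$position, truth$ptm)
  pkey <- paste(attenuation$accession, attenuation$position,
                attenuation$ptm)
  if (length(setdiff(pkey, tkey)))
    stop("attenuation table contains sites absent from the truth")
  tc <- truth[truth$concordant, , drop = FALSE]
  tckey <- paste(tc$accession, tc$position, tc$ptm)
  m <- match(pkey, tckey)
  matched <- !is.na(m)
  acc_of <- function(pred, tru) mean(pred[matched] == tru[m[matched]])
  sev_acc <- acc_of(attenuation$severity, tc$severity)
  res_acc <- acc_of(attenuation$residual_band, tc$residual_band)
  ast_acc <- acc_of(attenuation$asterisks, tc$asterisks)

  bin_task <- function(truth_pos_keys, pred_pos_keys) {
    all_keys <- tkey
    f1_score(all_keys %in% truth_pos_keys, all_keys %in% pred_pos_keys)
  }
  att_task <- bin_task(tckey[tc$attenuated],
                       pkey[attenuation$attenuated])
  dd_task <- bin_task(tckey[tc$attenuated & tc$asterisks == 2L],
                      pkey[attenuation$attenuated &
                             attenuation$asterisks == 2L])
  diff_task <- NULL
  if (!is.null(differential)) {
    ## differential results are per peptide row; truth features are rows too
    diff_task <- f1_score(truth$differential,
                          truth$feature %in%
                            differential$feature[differential$significant])
  }
  structure(list(n_truth_sites = nrow(truth),
                 n_matched = sum(matched),
                 severity_accuracy = sev_acc,
                 residual_accuracy = res_acc,
                 asterisk_accuracy = ast_acc,
                 attenuated = att_task,
                 double_asterisk = dd_task,
                 differential = diff_task),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("Recovery vs planted truth (%d sites, %d matched):\n",
              x$n_truth_sites, x$n_matched))
  cat(sprintf("  severity band accuracy : %.3f\n", x$severity_accuracy))
  cat(sprintf("  residual band accuracy : %.3f\n", x$residual_accuracy))
  cat(sprintf("  asterisk accuracy      : %.3f\n", x$asterisk_accuracy))
  for (task in c("attenuated", "double_asterisk", "differential")) {
    v <- x[[task]]
    if (is.null(v)) next
    cat(sprintf("  %-22s : P=%.3f R=%.3f F1=%.3f\n", task,
                v[["precision"]], v[["recall"]], v[["f1"]]))
  }
  invisible(x)
}
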