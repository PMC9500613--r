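## Monoisotopic masses of the elements involved (IUPAC values).
.MONOISOTOPIC <- c(C = 12, H = 1.0078250319, O = 15.9949146221)

## Elemental composition of the added moiety for each supported acyl PTM.
.PTM_COMPOSITION <- list(
  succinyl = c(C = 4, H = 4, O = 3),
  malonyl  = c(C = 3, H = 2, O = 3)
)

#' Monoisotopic mass shift of an acyl modification
#'
#' Succinylation adds C4H4O3 (+100.01604 Da) and malonylation C3H2O3
#' (+86.00039 Da) to the lysine side chain; the masses are computed from the
#' moiety's elemental composition and monoisotopic atomic masses.
#'
#' @param ptm character vector of PTM names (case-insensitive; `"succinyl"`
#'   or `"malonyl"`).
#' @return Numeric vector of mass deltas in Da.
#' @examples
#' ptm_mass_delta("succinyl") - ptm_mass_delta("malonyl")  # one CH2
#' @export
ptm_mass_delta <- function(ptm) {
  key <- tolower(ptm)
  bad <- !key %in% names(.PTM_COMPOSITION)
  if (any(bad))
    stop("unknown PTM '", ptm[bad][1L], "'; supported: ",
         paste(names(.PTM_COMPOSITION), collapse = ", "))
  vapply(key, function(k) {
    comp <- .PTM_COMPOSITION[[k]]
    sum(comp * .MONOISOTOPIC[names(comp)])
  }, 0, USE.NAMES = FALSE)
}

#' Count tryptic missed cleavages with the modified-lysine exclusion
#'
#' Counts internal (non-C-terminal) K/R residues that trypsin should have
#' cleaved but did not.  A lysine carrying an acyl modification blocks
#' cleavage and is not counted; by the standard tryptic convention, K/R
#' followed by proline is not a cleavage site either (flag-controlled).
#'
#' @param sequence peptide sequence (uppercase amino acids).
#' @param modified_k integer positions (1-based) of acyl-modified lysines.
#' @param kp_rule apply the K/R-before-P exception (default `TRUE`).
#' @return Integer count of missed cleavages.
#' @examples
#' count_missed_cleavages("AKLYK")                 # 1: internal K2
#' count_missed_cleavages("AKLYK", modified_k = 2) # 0: K2 is modified
#' count_missed_cleavages("AKPLR")                 # 0: K before P
#' @export
count_missed_cleavages <- function(sequence, modified_k = integer(),
                                   kp_rule = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < 2L) return(0L)
  aa <- strsplit(sequence, "")[[1L]]
  modified_k <- as.integer(modified_k)
  if (length(modified_k) && any(aa[modified_k] != "K"))
    stop("modified_k positions must index lysine residues")
  internal <- seq_len(n - 1L)
  site <- aa[internal] %in% c("K", "R")
  if (kp_rule) site <- site & aa[internal + 1L] != "P"
  site[internal %in% modified_k & aa[internal] == "K"] <- FALSE
  sum(site)
}

acyl_positions <- function(mods) {
  mods$pos[is_acyl(mods$ptm) & mods$residue == "K"]
}

#' Map peptide-level acyl modifications to protein coordinates
#'
#' Locates each peptide in its reported protein sequence and converts the
#' peptide-local modification positions of succinyl/malonyl marks into
#' protein residue positions; non-acyl modifications are ignored.  Sites
#' supported by several peptide ions are merged.
#'
#' @param peptides a `peptide_table`.
#' @param proteome named character vector, accession -> sequence (see
#'   [read_fasta()]).
#' @param first_match if a peptide occurs more than once in its protein, use
#'   the first occurrence instead of raising an ambiguity error.
#' @return A `modification_sites` data frame with columns `accession`,
#'   `position`, `ptm`, `n_peptides`, `peptide_rows` (comma-separated row
#'   indices of supporting peptides).
#' @export
map_sites <- function(peptides, proteome, first_match = FALSE) {
  stopifnot(inherits(peptides, "peptide_table"), is.character(proteome))
  rows <- list()
  for (i in seq_len(nrow(peptides))) {
    pos <- acyl_positions(peptides$modifications[[i]])
    if (!length(pos)) next
    acc <- peptides$accession[i]
    if (!acc %in% names(proteome))
      stop(sprintf("row %d: accession '%s' not in proteome", i, acc))
    prot <- proteome[[acc]]
    hits <- gregexpr(peptides$sequence[i], prot, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L)
      stop(sprintf("row %d: peptide '%s' not found in protein '%s'",
                   i, peptides$sequence[i], acc))
    if (length(hits) > 1L && !first_match)
      stop(sprintf(paste0("row %d: peptide '%s' matches protein '%s' %d times; ",
                          "set first_match = TRUE to take the first"),
                   i, peptides$sequence[i], acc, length(hits)))
    start <- hits[1L]
    mods <- peptides$modifications[[i]]
    acyl <- mods[is_acyl(mods$ptm) & mods$residue == "K", , drop = FALSE]
    prot_pos <- start + acyl$pos - 1L
    res <- substring(prot, prot_pos, prot_pos)
    if (any(res != "K"))
      stop(sprintf("row %d: mapped acyl position is not K in '%s'", i, acc))
    rows[[length(rows) + 1L]] <-
      data.frame(accession = acc, position = prot_pos,
                 ptm = tolower(acyl$ptm), row = i, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(accession = character(), position = integer(),
                      ptm = character(), n_peptides = integer(),
                      peptide_rows = character(), stringsAsFactors = FALSE)
    class(out) <- c("modification_sites", "data.frame")
    return(out)
  }
  all <- do.call(rbind, rows)
  key <- paste(all$accession, all$position, all$ptm, sep = "\r")
  agg <- lapply(split(seq_len(nrow(all)), key), function(idx) {
    data.frame(accession = all$accession[idx[1L]],
               position = all$position[idx[1L]],
               ptm = all$ptm[idx[1L]],
               n_peptides = length(unique(all$row[idx])),
               peptide_rows = paste(sort(unique(all$row[idx])), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$accession, out$position, out$ptm), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("modification_sites", "data.frame")
  out
}

#' Filter peptides by mass error and missed cleavages
#'
#' Applies the post-identification quality rules: absolute peptide mass
#' error must be below `max_mass_error_ppm` (default 20 ppm) and the number
#' of tryptic missed cleavages — counted with acyl-modified lysines excluded
#' — must not exceed `max_missed_cleavages` (default 1).  Every rejected row
#' carries a machine-readable reason; kept and rejected rows partition the
#' input.
#'
#' @param peptides a `peptide_table`.
#' @param thresholds an [acyl_thresholds] object.
#' @param kp_rule passed to [count_missed_cleavages()].
#' @return List with elements `kept` (a `peptide_table`) and `rejected`
#'   (data frame with columns `row`, `sequence`, `reason` where reason is
#'   `"mass_error"` or `"missed_cleavages"`).
#' @export
filter_peptides <- function(peptides, thresholds = acyl_thresholds(),
                            kp_rule = TRUE) {
  stopifnot(inherits(peptides, "peptide_table"),
            inherits(thresholds, "acyl_thresholds"))
  n <- nrow(peptides)
  reason <- character(n)
  bad_ppm <- abs(peptides$mass_error_ppm) >= thresholds$max_mass_error_ppm
  reason[bad_ppm] <- "mass_error"
  mc <- vapply(seq_len(n), function(i) {
    count_missed_cleavages(peptides$sequence[i],
                           acyl_positions(peptides$modifications[[i]]),
                           kp_rule = kp_rule)
  }, 0L)
  bad_mc <- mc > thresholds$max_missed_cleavages & !bad_ppm
  reason[bad_mc] <- "missed_cleavages"
  keep <- reason == ""
  kept <- peptides[keep, , drop = FALSE]
  attr(kept, "sample_ids") <- attr(peptides, "sample_ids")
  class(kept) <- class(peptides)
  rejected <- data.frame(row = which(!keep),
                         sequence = peptides$sequence[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  list(kept = kept, rejected = rejected)
}

#' Export a site list as TSV
#'
#' @param sites a `modification_sites` data frame from [map_sites()].
#' @param path output file.
#' @export
write_sites <- function(sites, path) {
  write.table(sites[, c("accession", "position", "ptm", "n_peptides")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
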