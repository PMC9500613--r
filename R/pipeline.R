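stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full acylation analysis pipeline
#'
#' Orchestrates every stage on one experiment: quality filtering, optional
#' total-abundance normalization, site annotation, Hi-N protein
#' quantitation (on unmodified peptides), ANOVA differential calling of
#' modified peptides, frequency summaries, the attenuation classifier (when
#' the design declares the four roles), and over-representation analysis of
#' the dysregulated proteins (when gene sets are given).  All outputs are
#' written as TSV under `out_dir` together with a JSON run manifest
#' recording thresholds, seed, and per-stage row counts.  Given the same
#' inputs, thresholds and seed, reruns are bitwise identical.
#'
#' @param peptides a `peptide_table` or path to a peptide CSV.
#' @param design a [study_design] or path to a design CSV.
#' @param proteome optional accession -> sequence vector or FASTA path.
#' @param gene_sets optional named list of gene sets or GMT path; query =
#'   accessions with significant modified peptides, background = all
#'   quantified accessions.
#' @param out_dir output directory (created).
#' @param thresholds an [acyl_thresholds].
#' @param normalize apply [normalize_total()] (`FALSE` for pre-normalized
#'   tables such as simulator output).
#' @param anova_filter passed to [attenuation_table()].
#' @param seed integer recorded in the manifest and set before any sampling
#'   (the pipeline itself is deterministic; the seed matters when callers
#'   interleave simulation).
#' @param enrichment if `TRUE` (default when `gene_sets` is given), run
#'   enrichment; requires `gene_sets`.
#' @return Invisibly, a list with the in-memory results: `peptides`
#'   (filtered), `rejected`, `sites`, `protein_quant`, `differential`,
#'   `frequency`, `attenuation`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(peptides, design, proteome = NULL,
                         gene_sets = NULL, out_dir,
                         thresholds = acyl_thresholds(),
                         normalize = TRUE, anova_filter = FALSE,
                         seed = NULL, enrichment = !is.null(gene_sets)) {
  if (enrichment && is.null(gene_sets))
    stop("enrichment requested but no gene sets (GMT) supplied")
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  peptides <- stage("read", {
    if (is.character(peptides)) read_peptide_table(peptides) else peptides
  })
  design <- stage("read", {
    if (is.character(design)) read_study_design(design) else design
  })
  ## a bare unnamed string is a FASTA path; a named vector is the proteome
  if (is.character(proteome) && length(proteome) == 1L &&
      is.null(names(proteome)))
    proteome <- stage("read", read_fasta(proteome))
  if (is.character(gene_sets)) gene_sets <- stage("read", read_gmt(gene_sets))
  stage("read", validate_design(design, peptides))
  n_input <- nrow(peptides)

  flt <- stage("filter", filter_peptides(peptides, thresholds))
  kept <- flt$kept
  if (nrow(kept) == 0L) stop("pipeline stage 'filter' removed every peptide")

  kept <- stage("normalize", {
    if (normalize) set_abundances(kept, normalize_total(abundance_matrix(kept)))
    else kept
  })

  sites <- NULL
  if (!is.null(proteome))
    sites <- stage("annotate", map_sites(kept, proteome, first_match = TRUE))

  prot_quant <- stage("quantify", {
    unmod <- !is_modified(kept)
    if (any(unmod))
      hi_n_protein_quant(abundance_matrix(kept)[unmod, , drop = FALSE],
                         kept$accession[unmod], n = thresholds$hi_n,
                         score = kept$score[unmod],
                         sequence = kept$sequence[unmod])
    else NULL
  })

  differential <- stage("differential",
                        call_differential(kept, design, thresholds))
  freq <- stage("differential", frequency_summary(kept, differential))

  atten <- NULL
  has_roles <- all(c("vehicle1", "vehicle2", "model", "treatment") %in%
                     names(design$roles))
  if (has_roles)
    atten <- stage("attenuation",
                   attenuation_table(kept, design, thresholds,
                                     proteome = proteome,
                                     anova_filter = anova_filter))

  enr <- NULL
  if (enrichment) {
    enr <- stage("enrichment", {
      query <- unique(differential$accession[differential$significant])
      background <- unique(kept$accession)
      if (length(query)) enrich(query, gene_sets, background, thresholds)
      else NULL
    })
  }

  stage("report", {
    write_peptide_table(kept, file.path(out_dir, "peptides_filtered.csv"))
    write.table(flt$rejected, file.path(out_dir, "rejected.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sites)) write_sites(sites, file.path(out_dir, "sites.tsv"))
    if (!is.null(prot_quant))
      write_quant_matrix(prot_quant, file.path(out_dir, "protein_quant.tsv"),
                         id_column = "accession")
    dd <- as.data.frame(differential)
    dd$modifications <- NULL
    write.table(dd, file.path(out_dir, "differential.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(atten)) {
      ad <- as.data.frame(atten)
      write.table(ad, file.path(out_dir, "attenuation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      format_attenuation_table(atten, file.path(out_dir,
                                                "attenuation_bands.tsv"))
    }
    if (!is.null(enr))
      write.table(as.data.frame(enr), file.path(out_dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  })

  manifest <- list(
    package = "acylsite",
    version = as.character(packageVersion("acylsite")),
    seed = if (is.null(seed)) NA else seed,
    thresholds = unclass(thresholds),
    stages = list(
      input_peptides = n_input,
      filtered_kept = nrow(kept),
      filtered_rejected = nrow(flt$rejected),
      sites = if (is.null(sites)) NA else nrow(sites),
      proteins_quantified = if (is.null(prot_quant)) 0L else nrow(prot_quant),
      differential_tested = nrow(differential),
      differential_significant = sum(differential$significant),
      attenuation_concordant = if (is.null(atten)) NA else nrow(atten),
      attenuation_dysregulated = if (is.null(atten)) NA else
        sum(atten$severity != "none"),
      attenuation_attenuated = if (is.null(atten)) NA else
        sum(atten$attenuated),
      enrichment_tested = if (is.null(enr)) NA else nrow(enr),
      enrichment_passing = if (is.null(enr)) NA else sum(enr$passes)))
  stage("report", jsonlite::write_json(manifest,
                                       file.path(out_dir, "manifest.json"),
                                       auto_unbox = TRUE, digits = NA,
                                       pretty = TRUE))

  invisible(list(peptides = kept, rejected = flt$rejected, sites = sites,
                 protein_quant = prot_quant, differential = differential,
                 frequency = freq, attenuation = atten, enrichment = enr,
                 manifest = manifest))
}
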