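#' Analysis thresholds
#'
#' Bundles every tunable cutoff used by the pipeline.  The defaults are the
#' study settings: peptide mass error < 20 ppm, at most one missed cleavage
#' (modified lysines not counted), ANOVA alpha 0.05, Hi-N with N = 3, vehicle
#' concordance within 10%, dysregulation/residual bands at 10/25/50%,
#' enrichment cutoffs FDR <= 1% and p <= 0.01, and a minimum of 5 gene names
#' per reported pathway.
#'
#' @param max_mass_error_ppm peptides with `|mass_error_ppm|` at or above this
#'   value are rejected.
#' @param anova_alpha significance level applied to raw ANOVA p-values.
#' @param hi_n number of top peptides averaged per protein (Hi-N).
#' @param vehicle_tolerance maximum symmetric relative difference between the
#'   two vehicle-group means for a feature to enter the attenuation analysis.
#' @param bands strictly increasing dysregulation thresholds in (0, 1]; the
#'   defaults 0.10, 0.25, 0.50 delimit the mild/moderate/severe severity bands
#'   and the residual bands.
#' @param enrich_fdr,enrich_p reporting cutoffs for over-representation.
#' @param min_pathway_genes minimum overlap (gene names found in a pathway)
#'   for a pathway to pass.
#' @param max_missed_cleavages maximum tryptic missed cleavages, counted with
#'   the modified-lysine exclusion (see [count_missed_cleavages()]).
#'
#' @return An object of class `acyl_thresholds` (a named list).
#' @examples
#' acyl_thresholds()
#' acyl_thresholds(anova_alpha = 0.01)
#' @export
acyl_thresholds <- function(max_mass_error_ppm = 20,
                            anova_alpha = 0.05,
                            hi_n = 3L,
                            vehicle_tolerance = 0.10,
                            bands = c(0.10, 0.25, 0.50),
                            enrich_fdr = 0.01,
                            enrich_p = 0.01,
                            min_pathway_genes = 5L,
                            max_missed_cleavages = 1L) {
  stopifnot(is.numeric(max_mass_error_ppm), length(max_mass_error_ppm) == 1L,
            max_mass_error_ppm > 0)
  for (nm in c("anova_alpha", "vehicle_tolerance", "enrich_fdr", "enrich_p")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop(sprintf("'%s' must be a single value in (0, 1]", nm))
  }
  if (!is.numeric(bands) || length(bands) < 1L || any(bands <= 0) ||
      any(bands > 1) || is.unsorted(bands, strictly = TRUE))
    stop("'bands' must be strictly increasing values in (0, 1]")
  hi_n <- as.integer(hi_n)
  min_pathway_genes <- as.integer(min_pathway_genes)
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  stopifnot(hi_n >= 1L, min_pathway_genes >= 0L, max_missed_cleavages >= 0L)
  structure(list(max_mass_error_ppm = max_mass_error_ppm,
                 anova_alpha = anova_alpha,
                 hi_n = hi_n,
                 vehicle_tolerance = vehicle_tolerance,
                 bands = as.numeric(bands),
                 enrich_fdr = enrich_fdr,
                 enrich_p = enrich_p,
                 min_pathway_genes = min_pathway_genes,
                 max_missed_cleavages = max_missed_cleavages),
            class = "acyl_thresholds")
}

#' @export
print.acyl_thresholds <- function(x, ...) {
  cat("Analysis thresholds:\n")
  cat(sprintf("  mass error        : |ppm| < %g\n", x$max_mass_error_ppm))
  cat(sprintf("  missed cleavages  : <= %d (modified K excluded)\n",
              x$max_missed_cleavages))
  cat(sprintf("  ANOVA alpha       : %g\n", x$anova_alpha))
  cat(sprintf("  Hi-N              : N = %d\n", x$hi_n))
  cat(sprintf("  vehicle tolerance : %g\n", x$vehicle_tolerance))
  cat(sprintf("  bands             : %s\n",
              paste(x$bands, collapse = " / ")))
  cat(sprintf("  enrichment        : FDR <= %g, p <= %g, overlap >= %d\n",
              x$enrich_fdr, x$enrich_p, x$min_pathway_genes))
  invisible(x)
}
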