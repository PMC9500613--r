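#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA F-test across k groups; the p-value comes from
#' the F distribution with (k - 1, n - k) degrees of freedom.  Degenerate
#' inputs are resolved explicitly: zero within-group variance yields p = 1
#' when all group means are equal and p = 0 (with a warning) when they are
#' not.
#'
#' @param values_by_group named list of numeric vectors, one per group; at
#'   least two groups with at least two values each.
#' @param on_log test on `log2(x + pseudo)` instead of the raw scale.
#' @param pseudo pseudo-count added before the log transform.
#' @return Named numeric vector `c(F = ..., p = ...)`.
#' @examples
#' anova_oneway(list(A = c(10, 12), B = c(20, 22)))  # F = 50
#' @export
anova_oneway <- function(values_by_group, on_log = FALSE, pseudo = 1) {
  if (length(values_by_group) < 2L)
    stop("need at least two groups")
  if (any(lengths(values_by_group) < 2L))
    stop("each group needs at least two values")
  vals <- lapply(values_by_group, as.numeric)
  if (on_log) {
    if (any(unlist(vals) + pseudo <= 0))
      stop("log transform requires values + pseudo > 0")
    vals <- lapply(vals, function(v) log2(v + pseudo))
  }
  ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 0))
  means <- vapply(vals, mean, 0)
  if (ssw == 0) {
    if (max(means) - min(means) == 0) return(c(F = 0, p = 1))
    warning("zero within-group variance with unequal means; p set to 0")
    return(c(F = Inf, p = 0))
  }
  x <- unlist(vals, use.names = FALSE)
  g <- factor(rep(seq_along(vals), lengths(vals)))
  ow <- oneway.test(x ~ g, var.equal = TRUE)
  c(F = unname(ow$statistic), p = unname(ow$p.value))
}

#' Differential abundance of modified peptides by one-way ANOVA
#'
#' Runs [anova_oneway()] for every acyl-modified peptide across the design's
#' groups.  Following label-free practice the test is performed on
#' log2(abundance + 1) by default; deviating group means are summarized as a
#' direction relative to `reference_group` (sign of the mean of the
#' non-reference group means minus the reference mean, on the linear scale).
#' Raw p-values are compared against `thresholds$anova_alpha` — no
#' multiple-testing correction enters the significance call — but BH
#' q-values are reported alongside.
#'
#' @param peptides a `peptide_table` (already filtered/normalized).
#' @param design a [study_design].
#' @param thresholds an [acyl_thresholds].
#' @param reference_group group id used as the direction reference; defaults
#'   to the `vehicle1` role if declared, else the first group.
#' @param on_log test on the log2 scale (default `TRUE`).
#' @param features `"modified"` (default) tests acyl-modified peptides only;
#'   `"all"` tests every peptide.
#' @return An `acyl_differential` data frame with one row per tested
#'   feature: `feature` (row index in `peptides`), `sequence`, `accession`,
#'   `ptm`, per-group mean columns (`mean_<group>`), `F`, `p`, `q`,
#'   `direction` (`"up"`/`"down"`), `significant`.  Features with all-zero
#'   abundances are skipped with a warning.
#' @export
call_differential <- function(peptides, design,
                              thresholds = acyl_thresholds(),
                              reference_group = NULL,
                              on_log = TRUE,
                              features = c("modified", "all")) {
  features <- match.arg(features)
  validate_design(design, peptides)
  if (is.null(reference_group)) {
    reference_group <- if ("vehicle1" %in% names(design$roles))
      design$roles[["vehicle1"]] else sort(unique(design$samples$group_id))[1L]
  }
  if (!reference_group %in% design$samples$group_id)
    stop("reference group '", reference_group, "' not in design")
  mat <- abundance_matrix(peptides)
  idx <- if (features == "modified") which(is_modified(peptides))
         else seq_len(nrow(peptides))
  gs <- group_samples(design)
  skipped <- 0L
  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (all(mat[i, ] == 0)) { skipped <- skipped + 1L; next }
    byg <- lapply(gs, function(s) mat[i, s])
    ft <- suppressWarnings(anova_oneway(byg, on_log = on_log))
    gmeans <- vapply(byg, mean, 0)
    delta <- mean(gmeans[names(gs) != reference_group]) -
      gmeans[[reference_group]]
    rec <- data.frame(feature = i,
                      sequence = peptides$sequence[i],
                      accession = peptides$accession[i],
                      ptm = acyl_type(peptides)[i],
                      F = ft[["F"]], p = ft[["p"]],
                      direction = if (delta >= 0) "up" else "down",
                      stringsAsFactors = FALSE)
    for (g in names(gs)) rec[[paste0("mean_", g)]] <- gmeans[[g]]
    rows[[j]] <- rec
  }
  if (skipped > 0L)
    warning(sprintf("%d all-zero feature(s) skipped", skipped))
  rows <- rows[!vapply(rows, is.null, NA)]
  if (!length(rows)) {
    out <- data.frame(feature = integer(), sequence = character(),
                      accession = character(), ptm = character(),
                      F = numeric(), p = numeric(), q = numeric(),
                      direction = character(), significant = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("acyl_differential", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$p <= thresholds$anova_alpha
  rownames(out) <- NULL
  attr(out, "reference_group") <- reference_group
  attr(out, "alpha") <- thresholds$anova_alpha
  class(out) <- c("acyl_differential", "data.frame")
  out
}

#' @export
print.acyl_differential <- function(x, ...) {
  cat(sprintf("Differential modified peptides: %d tested, %d significant (alpha = %g, reference = %s)\n",
              nrow(x), sum(x$significant), attr(x, "alpha"),
              attr(x, "reference_group")))
  if (nrow(x)) {
    sig <- x[x$significant, c("sequence", "accession", "ptm", "F", "p",
                              "direction"), drop = FALSE]
    print(head(sig[order(sig$p), ], 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Per-protein direction of significant modified peptides
#'
#' A protein whose significant sites all move up is labeled `"Up"`, all down
#' `"Down"`; proteins with sites in both directions are labeled `"Both"`.
#'
#' @param results an `acyl_differential` data frame.
#' @return Named character vector accession -> `"Up"`/`"Down"`/`"Both"`
#'   (significant results only; empty if none).
#' @export
classify_protein_direction <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  if (!nrow(sig)) return(setNames(character(), character()))
  vapply(split(sig$direction, sig$accession), function(d) {
    u <- unique(d)
    if (length(u) > 1L) "Both" else if (u == "up") "Up" else "Down"
  }, "")
}

#' Identification/dysregulation frequency summary
#'
#' Computes the headline frequencies: how many quantified peptides carry an
#' acyl modification, what fraction of the modified peptides are
#' dysregulated at the ANOVA threshold, and the per-protein direction
#' breakdown, overall and per PTM type.
#'
#' @param peptides a `peptide_table` of all quantified peptides.
#' @param results an `acyl_differential` from [call_differential()].
#' @return A `frequency_summary` list: `n_quantified`, and per scope
#'   (`overall`, `succinyl`, `malonyl`) `n_modified`, `n_dysregulated`,
#'   `pct_modified`, `pct_dysregulated_of_modified`; plus
#'   `protein_direction` (table of Up/Down/Both counts).
#' @export
frequency_summary <- function(peptides, results) {
  stopifnot(inherits(peptides, "peptide_table"))
  n_quant <- nrow(peptides)
  types <- acyl_type(peptides)
  pct <- function(num, den) {
    if (den == 0) {
      warning("zero denominator; percentage reported as 0")
      return(0)
    }
    100 * num / den
  }
  scope_stats <- function(match_fun) {
    n_mod <- sum(match_fun(types))
    n_dys <- if (nrow(results)) sum(results$significant &
                                      match_fun(results$ptm)) else 0L
    list(n_modified = n_mod, n_dysregulated = n_dys,
         pct_modified = pct(n_mod, n_quant),
         pct_dysregulated_of_modified = pct(n_dys, n_mod))
  }
  dirs <- classify_protein_direction(results)
  structure(list(n_quantified = n_quant,
                 overall = scope_stats(nzchar),
                 succinyl = scope_stats(function(t) grepl("succinyl", t)),
                 malonyl = scope_stats(function(t) grepl("malonyl", t)),
                 protein_direction = table(factor(dirs, levels = c("Up", "Down", "Both")))),
            class = "frequency_summary")
}

#' @export
print.frequency_summary <- function(x, ...) {
  cat(sprintf("Quantified peptides: %d\n", x$n_quantified))
  for (sc in c("overall", "succinyl", "malonyl")) {
    s <- x[[sc]]
    cat(sprintf("  %-9s modified: %d (%.2f%%), dysregulated: %d (%.2f%% of modified)\n",
                sc, s$n_modified, s$pct_modified,
                s$n_dysregulated, s$pct_dysregulated_of_modified))
  }
  cat("Protein direction (significant sites): ")
  cat(paste(sprintf("%s=%d", names(x$protein_direction),
                    as.integer(x$protein_direction)), collapse = ", "), "\n")
  invisible(x)
}
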