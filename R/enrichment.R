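#' Hypergeometric upper-tail probability
#'
#' Exact probability of drawing at least `k` annotated genes when `n` genes
#' are drawn from a universe of `N` genes of which `K` are annotated,
#' P(X >= k).
#'
#' @param k observed overlap.
#' @param K genes in the set (within the universe).
#' @param n query size.
#' @param N universe (background) size.
#' @return Upper-tail probability in (0, 1].
#' @examples
#' hypergeom_p(3, 4, 5, 10)  # 66/252
#' @export
hypergeom_p <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotone enforcement; input order is
#' preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values of the same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Over-representation analysis against gene sets
#'
#' For every gene set intersecting the background universe, tests whether
#' the query list overlaps it more than expected by chance with the exact
#' hypergeometric upper tail, adjusts across sets with Benjamini-Hochberg,
#' and flags the sets passing the reporting cutoffs (by default FDR <= 1%,
#' p <= 0.01, and at least 5 gene names found in the pathway).  The
#' background defaults to the proteins quantified in the experiment, since
#' that is the universe the query was drawn from; query genes outside the
#' background are dropped with a warning.
#'
#' @param query character vector of gene identifiers of interest.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param background character vector: the gene universe.
#' @param thresholds an [acyl_thresholds].
#' @return An `enrichment_result` data frame sorted by FDR then p:
#'   `set_name`, `k` (overlap), `K` (set size in universe), `n` (query
#'   size), `N` (universe size), `p_value`, `fdr`, `passes`, `genes`
#'   (comma-separated overlap).
#' @export
enrich <- function(query, gene_sets, background,
                   thresholds = acyl_thresholds()) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (!length(query)) stop("empty query")
  if (!length(background)) stop("empty background")
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the background dropped",
                    length(outside)))
    query <- intersect(query, background)
    if (!length(query)) stop("no query genes left within the background")
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), background)
    K <- length(members)
    if (K == 0L) return(NULL)
    hit <- intersect(members, query)
    k <- length(hit)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N,
               p_value = hypergeom_p(k, K, n, N),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, NA)]
  if (!length(rows)) {
    out <- data.frame(set_name = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      fdr = numeric(), passes = logical(),
                      genes = character(), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$passes <- out$fdr <= thresholds$enrich_fdr &
    out$p_value <= thresholds$enrich_p &
    out$k >= thresholds$min_pathway_genes
  out <- out[order(out$fdr, out$p_value, out$set_name),
             c("set_name", "k", "K", "n", "N", "p_value", "fdr", "passes",
               "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Over-representation: %d sets tested, %d passing\n",
              nrow(x), sum(x$passes)))
  if (nrow(x))
    print(head(as.data.frame(x)[, c("set_name", "k", "K", "p_value", "fdr",
                                    "passes")], 10L), row.names = FALSE)
  invisible(x)
}

#' Dot-plot export of enrichment results across comparisons
#'
#' Collects the passing pathways of several comparisons into one
#' long-format table and draws the summary dot plot: one dot per
#' (comparison, pathway), sized by the number of gene names found in the
#' pathway and colored by FDR.
#'
#' @param results named list of `enrichment_result` objects, one per
#'   comparison (names like `"haloperidol.succinyl.up"` are split on `"."`
#'   into `comparison`, `ptm`, `direction` columns when they have three
#'   fields).
#' @param passing_only keep only pathways with `passes == TRUE` (default).
#' @param file optional path; the figure is saved there (format by
#'   extension, e.g. `.svg`/`.png`).
#' @return Invisibly, a list with `table` (long-format data frame
#'   `comparison`, `ptm`, `direction`, `pathway`, `k`, `fdr`) and `plot`
#'   (a ggplot, `NULL` when the table is empty).
#' @export
dotplot_export <- function(results, passing_only = TRUE, file = NULL) {
  if (inherits(results, "enrichment_result")) results <- list(all = results)
  stopifnot(is.list(results), !is.null(names(results)))
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (passing_only) r <- r[r$passes, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    data.frame(comparison = nm,
               ptm = if (length(parts) == 3L) parts[2L] else NA_character_,
               direction = if (length(parts) == 3L) parts[3L] else NA_character_,
               pathway = r$set_name, k = r$k, fdr = r$fdr,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, NA)]
  if (!length(rows)) {
    warning("no enrichment results to plot")
    tab <- data.frame(comparison = character(), ptm = character(),
                      direction = character(), pathway = character(),
                      k = integer(), fdr = numeric(),
                      stringsAsFactors = FALSE)
    return(invisible(list(table = tab, plot = NULL)))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$comparison,
                                         y = .data$pathway,
                                         size = .data$k,
                                         color = .data$fdr)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient(low = "#132B43", high = "#56B1F7") +
    ggplot2::labs(x = NULL, y = NULL, size = "genes", color = "FDR") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 7, height = 5)
  invisible(list(table = tab, plot = p))
}
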