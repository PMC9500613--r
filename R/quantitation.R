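#' Total-abundance column normalization
#'
#' Scales each sample (column) so that all column sums equal the grand mean
#' of the input column sums.  Intended as a stand-in for the run-level
#' normalization that alignment software applies internally; skip it (or use
#' `no_op = TRUE`) for tables that are already normalized.
#'
#' @param mat numeric matrix, features x samples, non-negative.
#' @param no_op return the matrix unchanged (convenience for pre-normalized
#'   inputs).
#' @return Matrix of the same shape with equalized column sums.
#' @examples
#' m <- cbind(s1 = c(10, 90), s2 = c(60, 240))
#' colSums(normalize_total(m))
#' @export
normalize_total <- function(mat, no_op = FALSE) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (any(mat < 0)) stop("negative abundances")
  if (no_op) return(mat)
  cs <- colSums(mat)
  if (any(cs == 0))
    stop("all-zero abundance column for sample(s): ",
         paste(colnames(mat)[cs == 0], collapse = ", "))
  target <- mean(cs)
  sweep(mat, 2L, target / cs, `*`)
}

#' Hi-N (top-N) protein-level quantitation
#'
#' For each protein, the N peptides with the highest mean abundance across
#' all samples are selected (all peptides if the protein has fewer than N),
#' and the protein's abundance in each sample is the mean of the selected
#' peptides' abundances in that sample.  The selected peptide set is fixed
#' across samples, so protein ratios remain comparable between samples.
#' Ties in mean abundance are broken deterministically by higher
#' identification score, then lexicographic peptide sequence, then row
#' order.
#'
#' @param mat numeric peptide x sample abundance matrix.
#' @param accession character vector (length `nrow(mat)`) mapping each
#'   peptide row to its protein.
#' @param n number of top peptides to average (default 3).
#' @param score,sequence optional per-peptide tie-breakers.
#' @return Numeric protein x sample matrix (rownames = accessions, sorted).
#' @export
hi_n_protein_quant <- function(mat, accession, n = 3L,
                               score = NULL, sequence = NULL) {
  stopifnot(is.matrix(mat), length(accession) == nrow(mat))
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  if (is.null(score)) score <- rep(0, nrow(mat))
  if (is.null(sequence)) sequence <- rep("", nrow(mat))
  pepmean <- rowMeans(mat)
  groups <- split(seq_len(nrow(mat)), accession)
  prot <- t(vapply(groups, function(idx) {
    o <- order(-pepmean[idx], -score[idx], sequence[idx], idx)
    sel <- idx[o][seq_len(min(n, length(idx)))]
    colMeans(mat[sel, , drop = FALSE])
  }, numeric(ncol(mat))))
  colnames(prot) <- colnames(mat)
  prot[order(rownames(prot)), , drop = FALSE]
}

#' Write a quantitation matrix as TSV
#'
#' @param mat numeric matrix with feature rownames and sample colnames.
#' @param path output file.
#' @param id_column name for the feature-id column.
#' @export
write_quant_matrix <- function(mat, path, id_column = "feature") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
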