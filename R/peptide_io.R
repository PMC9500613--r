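.ACYL_PTMS <- c("succinyl", "malonyl")

.REQUIRED_COLUMNS <- c("sequence", "modifications", "charge", "score",
                       "mass_error_ppm", "accession")

is_acyl <- function(ptm) tolower(ptm) %in% .ACYL_PTMS

#' Parse modification annotation strings
#'
#' Modification strings follow the convention
#' `"PTMName(X<pos>)"` with entries separated by semicolons, e.g.
#' `"Succinyl(K3);Oxidation(M7)"`, where `X` is the modified residue and
#' `<pos>` its 1-based position in the peptide.
#'
#' @param x character vector of modification strings; `""` or `NA` means
#'   unmodified.
#' @return A list (one element per input) of data frames with columns
#'   `ptm`, `residue`, `pos`.
#' @examples
#' parse_modifications(c("Succinyl(K3);Oxidation(M7)", ""))
#' @export
parse_modifications <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s)))
      return(data.frame(ptm = character(), residue = character(),
                        pos = integer(), stringsAsFactors = FALSE))
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
    parts <- parts[nzchar(parts)]
    m <- regmatches(parts, regexec("^([A-Za-z][A-Za-z0-9_-]*)\\(([A-Z])([0-9]+)\\)$", parts))
    bad <- vapply(m, length, 1L) == 0L
    if (any(bad))
      stop(sprintf("malformed modification entry: '%s'", parts[bad][1L]))
    data.frame(ptm = vapply(m, `[`, "", 2L),
               residue = vapply(m, `[`, "", 3L),
               pos = as.integer(vapply(m, `[`, "", 4L)),
               stringsAsFactors = FALSE)
  })
}

#' @rdname parse_modifications
#' @param mods list of modification data frames as produced by
#'   `parse_modifications()`.
#' @export
format_modifications <- function(mods) {
  vapply(mods, function(df) {
    if (nrow(df) == 0L) return("")
    paste(sprintf("%s(%s%d)", df$ptm, df$residue, df$pos), collapse = ";")
  }, "")
}

new_peptide_table <- function(df, sample_ids) {
  stopifnot(is.data.frame(df), is.character(sample_ids))
  structure(df, sample_ids = sample_ids,
            class = c("peptide_table", "data.frame"))
}

validate_peptide_table <- function(x) {
  sids <- attr(x, "sample_ids")
  if (!all(sids %in% names(x)))
    stop("abundance columns missing for samples: ",
         paste(setdiff(sids, names(x)), collapse = ", "))
  n <- nchar(x$sequence)
  for (i in seq_len(nrow(x))) {
    mods <- x$modifications[[i]]
    if (nrow(mods) == 0L) next
    if (any(mods$pos < 1L | mods$pos > n[i]))
      stop(sprintf("row %d: modification position outside peptide", i))
    res <- substring(x$sequence[i], mods$pos, mods$pos)
    if (any(res != mods$residue))
      stop(sprintf("row %d: annotated residue does not match sequence", i))
    if (any(is_acyl(mods$ptm) & mods$residue != "K"))
      stop(sprintf("row %d: acyl modification on non-lysine residue", i))
  }
  ab <- abundance_matrix(x)
  if (any(ab < 0)) stop("negative abundance values")
  invisible(x)
}

#' Read a peptide-level quantitation table
#'
#' Reads the canonical peptide quantitation export: one row per identified
#' peptide ion with columns `sequence`, `modifications`, `charge`, `score`,
#' `mass_error_ppm`, `accession` followed by one abundance column per sample.
#' Rows are kept in file order and nothing is silently dropped: a
#' non-numeric abundance raises a row-level error, while an empty/missing
#' abundance cell is zero-filled with a warning (zeros are what alignment
#' software exports for unmatched features) unless `strict = TRUE`.
#'
#' @param path file to read.
#' @param dialect `"comma"` (CSV) or `"tab"` (TSV).
#' @param design optional [study_design]; when supplied the abundance columns
#'   are exactly the design's sample ids (matched by header name, any order).
#' @param sample_prefix optional prefix identifying abundance columns when no
#'   design is given; default: every column after the required six.
#' @param strict reject missing abundance cells instead of zero-filling.
#' @return A `peptide_table`: a data frame with the six metadata columns
#'   (modifications parsed into a list column) plus one numeric column per
#'   sample; sample ids are kept in `attr(x, "sample_ids")`.
#' @seealso [write_peptide_table()], [parse_modifications()]
#' @export
read_peptide_table <- function(path, dialect = c("comma", "tab"),
                               design = NULL, sample_prefix = NULL,
                               strict = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  reader <- if (dialect == "comma") read.csv else read.delim
  raw <- reader(path, check.names = FALSE, stringsAsFactors = FALSE,
                colClasses = "character")
  missing_cols <- setdiff(.REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("peptide table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(design)) {
    sids <- design$samples$sample_id
    absent <- setdiff(sids, names(raw))
    if (length(absent))
      stop("design sample(s) absent from table header: ",
           paste(absent, collapse = ", "))
  } else if (!is.null(sample_prefix)) {
    sids <- grep(paste0("^", sample_prefix), names(raw), value = TRUE)
    if (!length(sids)) stop("no columns match sample prefix '", sample_prefix, "'")
  } else {
    sids <- setdiff(names(raw), .REQUIRED_COLUMNS)
  }
  n <- nrow(raw)
  df <- data.frame(sequence = toupper(trimws(raw$sequence)),
                   charge = as.integer(raw$charge),
                   score = as.numeric(raw$score),
                   mass_error_ppm = as.numeric(raw$mass_error_ppm),
                   accession = trimws(raw$accession),
                   stringsAsFactors = FALSE)
  df$modifications <- parse_modifications(raw$modifications)
  df <- df[, c("sequence", "modifications", "charge", "score",
               "mass_error_ppm", "accession")]
  if (n > 0L && (anyNA(df$charge) || any(df$charge <= 0L)))
    stop("non-positive or non-numeric charge in row(s): ",
         paste(which(is.na(df$charge) | df$charge <= 0L), collapse = ", "))
  if (n > 0L && anyNA(df$mass_error_ppm))
    stop("non-numeric mass_error_ppm in row(s): ",
         paste(which(is.na(df$mass_error_ppm)), collapse = ", "))
  n_missing <- 0L
  for (s in sids) {
    cell <- trimws(raw[[s]])
    empty <- is.na(cell) | !nzchar(cell)
    val <- suppressWarnings(as.numeric(cell))
    bad <- !empty & is.na(val)
    if (any(bad))
      stop(sprintf("non-numeric abundance for sample '%s' in row(s): %s",
                   s, paste(which(bad), collapse = ", ")))
    if (any(empty)) {
      if (strict)
        stop(sprintf("missing abundance for sample '%s' in row(s): %s",
                     s, paste(which(empty), collapse = ", ")))
      val[empty] <- 0
      n_missing <- n_missing + sum(empty)
    }
    if (any(val < 0, na.rm = TRUE))
      stop(sprintf("negative abundance for sample '%s' in row(s): %s",
                   s, paste(which(val < 0), collapse = ", ")))
    df[[s]] <- val
  }
  if (n_missing > 0L)
    warning(sprintf("%d missing abundance cell(s) treated as 0", n_missing))
  out <- new_peptide_table(df, sids)
  validate_peptide_table(out)
  out
}

#' Write a peptide table
#'
#' Inverse of [read_peptide_table()]: serializes the modification list column
#' back to `"PTM(X<pos>)"` strings.  Reading the written file back yields an
#' identical table.
#'
#' @param x a `peptide_table`.
#' @param path output file.
#' @param dialect `"comma"` or `"tab"`.
#' @export
write_peptide_table <- function(x, path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "peptide_table"))
  sids <- attr(x, "sample_ids")
  out <- data.frame(sequence = x$sequence,
                    modifications = format_modifications(x$modifications),
                    charge = x$charge,
                    score = x$score,
                    mass_error_ppm = x$mass_error_ppm,
                    accession = x$accession,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (s in sids) out[[s]] <- x[[s]]
  write.table(out, path, sep = if (dialect == "comma") "," else "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the abundance matrix of a peptide table
#'
#' @param x a `peptide_table`.
#' @return Numeric matrix, one row per peptide (rownames = row index), one
#'   column per sample.
#' @export
abundance_matrix <- function(x) {
  stopifnot(inherits(x, "peptide_table"))
  sids <- attr(x, "sample_ids")
  m <- as.matrix(as.data.frame(x, check.names = FALSE)[, sids, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- seq_len(nrow(m))
  m
}

#' Replace the abundance values of a peptide table
#'
#' @param x a `peptide_table`.
#' @param m numeric matrix with the table's samples as columns.
#' @return The table with abundances taken from `m`.
#' @export
set_abundances <- function(x, m) {
  stopifnot(inherits(x, "peptide_table"),
            nrow(m) == nrow(x),
            all(attr(x, "sample_ids") %in% colnames(m)))
  for (s in attr(x, "sample_ids")) x[[s]] <- m[, s]
  x
}

#' Flag acyl-modified peptides
#'
#' @param x a `peptide_table`.
#' @return `is_modified`: logical vector, `TRUE` where the peptide carries at
#'   least one acyl (succinyl/malonyl) modification.
#' @export
is_modified <- function(x) {
  vapply(x$modifications, function(df) any(is_acyl(df$ptm)), NA)
}

#' @rdname is_modified
#' @return `acyl_type`: per-peptide acyl label (`"succinyl"`, `"malonyl"`,
#'   both joined by `";"`, or `""` if unmodified).
#' @export
acyl_type <- function(x) {
  vapply(x$modifications, function(df) {
    a <- sort(unique(tolower(df$ptm[is_acyl(df$ptm)])))
    paste(a, collapse = ";")
  }, "")
}

#' @export
print.peptide_table <- function(x, ...) {
  sids <- attr(x, "sample_ids")
  cat(sprintf("Peptide quantitation table: %d peptides x %d samples (%d acyl-modified)\n",
              nrow(x), length(sids), sum(is_modified(x))))
  if (nrow(x) > 0L) {
    show <- head(data.frame(sequence = x$sequence,
                            modifications = format_modifications(x$modifications),
                            accession = x$accession,
                            stringsAsFactors = FALSE), 6L)
    print(show)
    if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' Accessions are taken from the first whitespace-delimited token of each
#' header; UniProt-style `sp|ACC|NAME` (or `tr|ACC|NAME`) headers yield
#' `ACC`.  Sequences are uppercased.
#'
#' @param path FASTA file.
#' @return Named character vector, accession -> protein sequence.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P1|X", "MKK"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, "", 1L)
  uni <- grepl("^(sp|tr)\\|", acc)
  acc[uni] <- vapply(strsplit(acc[uni], "|", fixed = TRUE), `[`, "", 2L)
  if (anyDuplicated(acc))
    stop("duplicated accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  setNames(toupper(as.character(ss)), acc)
}

#' Write protein sequences to FASTA
#'
#' @param proteome named character vector, accession -> sequence.
#' @param path output file.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(is.character(proteome), !is.null(names(proteome)))
  ss <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: name, description, then member
#' identifiers.  Members are deduplicated; a set with no members is an
#' error.
#'
#' @param path GMT file.
#' @return Named list of character vectors (unique members per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(g) unique(g[nzchar(g)]))
  empty <- lengths(sets) == 0L
  if (any(empty))
    stop("gene set(s) with no members: ",
         paste(names(sets)[empty], collapse = ", "))
  if (anyDuplicated(names(sets)))
    stop("duplicated gene-set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets
}

#' Construct a study design
#'
#' A study design maps samples to experimental groups and optionally tags
#' groups with the roles needed by the attenuation analysis: the two vehicle
#' controls, the insult ("model", e.g. MK-801) group and the co-treatment
#' ("treatment") group.
#'
#' @param samples data frame with columns `sample_id`, `group_id`.
#' @param roles named character vector mapping roles (among `"vehicle1"`,
#'   `"vehicle2"`, `"model"`, `"treatment"`) to group ids; optional for
#'   analyses that do not use the attenuation classifier.
#' @return An object of class `study_design`.
#' @examples
#' study_design(data.frame(sample_id = c("a1", "a2", "b1", "b2"),
#'                         group_id  = c("A", "A", "B", "B")))
#' @export
study_design <- function(samples, roles = character()) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "group_id") %in% names(samples)))
  samples$sample_id <- as.character(samples$sample_id)
  samples$group_id <- as.character(samples$group_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample id(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  roles <- unlist(roles)
  if (length(roles)) {
    known <- c("vehicle1", "vehicle2", "model", "treatment")
    if (!all(names(roles) %in% known))
      stop("unknown role(s): ",
           paste(setdiff(names(roles), known), collapse = ", "),
           " (supported: ", paste(known, collapse = ", "), ")")
    absent <- setdiff(roles, samples$group_id)
    if (length(absent))
      stop("role group(s) absent from design: ", paste(absent, collapse = ", "))
    if (all(c("vehicle1", "vehicle2") %in% names(roles)) &&
        roles[["vehicle1"]] == roles[["vehicle2"]])
      stop("vehicle1 and vehicle2 must be different groups")
  }
  structure(list(samples = samples[, c("sample_id", "group_id")],
                 roles = roles),
            class = "study_design")
}

#' Read a study design table
#'
#' CSV with columns `sample_id`, `group_id` and optionally `role`; rows with
#' a non-empty role declare that their group plays that role.
#'
#' @param path CSV file.
#' @return A [study_design] object.
#' @export
read_study_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group_id") %in% names(df)))
    stop("study design needs columns sample_id, group_id")
  roles <- character()
  if ("role" %in% names(df)) {
    has <- !is.na(df$role) & nzchar(trimws(df$role))
    if (any(has)) {
      r <- unique(data.frame(role = trimws(df$role[has]),
                             group = df$group_id[has],
                             stringsAsFactors = FALSE))
      if (anyDuplicated(r$role))
        stop("role declared for more than one group: ",
             paste(unique(r$role[duplicated(r$role)]), collapse = ", "))
      roles <- setNames(r$group, r$role)
    }
  }
  study_design(df, roles)
}

#' Write a study design table
#'
#' @param design a [study_design].
#' @param path output CSV.
#' @export
write_study_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  df <- design$samples
  role_of_group <- setNames(names(design$roles), design$roles)
  df$role <- ifelse(df$group_id %in% names(role_of_group),
                    role_of_group[df$group_id], "")
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check a study design against a peptide table
#'
#' Verifies that every design sample has an abundance column, that groups
#' entering the ANOVA have at least two samples, and (when required) that the
#' attenuation roles are declared.
#'
#' @param design a [study_design].
#' @param peptides a `peptide_table`.
#' @param require_roles character vector of roles that must be present.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_design <- function(design, peptides, require_roles = character()) {
  stopifnot(inherits(design, "study_design"),
            inherits(peptides, "peptide_table"))
  sids <- attr(peptides, "sample_ids")
  absent <- setdiff(design$samples$sample_id, sids)
  if (length(absent))
    stop("design sample(s) without abundance column: ",
         paste(absent, collapse = ", "))
  sizes <- table(design$samples$group_id)
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    stop("group(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  missing_roles <- setdiff(require_roles, names(design$roles))
  if (length(missing_roles))
    stop("design is missing required role(s): ",
         paste(missing_roles, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.study_design <- function(x, ...) {
  sizes <- table(x$samples$group_id)
  cat(sprintf("Study design: %d samples in %d groups\n",
              nrow(x$samples), length(sizes)))
  for (g in names(sizes)) {
    role <- names(x$roles)[x$roles == g]
    cat(sprintf("  %s: %d samples%s\n", g, sizes[[g]],
                if (length(role)) paste0(" [", role, "]") else ""))
  }
  invisible(x)
}

group_samples <- function(design) {
  split(design$samples$sample_id, design$samples$group_id)
}

group_means <- function(mat, design) {
  gs <- group_samples(design)
  out <- vapply(gs, function(s) rowMeans(mat[, s, drop = FALSE]),
                numeric(nrow(mat)))
  if (nrow(mat) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(rownames(mat), names(gs)))
  out
}
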