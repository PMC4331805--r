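#' Validate a gene-by-condition expression matrix
#'
#' The expression container is a plain numeric matrix: rows are genes, columns
#' are conditions (tissues), dimnames carry the identifiers. Values are
#' FPKM-like: non-negative, finite, dimensionless. At least 3 conditions are
#' required because Pearson significance needs `n - 2 >= 1` degrees of freedom.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene IDs) and
#'   colnames (condition IDs).
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene IDs as rownames and condition IDs as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ID: ", rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate condition ID: ", colnames(values)[duplicated(colnames(values))][1L])
  if (ncol(values) < 3L)
    stop("need at least 3 conditions, got ", ncol(values))
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(values))
    stop(sprintf("invalid expression value %s at gene '%s', condition '%s' (must be finite and >= 0)",
                 format(values[bad[1L]]), rownames(values)[ij[1L]], colnames(values)[ij[2L]]))
  }
  invisible(values)
}

#' Read an expression matrix from TSV
#'
#' First row is a header of condition names, first column holds gene IDs,
#' remaining cells are non-negative numbers. Row and column order are
#' preserved.
#'
#' @param path Path to the delimited text file.
#' @param delimiter Field separator, default tab.
#' @return A validated numeric matrix (genes x conditions).
#' @export
read_expression_tsv <- function(path, delimiter = "\t") {
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, quote = "", comment.char = "")
  if (ncol(raw) < 4L)
    stop("need at least 3 condition columns in ", path, ", got ", ncol(raw) - 1L)
  gene_ids <- raw[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ID in ", path, ": ", gene_ids[duplicated(gene_ids)][1L])
  cond_ids <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(cond_ids),
                 dimnames = list(gene_ids, cond_ids))
  for (j in seq_along(cond_ids)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(col) & !is.na(raw[[j + 1L]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d (gene '%s'), column '%s' of %s",
                   raw[[j + 1L]][bad[1L]], bad[1L], gene_ids[bad[1L]], cond_ids[j], path))
    col_bad <- which(is.na(col) | col < 0)
    if (length(col_bad))
      stop(sprintf("negative or missing value '%s' at row %d (gene '%s'), column '%s' of %s",
                   as.character(raw[[j + 1L]][col_bad[1L]]), col_bad[1L],
                   gene_ids[col_bad[1L]], cond_ids[j], path))
    vals[, j] <- col
  }
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]: full-precision values so a round trip
#' reproduces identical numbers.
#'
#' @param values Validated expression matrix.
#' @param path Output path.
#' @export
write_expression_tsv <- function(values, path) {
  validate_expression_matrix(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(values)), collapse = "\t"), con)
  body <- apply(values, 1L, function(row)
    paste(format(row, digits = 17, scientific = TRUE, trim = TRUE), collapse = "\t"))
  writeLines(paste(rownames(values), body, sep = "\t"), con)
  invisible(path)
}

#' GENCODE-style biotype labels folded into the lncRNA class
#'
#' Everything not listed here and not `protein_coding` maps to `other`.
#' @export
lncrna_biotypes <- c(
  "lncRNA", "lincRNA", "antisense", "antisense_RNA", "sense_intronic",
  "sense_overlapping", "3prime_overlapping_ncRNA", "3prime_overlapping_ncrna",
  "bidirectional_promoter_lncRNA", "macro_lncRNA", "non_coding",
  "processed_transcript"
)

normalize_biotype <- function(x) {
  out <- rep("other", length(x))
  out[x == "protein_coding"] <- "protein_coding"
  out[x %in% lncrna_biotypes] <- "lncRNA"
  out
}

#' Read a gene biotype catalog from a two-column TSV
#'
#' Column 1 is the gene ID, column 2 a biotype label. Labels are normalized to
#' the closed vocabulary `{lncRNA, protein_coding, other}`: `protein_coding`
#' maps to itself, the GENCODE lncRNA-family labels in [lncrna_biotypes] map
#' to `lncRNA`, anything else to `other`. A header line starting with
#' `gene_id` is skipped if present.
#'
#' @param path Path to the TSV.
#' @return Named character vector: names are gene IDs, values normalized
#'   biotypes.
#' @export
read_gene_catalog <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (ncol(raw) < 2L) stop("gene catalog must have two tab-separated columns")
  if (nrow(raw) && tolower(raw[1L, 1L]) == "gene_id") raw <- raw[-1L, , drop = FALSE]
  if (!nrow(raw)) stop("empty gene catalog: ", path)
  ids <- raw[[1L]]
  biotype <- normalize_biotype(raw[[2L]])
  dup <- duplicated(ids)
  if (any(dup)) {
    for (id in unique(ids[dup])) {
      if (length(unique(biotype[ids == id])) > 1L)
        stop("gene '", id, "' listed with conflicting biotypes in ", path)
    }
    biotype <- biotype[!dup]
    ids <- ids[!dup]
  }
  stats::setNames(biotype, ids)
}

#' Extract a gene biotype catalog from a GTF file
#'
#' Uses lines with feature type `gene` and reads the `gene_id` and `gene_type`
#' (or `gene_biotype`) attributes. Non-gene features are ignored; lines whose
#' attribute block cannot be parsed are skipped with a warning.
#'
#' @param path Path to a GTF file.
#' @return Named character vector as for [read_gene_catalog()].
#' @export
extract_catalog_from_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_gene <- vapply(fields, function(f) length(f) >= 9L && f[3L] == "gene", logical(1L))
  fields <- fields[is_gene]
  if (!length(fields)) stop("no gene feature lines found in ", path)
  ids <- character(0)
  types <- character(0)
  n_skipped <- 0L
  for (f in fields) {
    attrs <- f[9L]
    gid <- regmatches(attrs, regexec('gene_id "([^"]+)"', attrs))[[1L]]
    gtype <- regmatches(attrs, regexec('gene_(?:bio)?type "([^"]+)"', attrs, perl = TRUE))[[1L]]
    if (length(gid) < 2L || length(gtype) < 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    ids <- c(ids, gid[2L])
    types <- c(types, gtype[2L])
  }
  if (n_skipped)
    warning(n_skipped, " gene line(s) with unparseable attributes skipped in ", path)
  if (!length(ids)) stop("no parseable gene lines in ", path)
  biotype <- normalize_biotype(types)
  dup <- duplicated(ids)
  if (any(dup)) {
    for (id in unique(ids[dup]))
      if (length(unique(biotype[ids == id])) > 1L)
        stop("gene '", id, "' has conflicting biotypes in ", path)
    ids <- ids[!dup]; biotype <- biotype[!dup]
  }
  stats::setNames(biotype, ids)
}

#' Split an expression matrix into lncRNA and protein-coding sub-matrices
#'
#' Genes absent from the catalog are dropped with a logged count (biotype
#' decides which side of a correlation pair a gene sits on, so guessing is
#' unsafe); genes with biotype `other` appear in neither output. Row order is
#' preserved.
#'
#' @param values Validated expression matrix.
#' @param catalog Named biotype vector from [read_gene_catalog()] or
#'   [extract_catalog_from_gtf()].
#' @return List with elements `lnc` and `coding`, both expression matrices
#'   over the same conditions.
#' @export
split_by_biotype <- function(values, catalog) {
  validate_expression_matrix(values)
  genes <- rownames(values)
  known <- genes %in% names(catalog)
  if (any(!known)) {
    lf_log("dropping %d/%d matrix genes absent from the catalog", sum(!known), length(genes))
    if (!any(known)) stop("catalog covers none of the matrix genes")
  }
  biotype <- catalog[genes[known]]
  lnc_ids <- genes[known][biotype == "lncRNA"]
  coding_ids <- genes[known][biotype == "protein_coding"]
  if (!length(lnc_ids)) stop("no lncRNA genes after the split")
  if (!length(coding_ids)) stop("no protein-coding genes after the split")
  list(lnc = values[lnc_ids, , drop = FALSE],
       coding = values[coding_ids, , drop = FALSE])
}

#' Optional preprocessing: log transform and expression filter
#'
#' Both are off by default: expression values are used as read unless the
#' caller opts in. `log_transform_expression` applies `log2(x + 1)`;
#' `filter_expressed` keeps genes with at least `min_conditions` conditions at
#' or above `min_value`.
#'
#' @param values Validated expression matrix.
#' @export
log_transform_expression <- function(values) {
  validate_expression_matrix(values)
  log2(values + 1)
}

#' @rdname log_transform_expression
#' @param min_value Expression threshold.
#' @param min_conditions Minimum number of conditions meeting `min_value`.
#' @export
filter_expressed <- function(values, min_value, min_conditions) {
  validate_expression_matrix(values)
  keep <- rowSums(values >= min_value) >= min_conditions
  lf_log("expression filter kept %d/%d genes (>= %g in >= %d conditions)",
         sum(keep), length(keep), min_value, min_conditions)
  values[keep, , drop = FALSE]
}
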