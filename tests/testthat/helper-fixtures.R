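# In-code micro-fixtures: tiny files written into tempdirs at test time.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tmp_expression_tsv <- function(mat) {
  lines <- c(paste(c("gene_id", colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(rownames(mat)[i], mat[i, ]), collapse = "\t"),
               character(1L)))
  write_lines_tmp(lines, ".tsv")
}

tmp_catalog_tsv <- function(ids, biotypes) {
  write_lines_tmp(paste(ids, biotypes, sep = "\t"), ".tsv")
}

# A 3-level toy ontology: root <- mid <- {leaf_a, leaf_b}; leaf_b also
# part_of mid (diamond-ish), plus an obsolete term.
tmp_toy_obo <- function() {
  write_lines_tmp(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: T:001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: T:002", "name: mid", "namespace: biological_process",
    "is_a: T:001 ! root", "",
    "[Term]", "id: T:003", "name: leaf_a", "namespace: biological_process",
    "is_a: T:002", "",
    "[Term]", "id: T:004", "name: leaf_b", "namespace: biological_process",
    "is_a: T:002", "relationship: part_of T:001", "",
    "[Term]", "id: T:005", "name: gone", "is_obsolete: true", ""
  ), ".obo")
}

tmp_gaf <- function(rows) {
  # rows: data.frame(gene, qualifier, term)
  lines <- c("!gaf-version: 2.1",
             vapply(seq_len(nrow(rows)), function(i)
               paste(c("DB", rows$gene[i], rows$gene[i], rows$qualifier[i],
                       rows$term[i], "REF:1", "EXP", "", "P", "", "", "gene",
                       "taxon:9606", "20260101", "DB", "", ""),
                     collapse = "\t"),
               character(1L)))
  write_lines_tmp(lines, ".gaf")
}

# Deterministic expression matrix with two perfectly planted groups, enough
# conditions for exact-correlation edges to be significant.
micro_expression <- function() {
  t <- seq_len(10)
  mat <- rbind(
    L1 = t,                 # correlates exactly with C1, C2
    L2 = rev(t),            # correlates exactly with C3
    C1 = 2 * t + 1,
    C2 = 5 * t,
    C3 = 3 * rev(t) + 2,
    C4 = rep(4, 10) + c(1, rep(0, 9))  # near-constant, uncorrelated
  )
  colnames(mat) <- sprintf("cond%02d", seq_len(10))
  mat
}

micro_catalog <- function() {
  stats::setNames(c("lncRNA", "lncRNA", rep("protein_coding", 4L)),
                  c("L1", "L2", "C1", "C2", "C3", "C4"))
}

# Synthetic annotation universe for filter-semantics tests: one term of size
# 4 (below the filter) and one of size 6 on a 40-gene universe.
micro_terms <- function() {
  genes <- sprintf("G%02d", 1:40)
  dag <- structure(
    list(terms = data.frame(id = c("T:A", "T:B"), name = c("small", "big"),
                            namespace = "biological_process",
                            stringsAsFactors = FALSE),
         edges = data.frame(child = character(0), parent = character(0),
                            type = character(0), stringsAsFactors = FALSE),
         obsolete = character(0)),
    class = "ontology_dag")
  direct <- list("T:A" = genes[1:4], "T:B" = genes[3:8])
  ann <- propagate_annotations(annotation_set(direct, dag))
  list(universe = genes, ann = ann)
}
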