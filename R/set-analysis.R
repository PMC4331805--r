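#' Build a set-level query
#'
#' A set of lncRNAs and the minimum co-expression support `K`: a coding gene
#' enters the analysis only if it is significantly co-expressed with at least
#' `K` of the query lncRNAs. `K = 1` (the default) is the plain union; larger
#' `K` sharpens the set toward genes shared by several of the lncRNAs.
#'
#' @param lncrna_ids Non-empty character vector of lncRNA IDs (duplicates
#'   collapse).
#' @param k Minimum support count, integer >= 1.
#' @return A `set_query` object.
#' @export
set_query <- function(lncrna_ids, k = 1L) {
  lncrna_ids <- unique(as.character(lncrna_ids))
  if (!length(lncrna_ids)) stop("query lncRNA set is empty")
  if (length(k) != 1L || is.na(k) || k < 1 || k != floor(k))
    stop("K must be a single integer >= 1")
  structure(list(lncrna_ids = lncrna_ids, k = as.integer(k)),
            class = "set_query")
}

#' Coding genes co-expressed with at least K query lncRNAs
#'
#' Support of a coding gene = number of query lncRNAs it is significantly
#' co-expressed with. Query lncRNAs absent from the network contribute
#' nothing but are reported in `skipped` rather than silently dropped. A `K`
#' that eliminates every gene yields an empty set, not an error.
#'
#' @param network A `coexpression_network`.
#' @param query A `set_query`.
#' @return List: `genes` (character vector, sorted), `support` (named integer
#'   vector over `genes`), `present` and `skipped` (query IDs in / not in the
#'   network).
#' @export
supported_gene_union <- function(network, query) {
  stopifnot(inherits(network, "coexpression_network"), inherits(query, "set_query"))
  present <- intersect(query$lncrna_ids, unique(network$edges$lncrna_id))
  skipped <- setdiff(query$lncrna_ids, present)
  if (length(skipped))
    lf_log("%d query lncRNA(s) absent from the network: %s",
           length(skipped), paste(utils::head(skipped, 5L), collapse = ", "))
  sub <- network$edges[network$edges$lncrna_id %in% present, , drop = FALSE]
  support <- table(sub$coding_id)  # edges are unique per (lncrna, coding) pair
  support <- support[support >= query$k]
  genes <- sort(names(support))
  list(genes = genes,
       support = stats::setNames(as.integer(support[genes]), genes),
       present = present, skipped = skipped)
}

#' Functionally annotate a set of lncRNAs
#'
#' The K-supported union of co-expressed coding genes (see
#' [supported_gene_union()]) replaces the single-lncRNA co-expressed set; the
#' statistical pipeline is otherwise identical to [annotate_lncrna()], with
#' `n` equal to the size of the union (support counts never weight the test).
#' The same minimum-size filter applies: a union smaller than `min_coexp` is
#' an explicit not-annotatable outcome. A singleton query with `K = 1`
#' reduces exactly to the single-lncRNA annotation.
#'
#' @param query A `set_query`.
#' @inheritParams annotate_lncrna
#' @return An `lncrna_set_annotation` with the same result fields as
#'   [annotate_lncrna()] plus `support` and `skipped`.
#' @export
annotate_set <- function(query, network, go, pathways, universe,
                         min_coexp = 5L, min_term_size = 5L, alpha = 0.05,
                         namespaces = NULL) {
  stopifnot(inherits(query, "set_query"))
  u <- supported_gene_union(network, query)
  not_ok <- if (!length(u$present)) "no query lncRNA present in the network"
    else if (length(u$genes) < min_coexp)
      sprintf("K-supported union has %d protein-coding genes (minimum %d)",
              length(u$genes), min_coexp)
    else NA_character_
  base <- list(lncrna_ids = query$lncrna_ids, k = query$k,
               n_coexpressed = length(u$genes), coexpressed = u$genes,
               support = u$support, skipped = u$skipped)
  if (!is.na(not_ok)) {
    return(structure(c(base, list(status = "not_annotatable", reason = not_ok,
                                  go = empty_enrichment(),
                                  pathway = empty_enrichment())),
                     class = "lncrna_set_annotation"))
  }
  go_res <- if (is.null(go)) empty_enrichment()
    else enrich(u$genes, go, universe, min_term_size = min_term_size,
                correction = "BY", alpha = alpha, namespaces = namespaces)
  pw_res <- if (is.null(pathways)) empty_enrichment()
    else enrich(u$genes, pathways, universe, min_term_size = min_term_size,
                correction = "BH", alpha = alpha)
  structure(c(base, list(status = "annotated", reason = NA_character_,
                         go = go_res, pathway = pw_res)),
            class = "lncrna_set_annotation")
}

#' @export
print.lncrna_set_annotation <- function(x, ...) {
  cat(sprintf("lncRNA set (%d IDs, K = %d): ", length(x$lncrna_ids), x$k))
  if (x$status == "not_annotatable") {
    cat(sprintf("not annotatable (%s)\n", x$reason))
  } else {
    cat(sprintf("%d supported coding genes; %d/%d GO terms and %d/%d pathways significant\n",
                x$n_coexpressed, sum(x$go$significant), nrow(x$go),
                sum(x$pathway$significant), nrow(x$pathway)))
  }
  if (length(x$skipped))
    cat("  skipped (absent from network): ", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
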