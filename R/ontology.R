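#' Parse a Gene Ontology file in OBO 1.2 format
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `namespace`, `is_a` edges and
#' `relationship: part_of` edges (the safe-propagation pair; other
#' relationship types are dropped with a logged count). Obsolete terms are
#' recorded separately and carry no edges. The resulting child-to-parent graph
#' must be acyclic and closed: a dangling edge target or a cycle is a hard
#' error.
#'
#' @param path Path to the OBO file.
#' @return An `ontology_dag` object: `terms` (data.frame `id`, `name`,
#'   `namespace`), `edges` (data.frame `child`, `parent`, `type`), `obsolete`
#'   (character vector of obsolete term IDs).
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  # strip trailing OBO comments ("! ..."), keep structure
  lines <- sub("\\s*!.*$", "", lines)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas found in ", path)
  stanza_bounds <- c(which(grepl("^\\[.*\\]$", lines)), length(lines) + 1L)

  ids <- character(0); names_ <- character(0); namespaces <- character(0)
  obsolete <- character(0)
  edge_child <- character(0); edge_parent <- character(0); edge_type <- character(0)
  n_other_rel <- 0L

  for (s in term_starts) {
    end <- min(stanza_bounds[stanza_bounds > s]) - 1L
    block <- lines[(s + 1L):end]
    get1 <- function(key) {
      hit <- block[startsWith(block, paste0(key, ":"))]
      if (!length(hit)) return(NA_character_)
      trimws(sub(paste0("^", key, ":\\s*"), "", hit[1L]))
    }
    id <- get1("id")
    if (is.na(id)) next
    if (identical(get1("is_obsolete"), "true")) {
      obsolete <- c(obsolete, id)
      next
    }
    ids <- c(ids, id)
    names_ <- c(names_, get1("name"))
    namespaces <- c(namespaces, get1("namespace"))
    isa <- block[startsWith(block, "is_a:")]
    for (ln in isa) {
      edge_child <- c(edge_child, id)
      edge_parent <- c(edge_parent, trimws(sub("^is_a:\\s*", "", ln)))
      edge_type <- c(edge_type, "is_a")
    }
    rel <- block[startsWith(block, "relationship:")]
    for (ln in rel) {
      parts <- strsplit(trimws(sub("^relationship:\\s*", "", ln)), "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[1L] == "part_of") {
        edge_child <- c(edge_child, id)
        edge_parent <- c(edge_parent, parts[2L])
        edge_type <- c(edge_type, "part_of")
      } else {
        n_other_rel <- n_other_rel + 1L
      }
    }
  }
  if (anyDuplicated(ids)) stop("duplicate term id in ", path, ": ",
                               ids[duplicated(ids)][1L])
  if (n_other_rel) lf_log("dropped %d non-is_a/part_of relationship(s)", n_other_rel)

  dangling <- setdiff(edge_parent, c(ids, obsolete))
  if (length(dangling))
    stop("edge target(s) absent from the ontology: ",
         paste(utils::head(dangling, 5L), collapse = ", "))
  # edges touching obsolete terms are invalid per the OBO contract; drop them
  keep <- !(edge_child %in% obsolete) & !(edge_parent %in% obsolete)
  edge_child <- edge_child[keep]; edge_parent <- edge_parent[keep]
  edge_type <- edge_type[keep]

  dag <- structure(
    list(terms = data.frame(id = ids, name = names_, namespace = namespaces,
                            stringsAsFactors = FALSE),
         edges = data.frame(child = edge_child, parent = edge_parent,
                            type = edge_type, stringsAsFactors = FALSE),
         obsolete = obsolete),
    class = "ontology_dag"
  )
  assert_acyclic(dag)
  dag
}

# Hard-fails with one example cycle if the child->parent graph is cyclic.
assert_acyclic <- function(dag) {
  if (!nrow(dag$edges)) return(invisible(dag))
  g <- igraph::graph_from_data_frame(dag$edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = dag$terms$id)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1L)[1L]]
    stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  invisible(dag)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("Ontology DAG: %d terms, %d edges, %d obsolete\n",
              nrow(x$terms), nrow(x$edges), length(x$obsolete)))
  invisible(x)
}

dag_children <- function(dag) {
  # term_id -> character vector of direct children
  split(dag$edges$child, factor(dag$edges$parent, levels = dag$terms$id))
}

#' Parse gene-to-GO annotations in GAF 2.x format
#'
#' Column 2 is the gene/product identifier, column 4 the qualifier, column 5
#' the GO term. Lines starting with `!` are comments. Rows with a `NOT`
#' qualifier are skipped, as are rows citing terms that are obsolete or
#' absent from the DAG (with a logged count). Duplicate annotations collapse.
#' Evidence codes (column 7) are all accepted unless listed in
#' `exclude_evidence`.
#'
#' @param path Path to the GAF file.
#' @param dag `ontology_dag` the annotations refer to.
#' @param exclude_evidence Optional character vector of evidence codes to
#'   drop (e.g. `"IEA"`); default none.
#' @return An `annotation_set` with the direct map filled and the propagated
#'   map empty; see [propagate_annotations()].
#' @export
parse_gaf <- function(path, dag, exclude_evidence = character(0)) {
  stopifnot(inherits(dag, "ontology_dag"))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok_len <- vapply(fields, length, integer(1L)) >= 5L
  if (any(!ok_len))
    warning(sum(!ok_len), " malformed GAF line(s) skipped in ", path)
  fields <- fields[ok_len]
  gene <- vapply(fields, `[`, character(1L), 2L)
  qualifier <- vapply(fields, `[`, character(1L), 4L)
  term <- vapply(fields, `[`, character(1L), 5L)
  evidence <- vapply(fields, function(f) if (length(f) >= 7L) f[7L] else "",
                     character(1L))
  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  if (length(exclude_evidence)) keep <- keep & !(evidence %in% exclude_evidence)
  unknown <- !(term %in% dag$terms$id)
  if (any(unknown & keep))
    lf_log("skipped %d annotation row(s) citing obsolete/unknown terms",
           sum(unknown & keep))
  keep <- keep & !unknown
  if (!any(keep)) stop("no usable annotation rows in ", path)
  gene <- gene[keep]; term <- term[keep]
  direct <- lapply(split(gene, term), function(g) sort(unique(g)))
  annotation_set(direct = direct, dag = dag)
}

#' Construct an annotation set
#'
#' @param direct Named list: term ID -> character vector of directly annotated
#'   genes.
#' @param dag The `ontology_dag` the terms belong to (provides names and
#'   namespaces for reporting).
#' @param propagated Optional named list of propagated gene sets.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(direct, dag, propagated = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  bad <- setdiff(names(direct), dag$terms$id)
  if (length(bad))
    stop("direct annotations cite terms absent from the DAG: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  structure(
    list(direct = direct, propagated = propagated,
         universe = sort(unique(unlist(direct, use.names = FALSE))),
         terms = dag$terms, dag = dag),
    class = "annotation_set"
  )
}

#' Propagate annotations up the ontology
#'
#' Fills the propagated map with the offspring rule: a term's annotated genes
#' are the genes directly annotated to it plus the genes annotated to any of
#' its descendants, following `is_a` and `part_of` edges child-to-parent.
#' Computed once in reverse topological order; idempotent (the propagated map
#' is always recomputed from the direct map).
#'
#' @param ann An `annotation_set`.
#' @return The `annotation_set` with `propagated` filled for every
#'   non-obsolete term.
#' @export
propagate_annotations <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  dag <- ann$dag
  term_ids <- dag$terms$id
  prop <- stats::setNames(vector("list", length(term_ids)), term_ids)
  children <- dag_children(dag)
  if (nrow(dag$edges)) {
    g <- igraph::graph_from_data_frame(dag$edges[, c("child", "parent")],
                                       directed = TRUE, vertices = term_ids)
    order_ids <- names(igraph::topo_sort(g, mode = "out"))
  } else {
    order_ids <- term_ids
  }
  # children precede parents in "out" topological order of child->parent edges
  for (t in order_ids) {
    g <- unlist(c(ann$direct[t], prop[children[[t]]]), use.names = FALSE)
    prop[[t]] <- if (is.null(g)) character(0) else sort(unique(g))
  }
  ann$propagated <- prop
  ann
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set: %d terms with direct annotations, %d genes; propagated: %s\n",
              length(x$direct), length(x$universe),
              if (is.null(x$propagated)) "no" else "yes"))
  invisible(x)
}

#' Parse flat pathway gene sets in GMT format
#'
#' One pathway per line: `name TAB description TAB gene1 TAB gene2 ...`. The
#' description field carries the source-database label when present (empty
#' descriptions become `"unlabeled"`). Lines without genes are skipped with a
#' warning; the same `(database, name)` pair appearing twice with different
#' gene sets is a hard error.
#'
#' @param path Path to the GMT file.
#' @return A `pathway_collection`: `meta` (data.frame `key`, `database`,
#'   `name`) and `sets` (named list of gene vectors keyed by
#'   `database::name`).
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keys <- character(0); dbs <- character(0); nms <- character(0)
  sets <- list()
  n_empty <- 0L
  for (f in fields) {
    if (length(f) < 3L) { n_empty <- n_empty + 1L; next }
    genes <- sort(unique(f[-(1:2)][nzchar(f[-(1:2)])]))
    if (!length(genes)) { n_empty <- n_empty + 1L; next }
    db <- if (nzchar(f[2L])) f[2L] else "unlabeled"
    key <- paste0(db, "::", f[1L])
    if (key %in% keys) {
      if (!identical(sets[[key]], genes))
        stop("pathway '", key, "' appears twice with different gene sets in ", path)
      next
    }
    keys <- c(keys, key); dbs <- c(dbs, db); nms <- c(nms, f[1L])
    sets[[key]] <- genes
  }
  if (n_empty) warning(n_empty, " GMT line(s) without genes skipped in ", path)
  if (!length(sets)) stop("no usable pathways in ", path)
  structure(
    list(meta = data.frame(key = keys, database = dbs, name = nms,
                           stringsAsFactors = FALSE),
         sets = sets),
    class = "pathway_collection"
  )
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("Pathway collection: %d gene sets from %d database label(s)\n",
              length(x$sets), length(unique(x$meta$database))))
  invisible(x)
}

#' Genes annotated to a term, on a common universe
#'
#' For a GO term this is the propagated gene set; for a pathway the flat set.
#' Intersecting with `universe_filter` (normally the protein-coding universe)
#' guarantees the enrichment counts M and N are taken over the same gene
#' universe.
#'
#' @param source An `annotation_set` (propagated) or `pathway_collection`.
#' @param term Term ID (GO) or pathway key (`database::name`).
#' @param universe_filter Optional gene set to intersect with.
#' @return Character vector of gene IDs; empty with a warning for an unknown
#'   term.
#' @export
annotated_genes <- function(source, term, universe_filter = NULL) {
  genes <- if (inherits(source, "annotation_set")) {
    if (is.null(source$propagated))
      stop("annotation set has not been propagated; call propagate_annotations() first")
    source$propagated[[term]]
  } else if (inherits(source, "pathway_collection")) {
    source$sets[[term]]
  } else stop("unsupported annotation source")
  if (is.null(genes)) {
    warning("unknown term '", term, "'")
    return(character(0))
  }
  if (!is.null(universe_filter)) genes <- intersect(genes, universe_filter)
  genes
}
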