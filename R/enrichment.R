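#' Upper-tail hypergeometric p-value for term enrichment
#'
#' The enrichment p-value for a functional term: the probability of drawing at
#' least `m` annotated genes when `n` genes are sampled without replacement
#' from a universe of `N` protein-coding genes of which `M` carry the
#' annotation,
#' \deqn{p = \sum_{i=m}^{\min(n,M)} \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}.}
#' The sum is evaluated in log space (log-gamma terms combined by
#' log-sum-exp), so p-values far below the double underflow of a naive product
#' (e.g. 1e-109) are computed with small relative error. `m = 0` returns 1
#' exactly.
#'
#' @param N Universe size (all protein-coding genes).
#' @param M Universe genes annotated to the term.
#' @param n Query size (co-expressed genes).
#' @param m Query genes annotated to the term.
#' @param log.p Return the natural log of the p-value instead.
#' @return The tail probability (or its log).
#' @export
hypergeom_pvalue <- function(N, M, n, m, log.p = FALSE) {
  check_term_stats(N, M, n, m)
  if (m == 0L) return(if (log.p) 0 else 1)
  lp <- hypergeom_logp_tails(N, M, n)[m + 1L]
  if (log.p) lp else exp(lp)
}

# Invariants of the (N, M, n, m) contingency; fails naming the violated one.
check_term_stats <- function(N, M, n, m) {
  for (v in list(N = N, M = M, n = n, m = m)) {
    if (length(v) != 1L || is.na(v) || v < 0 || v != floor(v))
      stop("N, M, n, m must be single non-negative integers")
  }
  if (M > N) stop("invariant violated: M <= N (got M=", M, ", N=", N, ")")
  if (n > N) stop("invariant violated: n <= N (got n=", n, ", N=", N, ")")
  if (m > min(n, M)) stop("invariant violated: m <= min(n, M) (got m=", m,
                          ", min(n, M)=", min(n, M), ")")
  invisible(TRUE)
}

# log tail probabilities for every cutoff at once: element m+1 is
# log P(X >= m) for X ~ Hypergeometric(N, M, n), m = 0..min(n, M).
hypergeom_logp_tails <- function(N, M, n) {
  k <- min(n, M)
  i <- 0:k
  log_terms <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  lp <- rev_cum_logsumexp(log_terms)
  lp[1L] <- 0  # full support sums to exactly 1
  pmin(lp, 0)
}

#' Benjamini-Hochberg and Benjamini-Yekutieli FDR adjustment
#'
#' `benjamini_hochberg()` is the step-up procedure for independent tests:
#' sort ascending, multiply the k-th smallest by `m/k`, enforce monotonicity
#' by a cumulative minimum from the largest rank, cap at 1, restore input
#' order. `benjamini_yekutieli()` additionally multiplies by the harmonic sum
#' `c(m) = sum(1/i, i = 1..m)`, which makes the control valid under arbitrary
#' dependence — the appropriate choice for hierarchically dependent GO terms,
#' while BH is used for the flat pathway family. Both delegate to
#' [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(pvals) {
  check_pvals(pvals)
  stats::p.adjust(pvals, method = "BH")
}

#' @rdname benjamini_hochberg
#' @export
benjamini_yekutieli <- function(pvals) {
  check_pvals(pvals)
  stats::p.adjust(pvals, method = "BY")
}

check_pvals <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must be numeric in [0, 1]")
  invisible(TRUE)
}

#' Enrichment of a gene set against GO terms or pathways
#'
#' Tests every term with at least `min_term_size` annotated genes (after GO
#' propagation and intersection with the universe) for over-representation in
#' the query, by [hypergeom_pvalue()]. The multiple-testing family is exactly
#' the set of terms tested in this call. All tested terms are returned, sorted
#' by corrected p ascending (ties: raw p, then term ID), with a significance
#' flag at `p_corrected < alpha`.
#'
#' @param query_genes Character vector of query gene IDs. Genes outside the
#'   universe are dropped with a warning; an empty query is an error.
#' @param terms An `annotation_set` (propagated) or `pathway_collection`.
#' @param universe Character vector: the protein-coding gene universe (its
#'   size is N).
#' @param min_term_size Minimum M for a term to be tested, default 5.
#' @param correction `"BY"` or `"BH"`.
#' @param alpha Significance cutoff on the corrected p-value, default 0.05.
#' @param namespaces Optional restriction to GO namespaces (e.g.
#'   `"biological_process"`); ignored for pathway collections.
#' @return `data.frame` with columns `term_id`, `term_name`, `database`, `N`,
#'   `M`, `n`, `m`, `p_raw`, `p_corrected`, `significant`; attribute
#'   `correction_method`.
#' @export
enrich <- function(query_genes, terms, universe, min_term_size = 5L,
                   correction = c("BY", "BH"), alpha = 0.05,
                   namespaces = NULL) {
  correction <- match.arg(correction)
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query_genes <- setdiff(query_genes, outside)
  }
  if (!length(query_genes)) stop("empty query after universe filtering")

  if (inherits(terms, "annotation_set")) {
    if (is.null(terms$propagated))
      stop("annotation set has not been propagated; call propagate_annotations() first")
    term_ids <- names(terms$propagated)
    info <- terms$terms[match(term_ids, terms$terms$id), ]
    if (!is.null(namespaces)) {
      keep_ns <- info$namespace %in% namespaces
      term_ids <- term_ids[keep_ns]; info <- info[keep_ns, , drop = FALSE]
    }
    gene_sets <- terms$propagated[term_ids]
    term_name <- info$name
    database <- info$namespace
  } else if (inherits(terms, "pathway_collection")) {
    term_ids <- names(terms$sets)
    gene_sets <- terms$sets
    idx <- match(term_ids, terms$meta$key)
    term_name <- terms$meta$name[idx]
    database <- terms$meta$database[idx]
  } else stop("`terms` must be an annotation_set or a pathway_collection")

  gene_sets <- lapply(gene_sets, intersect, y = universe)
  M <- lengths(gene_sets)
  testable <- M >= min_term_size
  lf_log("testing %d/%d terms with M >= %d annotated genes",
         sum(testable), length(M), min_term_size)
  if (!any(testable)) {
    res <- empty_enrichment()
    attr(res, "correction_method") <- correction
    return(res)
  }
  gene_sets <- gene_sets[testable]
  term_ids <- term_ids[testable]; term_name <- term_name[testable]
  database <- database[testable]; M <- M[testable]
  N <- length(universe)
  n <- length(query_genes)
  m <- vapply(gene_sets, function(s) length(intersect(query_genes, s)), integer(1L))
  p_raw <- vapply(seq_along(M), function(i) hypergeom_pvalue(N, M[i], n, m[i]),
                  numeric(1L))
  p_corrected <- if (correction == "BY") benjamini_yekutieli(p_raw) else benjamini_hochberg(p_raw)
  res <- data.frame(
    term_id = term_ids, term_name = term_name, database = database,
    N = N, M = as.integer(M), n = n, m = m,
    p_raw = p_raw, p_corrected = p_corrected,
    significant = p_corrected < alpha,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p_corrected, res$p_raw, res$term_id), ]
  rownames(res) <- NULL
  attr(res, "correction_method") <- correction
  res
}

empty_enrichment <- function() {
  data.frame(term_id = character(0), term_name = character(0),
             database = character(0), N = integer(0), M = integer(0),
             n = integer(0), m = integer(0), p_raw = numeric(0),
             p_corrected = numeric(0), significant = logical(0),
             stringsAsFactors = FALSE)
}

#' Functionally annotate one lncRNA
#'
#' Looks up the protein-coding genes significantly co-expressed with the
#' lncRNA in the network, then runs GO enrichment (corrected with BY, because
#' hierarchical GO terms are dependent) and pathway enrichment (corrected
#' with BH) as two separate families. lncRNAs with fewer than `min_coexp`
#' co-expressed coding genes — or absent from the network — yield an explicit
#' not-annotatable outcome, distinct from empty results.
#'
#' @param lncrna_id Query lncRNA identifier.
#' @param network A `coexpression_network`.
#' @param go Propagated `annotation_set`.
#' @param pathways A `pathway_collection` (or `NULL` to skip pathways).
#' @param universe Protein-coding gene universe (size N of the test).
#' @param min_coexp Minimum number of co-expressed coding genes, default 5.
#' @inheritParams enrich
#' @return An `lncrna_annotation`: `status` (`"annotated"` or
#'   `"not_annotatable"`), `reason`, `n_coexpressed`, `coexpressed`, `go` and
#'   `pathway` result tables.
#' @export
annotate_lncrna <- function(lncrna_id, network, go, pathways, universe,
                            min_coexp = 5L, min_term_size = 5L, alpha = 0.05,
                            namespaces = NULL) {
  stopifnot(inherits(network, "coexpression_network"))
  known <- lncrna_id %in% network$edges$lncrna_id
  coexp <- if (known) coexpressed_set(network, lncrna_id) else character(0)
  not_ok <- if (!known) "absent from network"
    else if (length(coexp) < min_coexp)
      sprintf("only %d co-expressed protein-coding genes (minimum %d)",
              length(coexp), min_coexp)
    else NA_character_
  if (!is.na(not_ok)) {
    return(structure(
      list(lncrna_id = lncrna_id, status = "not_annotatable", reason = not_ok,
           n_coexpressed = length(coexp), coexpressed = coexp,
           go = empty_enrichment(), pathway = empty_enrichment()),
      class = "lncrna_annotation"))
  }
  go_res <- if (is.null(go)) empty_enrichment()
    else enrich(coexp, go, universe, min_term_size = min_term_size,
                correction = "BY", alpha = alpha, namespaces = namespaces)
  pw_res <- if (is.null(pathways)) empty_enrichment()
    else enrich(coexp, pathways, universe, min_term_size = min_term_size,
                correction = "BH", alpha = alpha)
  structure(
    list(lncrna_id = lncrna_id, status = "annotated", reason = NA_character_,
         n_coexpressed = length(coexp), coexpressed = coexp,
         go = go_res, pathway = pw_res),
    class = "lncrna_annotation")
}

#' @export
print.lncrna_annotation <- function(x, ...) {
  if (x$status == "not_annotatable") {
    cat(sprintf("lncRNA %s: not annotatable (%s)\n", x$lncrna_id, x$reason))
  } else {
    cat(sprintf("lncRNA %s: %d co-expressed coding genes; %d/%d GO terms and %d/%d pathways significant\n",
                x$lncrna_id, x$n_coexpressed,
                sum(x$go$significant), nrow(x$go),
                sum(x$pathway$significant), nrow(x$pathway)))
  }
  invisible(x)
}

#' Write an enrichment result table as TSV
#'
#' Mirrors the layout of published annotation tables: term, database,
#' background frequency `M/N`, sample frequency `m/n`, raw and corrected
#' p-values.
#'
#' @param res Result `data.frame` from [enrich()].
#' @param path Output path.
#' @param significant_only Keep only rows passing the significance flag.
#' @export
write_enrichment_tsv <- function(res, path, significant_only = FALSE) {
  if (significant_only) res <- res[res$significant, , drop = FALSE]
  out <- data.frame(
    term = res$term_name, term_id = res$term_id, database = res$database,
    background_frequency = sprintf("%d/%d", res$M, res$N),
    sample_frequency = sprintf("%d/%d", res$m, res$n),
    p_value = format(res$p_raw, digits = 6, scientific = TRUE, trim = TRUE),
    corrected_p_value = format(res$p_corrected, digits = 6, scientific = TRUE,
                               trim = TRUE),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
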