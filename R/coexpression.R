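#' Pearson correlation between two expression profiles
#'
#' Standard sample Pearson correlation, clamped to `[-1, 1]` against floating
#' point rounding. A zero-variance profile has no defined correlation and is a
#' hard error; callers computing all pairs drop such genes up front.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero-variance profile")
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact test for bivariate-normal data: `t = r * sqrt(n-2) /
#' sqrt(1-r^2)` on `n - 2` degrees of freedom, two-sided. `r = +/-1` gives
#' `p = 0` exactly. Vectorized over `r`.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @param n Number of paired observations (conditions), >= 3.
#' @return Two-sided p-value(s).
#' @export
pearson_pvalue <- function(r, n) {
  if (n < 3L) stop("need n >= 3 conditions for a correlation test")
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  tstat <- abs(r[ok]) * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  pmin(p, 1)
}

#' Correlation and significance for all lncRNA x coding-gene pairs
#'
#' Computes the Pearson correlation of every lncRNA profile against every
#' protein-coding profile over the shared conditions, with the two-sided
#' p-value from [pearson_pvalue()]. Genes with zero variance are dropped (the
#' correlation is undefined for them) with a logged count. Work is blocked by
#' lncRNA rows so memory stays proportional to one block; results are
#' identical for any block size. Output order is lexicographic by lncRNA ID,
#' then coding ID.
#'
#' @param lnc,coding Expression matrices over the same conditions.
#' @param block_size Number of lncRNA rows correlated per block.
#' @return `data.frame` with columns `lncrna_id`, `coding_id`, `r`, `p_raw`,
#'   carrying the condition count in attribute `n_conditions`.
#' @export
coexpress_all_pairs <- function(lnc, coding, block_size = 512L) {
  validate_expression_matrix(lnc)
  validate_expression_matrix(coding)
  if (!identical(colnames(lnc), colnames(coding)))
    stop("lncRNA and coding matrices must share the same conditions in the same order")
  n <- ncol(lnc)
  lnc_var <- apply(lnc, 1L, stats::sd) > 0
  cod_var <- apply(coding, 1L, stats::sd) > 0
  n_dropped_pairs <- sum(!lnc_var) * nrow(coding) +
    sum(lnc_var) * sum(!cod_var)
  if (n_dropped_pairs)
    lf_log("dropping %d pair(s) involving %d zero-variance gene(s)",
           n_dropped_pairs, sum(!lnc_var) + sum(!cod_var))
  lnc <- lnc[lnc_var, , drop = FALSE]
  coding <- coding[cod_var, , drop = FALSE]
  if (!nrow(lnc) || !nrow(coding)) stop("no variable genes left to correlate")
  lnc <- lnc[order(rownames(lnc)), , drop = FALSE]
  coding <- coding[order(rownames(coding)), , drop = FALSE]
  tc <- t(coding)
  chunks <- split(seq_len(nrow(lnc)), ceiling(seq_len(nrow(lnc)) / block_size))
  res <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    rmat <- stats::cor(t(lnc[idx, , drop = FALSE]), tc)
    rmat[rmat > 1] <- 1
    rmat[rmat < -1] <- -1
    res[[ci]] <- data.frame(
      lncrna_id = rep(rownames(lnc)[idx], each = nrow(coding)),
      coding_id = rep(rownames(coding), times = length(idx)),
      r = as.vector(t(rmat)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$p_raw <- pearson_pvalue(out$r, n)
  lf_log("tested %d lncRNA x %d coding = %d pairs over %d conditions",
         nrow(lnc), nrow(coding), nrow(out), n)
  attr(out, "n_conditions") <- n
  out
}

#' Adjust pair p-values and keep the significant co-expression network
#'
#' Adjusts the raw p-values over all tested pairs as one family, then retains
#' the pairs with `|r| > r_cutoff` (strict) and adjusted p `< alpha` (strict).
#'
#' @param pairs Output of [coexpress_all_pairs()].
#' @param r_cutoff Absolute-correlation threshold, default 0.9.
#' @param alpha Significance level on the adjusted p-value, default 0.05.
#' @param method Multiple-testing correction, `"BH"` (default) or `"BY"`.
#' @param n_conditions Condition count; defaults to the attribute set by
#'   [coexpress_all_pairs()].
#' @return A `coexpression_network` object.
#' @export
adjust_and_filter <- function(pairs, r_cutoff = 0.9, alpha = 0.05,
                              method = c("BH", "BY"),
                              n_conditions = attr(pairs, "n_conditions")) {
  method <- match.arg(method)
  if (!nrow(pairs)) stop("empty pair collection")
  if (is.null(n_conditions)) stop("n_conditions not supplied and not found on `pairs`")
  p_adj <- if (method == "BH") benjamini_hochberg(pairs$p_raw) else benjamini_yekutieli(pairs$p_raw)
  keep <- abs(pairs$r) > r_cutoff & p_adj < alpha
  edges <- pairs[keep, c("lncrna_id", "coding_id", "r", "p_raw"), drop = FALSE]
  edges$p_adj <- p_adj[keep]
  rownames(edges) <- NULL
  lf_log("retained %d/%d significant pairs (|r| > %g, %s-adjusted p < %g)",
         nrow(edges), nrow(pairs), r_cutoff, method, alpha)
  structure(
    list(edges = edges, n_conditions = as.integer(n_conditions),
         n_tested = nrow(pairs), r_cutoff = r_cutoff, alpha = alpha,
         method = method),
    class = "coexpression_network"
  )
}

#' Build a co-expression network in one call
#'
#' Convenience wrapper: [coexpress_all_pairs()] followed by
#' [adjust_and_filter()].
#'
#' @inheritParams coexpress_all_pairs
#' @inheritParams adjust_and_filter
#' @export
build_network <- function(lnc, coding, r_cutoff = 0.9, alpha = 0.05,
                          method = "BH", block_size = 512L) {
  pairs <- coexpress_all_pairs(lnc, coding, block_size = block_size)
  adjust_and_filter(pairs, r_cutoff = r_cutoff, alpha = alpha, method = method)
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "Co-expression network: %d edges (%d lncRNAs, %d coding genes)\n",
    nrow(x$edges), length(unique(x$edges$lncrna_id)),
    length(unique(x$edges$coding_id))))
  cat(sprintf("  %d pairs tested over %d conditions; |r| > %g, %s-adjusted p < %g\n",
              x$n_tested, x$n_conditions, x$r_cutoff, x$method, x$alpha))
  invisible(x)
}

#' Coding genes significantly co-expressed with one lncRNA
#'
#' @param network A `coexpression_network`.
#' @param lncrna_id Query lncRNA identifier. Unknown IDs yield an empty set
#'   with a warning.
#' @return Character vector of coding gene IDs (unique, sorted).
#' @export
coexpressed_set <- function(network, lncrna_id) {
  stopifnot(inherits(network, "coexpression_network"))
  hit <- network$edges$lncrna_id == lncrna_id
  if (!any(hit)) {
    warning("lncRNA '", lncrna_id, "' is absent from the network")
    return(character(0))
  }
  sort(unique(network$edges$coding_id[hit]))
}

#' Write / read a co-expression network as TSV
#'
#' Columns `lncrna_id`, `coding_id`, `r`, `p_raw`, `p_adj`; numeric values at
#' 17 significant digits so a round trip is lossless. Network-level
#' parameters are carried in `#`-prefixed header comments.
#'
#' @param network A `coexpression_network`.
#' @param path Output path.
#' @export
write_network_tsv <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_conditions=%d n_tested=%d r_cutoff=%s alpha=%s method=%s",
                     network$n_conditions, network$n_tested,
                     format(network$r_cutoff, digits = 17),
                     format(network$alpha, digits = 17), network$method), con)
  writeLines("lncrna_id\tcoding_id\tr\tp_raw\tp_adj", con)
  if (nrow(network$edges)) {
    fmt <- function(v) format(v, digits = 17, scientific = TRUE, trim = TRUE)
    writeLines(paste(network$edges$lncrna_id, network$edges$coding_id,
                     fmt(network$edges$r), fmt(network$edges$p_raw),
                     fmt(network$edges$p_adj), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  lines <- readLines(path, n = 1L)
  meta <- list(n_conditions = NA_integer_, n_tested = NA_integer_,
               r_cutoff = NA_real_, alpha = NA_real_, method = "BH")
  if (startsWith(lines[1L], "#")) {
    kv <- regmatches(lines[1L], gregexpr("[a-z_]+=[^ ]+", lines[1L]))[[1L]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1L]]
      meta[[parts[1L]]] <- parts[2L]
    }
  }
  edges <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                             colClasses = c("character", "character",
                                            "numeric", "numeric", "numeric"))
  structure(
    list(edges = edges, n_conditions = as.integer(meta$n_conditions),
         n_tested = as.integer(meta$n_tested),
         r_cutoff = as.numeric(meta$r_cutoff), alpha = as.numeric(meta$alpha),
         method = meta$method),
    class = "coexpression_network"
  )
}
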