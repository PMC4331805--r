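# Independent oracles used across the suite. Everything here is deliberately
# naive/brute-force and shares no code with the package implementation.

# ---- exact integer arithmetic (base 2^24 limbs, little-endian) -------------
# All binomials and partial sums needed for N <= 60 are bounded by
# C(60, 30) < 2^57, i.e. at most 3 limbs; every limb operation below stays
# below 2^53, so the arithmetic is exact. The only rounding is the final
# conversion to double (~1e-16), far under the 1e-6 comparison tolerance.

BIG_BASE <- 2^24

big_norm <- function(x) {
  i <- 1L
  while (i <= length(x)) {
    carry <- floor(x[i] / BIG_BASE)
    if (carry > 0) {
      x[i] <- x[i] - carry * BIG_BASE
      if (i == length(x)) x <- c(x, 0)
      x[i + 1L] <- x[i + 1L] + carry
    }
    i <- i + 1L
  }
  x
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

big_mul <- function(a, b) {
  res <- rep(0, length(a) + length(b))
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    res[idx] <- res[idx] + a[i] * b
    res <- big_norm(res)
  }
  res
}

big_to_double <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1L))

# Pascal's triangle of exact binomial coefficients up to row `nmax`:
# big_binom[[r + 1]][[k + 1]] == C(r, k).
build_big_binom <- function(nmax) {
  tri <- vector("list", nmax + 1L)
  tri[[1L]] <- list(c(1))
  for (r in seq_len(nmax)) {
    prev <- tri[[r]]
    row <- vector("list", r + 1L)
    row[[1L]] <- c(1)
    row[[r + 1L]] <- c(1)
    if (r > 1L) for (k in 2:r)
      row[[k]] <- big_add(prev[[k - 1L]], prev[[k]])
    tri[[r + 1L]] <- row
  }
  tri
}

big_choose <- function(tri, n, k) {
  if (k < 0 || k > n) return(c(0))
  tri[[n + 1L]][[k + 1L]]
}

# Exact hypergeometric upper-tail probabilities for all cutoffs:
# element m + 1 is P(X >= m), m = 0..min(n, M), computed by exact integer
# summation of C(M, i) * C(N - M, n - i) over i >= m, divided by C(N, n).
oracle_hyper_tails <- function(N, M, n, tri) {
  k <- min(n, M)
  acc <- c(0)
  out <- numeric(k + 1L)
  den <- big_to_double(big_choose(tri, N, n))
  for (i in k:0) {
    term <- big_mul(big_choose(tri, M, i), big_choose(tri, N - M, n - i))
    acc <- big_add(acc, term)
    out[i + 1L] <- big_to_double(acc) / den
  }
  out
}

# ---- hand-stepped FDR procedures -------------------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  stepped <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(stepped)))
  pmin(adj, 1)[order(o)]
}

oracle_by <- function(p) {
  pmin(oracle_bh(p) * sum(1 / seq_along(p)), 1)
}

# ---- brute-force ontology propagation --------------------------------------

# Descendants by explicit edge-chasing: a term's propagated genes are the
# union of direct sets over itself and every term from which it is reachable
# via child -> parent edges.
oracle_propagate <- function(dag, direct) {
  desc_closure <- function(t) {
    members <- t
    repeat {
      more <- dag$edges$child[dag$edges$parent %in% members]
      new <- setdiff(more, members)
      if (!length(new)) break
      members <- c(members, new)
    }
    members
  }
  out <- lapply(dag$terms$id, function(t) {
    g <- unlist(direct[desc_closure(t)], use.names = FALSE)
    if (is.null(g)) character(0) else sort(unique(g))
  })
  names(out) <- dag$terms$id
  out
}

# Random DAG: edges only from higher-numbered child to lower-numbered parent,
# guaranteeing acyclicity by construction.
random_dag <- function(n_terms, edge_prob = 0.15) {
  ids <- sprintf("T:%03d", seq_len(n_terms))
  child <- character(0); parent <- character(0)
  for (i in seq_len(n_terms)[-1L]) {
    par <- which(stats::runif(i - 1L) < edge_prob)
    if (!length(par)) par <- sample.int(i - 1L, 1L)  # keep it connected
    child <- c(child, rep(ids[i], length(par)))
    parent <- c(parent, ids[par])
  }
  structure(
    list(terms = data.frame(id = ids, name = ids,
                            namespace = "biological_process",
                            stringsAsFactors = FALSE),
         edges = data.frame(child = child, parent = parent, type = "is_a",
                            stringsAsFactors = FALSE),
         obsolete = character(0)),
    class = "ontology_dag")
}

random_direct <- function(dag, n_genes = 30L, p_annot = 0.1) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  direct <- lapply(dag$terms$id, function(t) {
    g <- genes[stats::runif(n_genes) < p_annot]
    sort(g)
  })
  names(direct) <- dag$terms$id
  direct[lengths(direct) > 0L]
}
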