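# Internal helpers shared across modules.

# Progress/filter-count logging. Uses message() so callers can suppress with
# suppressMessages(); every filtering stage reports its counts through here.
lf_log <- function(fmt, ...) {
  message(sprintf(paste0("[lncfun] ", fmt), ...))
}

# log(sum(exp(x))) without overflow/underflow; x may contain -Inf.
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Reverse cumulative logsumexp: out[i] = log(sum(exp(x[i:length(x)]))).
# Used for hypergeometric tail probabilities at every cutoff at once.
rev_cum_logsumexp <- function(x) {
  k <- length(x)
  out <- numeric(k)
  acc <- -Inf
  for (i in k:1L) {
    m <- max(acc, x[i])
    acc <- if (is.finite(m)) m + log(exp(acc - m) + exp(x[i] - m)) else m
    out[i] <- acc
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
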