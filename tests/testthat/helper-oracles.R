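# Independent oracles, deliberately implemented from first principles and
# kept apart from the package's computation paths.

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# n-subsets of a universe of size N in which the first K elements form the
# pathway. Exact rational arithmetic via integer counting.
oracle_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(if (k == 0) 1 else stop("k > n"))
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  sum(hits >= k) / ncol(subsets)
}

# Textbook Benjamini-Hochberg step-up, written directly from the
# definition: sort ascending, q_(i) = min_{j >= i} p_(j) * m / j, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ranked <- p[o]
  q <- ranked * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Partial hallmark score from its defining formula.
oracle_partial <- function(pvals, N_h) {
  R <- length(pvals)
  if (R == 0) return(0)
  sum(-log10(pvals)) * N_h * (1 + log2(R + 1) / 4)
}

# Diversity factor from its defining formula (entropy in bits over the
# non-zero scores, normalized by log2 of the total hallmark count).
oracle_df <- function(scores, N_t = 11) {
  nz <- scores[scores > 0]
  if (length(nz) == 0) return(0)
  q <- nz / sum(nz)
  H <- -sum(q * log2(q))
  (length(nz) / N_t) * (1 + H / log2(N_t))
}

# Total score as a one-line composition of the definitions.
oracle_total <- function(combined, N_t = 11) {
  sum(combined) * oracle_df(combined, N_t)
}
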