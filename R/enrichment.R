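#' Upper-tail hypergeometric probability for over-representation
#'
#' Probability of observing at least `k` members of a pathway of size `K` in
#' a query of size `n` drawn from a universe of size `N` — the one-sided
#' Fisher/hypergeometric over-representation p-value. Computed with
#' [stats::phyper()], which works on log-factorials and is numerically
#' stable.
#'
#' @param k observed overlap count (vectorized).
#' @param K pathway (gene-set) size.
#' @param n query size.
#' @param N universe (background) size.
#' @return p-value(s) in (0, 1].
#' @export
#' @examples
#' hypergeom_upper_tail(3, 5, 5, 20)  # 1126/15504
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0) || any(K < 0) || any(n < 0) || any(N < 0)) {
    stop("counts must be non-negative")
  }
  if (any(K > N) || any(n > N)) stop("K and n must not exceed N")
  if (any(k > pmin(n, K))) stop("k must not exceed min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate correction, returned in input
#' order. Thin wrapper over [stats::p.adjust()] with input validation:
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same length and order; `q >= p`
#'   elementwise.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# Internal: fast overlap machinery. Returns pathway x gene 0/1 membership
# matrix plus per-pathway sizes, built once per library and reused across
# thousands of resampling draws.
library_index <- function(library) {
  idx <- attr(library, ".index")
  if (!is.null(idx)) return(idx)
  universe <- library$universe
  ids <- names(library$sets)
  M <- matrix(0, nrow = length(ids), ncol = length(universe),
              dimnames = list(ids, NULL))
  pos <- lapply(library$sets, function(s) match(s$members, universe))
  for (i in seq_along(ids)) M[i, pos[[i]]] <- 1
  list(M = M, K = rowSums(M), ids = ids, universe = universe,
       N = length(universe))
}

# Internal: overlap counts of pathways (rows) with query gene-index masks
# (columns of Q, a n_genes x n_queries 0/1 matrix).
overlap_counts <- function(idx, Q) {
  idx$M %*% Q
}

#' Test a gene query for pathway over-representation
#'
#' Tests every pathway in the library with the one-sided hypergeometric test
#' against the library universe and keeps pathways with `p < alpha`
#' (strict). Query genes outside the universe are dropped (their count is
#' recorded in the result).
#'
#' @param query character vector of gene symbols.
#' @param library a [gene_set_library()].
#' @param alpha significance gate on the raw enrichment p-value
#'   (default 0.001).
#' @param disease_id optional label carried into the result.
#' @return An object of class `enriched_set`: list with `disease_id`,
#'   `alpha`, `n_query` (effective query size), `n_dropped`, and `results`,
#'   a data frame (pathway_id, k, K, n, N, p_value) sorted by ascending
#'   p-value then pathway_id.
#' @export
enrich <- function(query, library, alpha = 0.001, disease_id = NA_character_) {
  stopifnot(inherits(library, "gene_set_library"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  query <- unique(toupper(trimws(as.character(query))))
  query <- query[nzchar(query)]
  if (length(query) == 0) stop("empty query: no genes supplied")
  idx <- library_index(library)
  pos <- match(query, idx$universe)
  n_dropped <- sum(is.na(pos))
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0) {
    stop("empty effective query: none of the ", length(query),
         " query genes are in the library universe")
  }
  qmask <- matrix(0, nrow = idx$N, ncol = 1)
  qmask[pos, 1] <- 1
  k <- as.numeric(overlap_counts(idx, qmask))
  n <- length(pos)
  p <- hypergeom_upper_tail(k, idx$K, n, idx$N)
  keep <- which(p < alpha)
  res <- data.frame(pathway_id = idx$ids[keep], k = as.integer(k[keep]),
                    K = as.integer(idx$K[keep]),
                    n = rep(n, length(keep)), N = rep(idx$N, length(keep)),
                    p_value = p[keep], stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(disease_id = disease_id, alpha = alpha, n_query = n,
                 n_dropped = n_dropped, results = res),
            class = "enriched_set")
}

#' @export
print.enriched_set <- function(x, ...) {
  cat("Enriched set", if (!is.na(x$disease_id)) paste0(" for '", x$disease_id, "'"),
      ": ", nrow(x$results), " pathways at p < ", x$alpha,
      " (query of ", x$n_query, " genes", sep = "")
  if (x$n_dropped > 0) cat(", ", x$n_dropped, " outside universe dropped", sep = "")
  cat(")\n")
  if (nrow(x$results) > 0) print(utils::head(x$results, 10), row.names = FALSE)
  invisible(x)
}
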