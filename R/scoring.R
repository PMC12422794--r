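#' Scoring configuration
#'
#' Collects every tunable constant of the pipeline. Defaults follow the
#' published design: targets with association score > 0.4 are kept, the top
#' 60 by score are the sampling pool, 50 are drawn per resample, the
#' procedure repeats 250 times, pathways are enriched at raw p < 0.001, and
#' hallmark cells with BH q >= 0.001 are flagged not significant.
#'
#' @param min_assoc strict lower bound on the association score (default 0.4).
#' @param top_k size of the ranked sampling pool (default 60).
#' @param sample_size genes drawn per resample without replacement
#'   (default 50).
#' @param n_samples number of resamples per disease (default 250).
#' @param enrich_alpha raw enrichment p-value gate (default 0.001, strict).
#' @param q_threshold BH q reporting threshold; cells with q >= this are
#'   flagged NS (default 0.001).
#' @param w_pathway weight of the pathway enrichment component (default 1).
#' @param w_genelist weight of the gene-list over-representation component
#'   (default 0.25; lower because gene-level hallmark annotation is sparser
#'   than pathway-level annotation). Only active when a gene map is present.
#' @param n_perm permutation count for `sig_method = "permutation"`
#'   (default 999).
#' @param seed master RNG seed; per-disease substreams are derived from it.
#' @param entropy_base_total logical; normalize the entropy in the diversity
#'   factor by log2 of the total hallmark count (default TRUE) rather than
#'   by log2 of the number of non-zero hallmarks.
#' @param norm_strategy hallmark normalizer: `"inverse_frequency"` (default)
#'   scales each hallmark by mean pathway count over populated hallmarks
#'   divided by its own count; `"uniform"` sets every populated hallmark's
#'   weight to 1.
#' @param sig_method significance test for "hallmark score > 0":
#'   `"binomial"` (default) is a one-sided sign test on the number of
#'   resamples with a positive score; `"permutation"` compares the observed
#'   mean against scores of random same-size gene sets with the add-one
#'   estimator. The binomial default is used because the add-one
#'   permutation p cannot fall below 1/(n_perm + 1), which at practical
#'   permutation counts can never clear a q < 0.001 call.
#' @param bh_family `"global"` (default) corrects all disease x hallmark
#'   cells as one family; `"per_disease"` corrects within each disease.
#' @param ci_method `"percentile"` (default) 2.5/97.5 empirical percentiles
#'   of the resampled scores; `"normal"` mean +/- 1.96 SD.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(min_assoc = 0.4, top_k = 60, sample_size = 50,
                           n_samples = 250, enrich_alpha = 0.001,
                           q_threshold = 0.001, w_pathway = 1.0,
                           w_genelist = 0.25, n_perm = 999, seed = 1,
                           entropy_base_total = TRUE,
                           norm_strategy = c("inverse_frequency", "uniform"),
                           sig_method = c("binomial", "permutation"),
                           bh_family = c("global", "per_disease"),
                           ci_method = c("percentile", "normal")) {
  norm_strategy <- match.arg(norm_strategy)
  sig_method <- match.arg(sig_method)
  bh_family <- match.arg(bh_family)
  ci_method <- match.arg(ci_method)
  stopifnot(min_assoc >= 0, min_assoc <= 1)
  stopifnot(top_k >= 1, sample_size >= 1, sample_size <= top_k)
  stopifnot(n_samples >= 1, n_perm >= 1)
  stopifnot(enrich_alpha > 0, enrich_alpha <= 1)
  stopifnot(q_threshold > 0, q_threshold <= 1)
  stopifnot(w_pathway >= 0, w_genelist >= 0)
  structure(list(min_assoc = min_assoc, top_k = as.integer(top_k),
                 sample_size = as.integer(sample_size),
                 n_samples = as.integer(n_samples),
                 enrich_alpha = enrich_alpha, q_threshold = q_threshold,
                 w_pathway = w_pathway, w_genelist = w_genelist,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 entropy_base_total = isTRUE(entropy_base_total),
                 norm_strategy = norm_strategy, sig_method = sig_method,
                 bh_family = bh_family, ci_method = ci_method),
            class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("Scoring configuration:\n")
  for (nm in names(x)) cat("  ", nm, " = ", as.character(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Select high-evidence targets as the sampling pool
#'
#' Keeps genes with association score strictly greater than `min_assoc`,
#' sorts by (score descending, gene ascending), and truncates to the top
#' `top_k`.
#'
#' @param table a [target_table()].
#' @param min_assoc strict score threshold (default 0.4).
#' @param top_k pool size cap (default 60).
#' @param sample_size optional; if given, warn when fewer than `sample_size`
#'   genes survive the filter.
#' @return Character vector of ranked gene symbols.
#' @export
select_targets <- function(table, min_assoc = 0.4, top_k = 60,
                           sample_size = NULL) {
  stopifnot(inherits(table, "target_table"))
  keep <- table$score > min_assoc
  if (!any(keep)) {
    stop("no high-evidence targets: no gene has association score > ", min_assoc)
  }
  df <- table[keep, , drop = FALSE]
  o <- order(-df$score, df$gene)
  ranked <- utils::head(df$gene[o], top_k)
  if (!is.null(sample_size) && length(ranked) < sample_size) {
    warning("only ", length(ranked), " targets pass the filter; fewer than the ",
            "sample size of ", sample_size, " (sampling is degenerate)")
  }
  ranked
}

#' Per-hallmark normalizers for uneven pathway annotation density
#'
#' Hallmarks with many annotated pathways accumulate -log10(p) mass more
#' easily than sparsely annotated ones. The inverse-frequency normalizer
#' corrects this: with `C_h` the number of library pathways annotated to
#' hallmark `h`, `N_h = mean(C over populated hallmarks) / C_h` for
#' `C_h > 0` and 0 otherwise, so the weights average 1 and are equal when
#' annotation is uniform. The `"uniform"` strategy sets `N_h = 1` for every
#' populated hallmark.
#'
#' @param library a [gene_set_library()].
#' @param ann a [hallmark_annotation()].
#' @param strategy `"inverse_frequency"` (default) or `"uniform"`.
#' @return An object of class `hallmark_normalizers`: list with named
#'   numeric `N` and named integer `C` over [aging_hallmarks()].
#' @export
hallmark_normalizers <- function(library, ann,
                                 strategy = c("inverse_frequency", "uniform")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(library, "gene_set_library"),
            inherits(ann, "hallmark_annotation"))
  vocab <- aging_hallmarks()
  in_lib <- names(ann$pathway_map) %in% names(library$sets)
  pmap <- ann$pathway_map[in_lib]
  C <- vapply(vocab, function(h) {
    sum(vapply(pmap, function(x) h %in% x, logical(1)))
  }, integer(1))
  if (all(C == 0)) stop("no library pathway carries a hallmark annotation")
  N <- numeric(length(vocab))
  names(N) <- vocab
  pos <- C > 0
  if (strategy == "inverse_frequency") {
    N[pos] <- mean(C[pos]) / C[pos]
  } else {
    N[pos] <- 1
  }
  structure(list(N = N, C = C, strategy = strategy),
            class = "hallmark_normalizers")
}

#' Partial hallmark scores from an enriched pathway set
#'
#' For each hallmark `h`, let `R_h` be the enriched pathways annotated to
#' `h` (a multi-label pathway joins every hallmark it carries). The partial
#' score is
#' \deqn{P_h = \left[\sum_{p \in R_h} -\log_{10}(p_p)\right] \times N_h
#'   \times \left(1 + \frac{\log_2(|R_h| + 1)}{4}\right)}
#' i.e. the -log10 p-value mass of the hallmark's enriched pathways, scaled
#' by the annotation-density normalizer and a bonus that rewards several
#' independent pathways pointing at the same hallmark. Hallmarks with empty
#' `R_h` score 0.
#'
#' @param enriched an `enriched_set` from [enrich()].
#' @param ann a [hallmark_annotation()].
#' @param norms a [hallmark_normalizers()] computed from the same library.
#' @return List with named numeric `score` (P_h) and named integer `count`
#'   (|R_h|) over [aging_hallmarks()].
#' @export
partial_hallmark_scores <- function(enriched, ann, norms) {
  stopifnot(inherits(enriched, "enriched_set"),
            inherits(ann, "hallmark_annotation"),
            inherits(norms, "hallmark_normalizers"))
  vocab <- aging_hallmarks()
  score <- stats::setNames(numeric(length(vocab)), vocab)
  count <- stats::setNames(integer(length(vocab)), vocab)
  res <- enriched$results
  if (nrow(res) > 0) {
    labs <- ann$pathway_map[res$pathway_id]
    for (i in seq_len(nrow(res))) {
      hs <- labs[[i]]
      if (is.null(hs)) next  # unannotated pathway contributes nowhere
      score[hs] <- score[hs] - log10(res$p_value[i])
      count[hs] <- count[hs] + 1L
    }
  }
  score <- score * norms$N * (1 + log2(count + 1) / 4)
  list(score = score, count = count)
}

#' Gene-list hallmark component
#'
#' Over-representation of the sampled genes directly in per-hallmark gene
#' lists (when a gene map is available): `G_h` is the -log10 upper-tail
#' hypergeometric p of the overlap between the sample and hallmark `h`'s
#' gene list against the universe, clamped to 0 when the overlap is empty.
#' Kept on the same -log10 p scale as the pathway term so the two can be
#' combined by weights.
#'
#' @param sample character vector of sampled gene symbols.
#' @param ann a [hallmark_annotation()]; if its `gene_map` is `NULL` the
#'   component is disabled and all `G_h = 0`.
#' @param universe character vector: the enrichment background.
#' @return Named numeric `G_h` over [aging_hallmarks()], with attribute
#'   `enabled`.
#' @export
genelist_component <- function(sample, ann, universe) {
  stopifnot(inherits(ann, "hallmark_annotation"))
  vocab <- aging_hallmarks()
  G <- stats::setNames(numeric(length(vocab)), vocab)
  if (is.null(ann$gene_map)) {
    attr(G, "enabled") <- FALSE
    return(G)
  }
  sample <- unique(toupper(sample))
  sample <- intersect(sample, universe)
  N <- length(universe)
  n <- length(sample)
  for (h in vocab) {
    genes_h <- names(ann$gene_map)[vapply(ann$gene_map, function(x) h %in% x,
                                          logical(1))]
    genes_h <- intersect(genes_h, universe)
    K <- length(genes_h)
    if (K == 0 || n == 0) next
    k <- length(intersect(sample, genes_h))
    if (k == 0) next
    G[h] <- -log10(hypergeom_upper_tail(k, K, n, N))
  }
  attr(G, "enabled") <- TRUE
  G
}

#' Diversity factor of a hallmark score distribution
#'
#' Rewards diseases whose score mass spreads across many hallmarks rather
#' than concentrating in one:
#' \deqn{D_f = \frac{N_{nz}}{N_t} (1 + E_n)}
#' with `N_nz` the number of hallmarks with a positive score, `N_t` the
#' total number of hallmarks (11), and `E_n` the normalized Shannon entropy
#' (base 2) of the score distribution. With the default normalization by
#' `log2(N_t)`, a perfectly even spread over all hallmarks gives `E_n = 1`
#' and `D_f = 2`; a single non-zero hallmark gives `D_f = 1/N_t`. All-zero
#' scores give `D_f = 0`.
#'
#' @param scores non-negative numeric vector of per-hallmark scores.
#' @param n_total total number of hallmarks `N_t` (default
#'   `length(aging_hallmarks())`).
#' @param entropy_base_total normalize entropy by `log2(n_total)` (default)
#'   rather than `log2(N_nz)`.
#' @return List with `df`, `n_nonzero`, `entropy_norm`.
#' @export
diversity_factor <- function(scores, n_total = length(aging_hallmarks()),
                             entropy_base_total = TRUE) {
  scores <- as.numeric(scores)
  if (any(is.na(scores)) || any(scores < 0)) stop("scores must be non-negative")
  stopifnot(n_total >= 1)
  nz <- scores[scores > 0]
  n_nz <- length(nz)
  if (n_nz == 0) return(list(df = 0, n_nonzero = 0L, entropy_norm = 0))
  q <- nz / sum(nz)
  H <- -sum(q * log2(q))
  denom <- if (entropy_base_total) log2(n_total) else log2(n_nz)
  E_n <- if (denom > 0) H / denom else 0
  list(df = (n_nz / n_total) * (1 + E_n), n_nonzero = n_nz, entropy_norm = E_n)
}

#' Total aging-alignment score for one gene sample
#'
#' Combines the pathway and gene-list components per hallmark
#' (`combined_h = w_pathway * P_h + w_genelist * G_h`), computes the
#' diversity factor on the combined scores, and returns the total
#' \deqn{A_d = \left(\sum_h combined_h\right) \times D_f.}
#'
#' @param partial list from [partial_hallmark_scores()] (or a named numeric
#'   vector of P_h).
#' @param genelist named numeric G_h from [genelist_component()], or `NULL`.
#' @param config a [scoring_config()].
#' @return An object of class `hallmark_score_vector`: list with `partial`,
#'   `genelist`, `combined`, `count`, `d_f`, `n_nonzero`, `entropy_norm`,
#'   `total`.
#' @export
total_score <- function(partial, genelist = NULL, config = scoring_config()) {
  vocab <- aging_hallmarks()
  P <- if (is.list(partial)) partial$score else partial
  count <- if (is.list(partial)) partial$count else NULL
  stopifnot(all(vocab %in% names(P)))
  P <- P[vocab]
  G <- if (is.null(genelist)) stats::setNames(numeric(length(vocab)), vocab)
       else genelist[vocab]
  combined <- config$w_pathway * P + config$w_genelist * G
  d <- diversity_factor(combined, n_total = length(vocab),
                        entropy_base_total = config$entropy_base_total)
  structure(list(partial = P, genelist = G, combined = combined,
                 count = count, d_f = d$df, n_nonzero = d$n_nonzero,
                 entropy_norm = d$entropy_norm,
                 total = sum(combined) * d$df),
            class = "hallmark_score_vector")
}

#' @export
print.hallmark_score_vector <- function(x, ...) {
  cat("Hallmark score vector: total A_d = ", fmt_num(x$total),
      " (D_f = ", fmt_num(x$d_f), ", ", x$n_nonzero, " non-zero hallmarks)\n",
      sep = "")
  nz <- x$combined[x$combined > 0]
  if (length(nz) > 0) {
    for (h in names(sort(nz, decreasing = TRUE))) {
      cat("  ", format(h, width = 36), fmt_num(x$combined[h]), "\n", sep = "")
    }
  }
  invisible(x)
}
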