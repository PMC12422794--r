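#' Draw one target subsample
#'
#' Uniform sample without replacement of `sample_size` genes from the ranked
#' pool, using the caller's RNG stream. When the pool is not larger than the
#' sample size, the full pool is returned unchanged (degenerate sampling;
#' the short-pool warning is emitted upstream by [select_targets()]).
#'
#' @param ranked character vector: the ranked sampling pool.
#' @param sample_size number of genes to draw.
#' @return Character vector of sampled genes.
#' @export
sample_targets <- function(ranked, sample_size) {
  if (length(ranked) == 0) stop("ranked gene list is empty")
  if (length(ranked) <= sample_size) return(ranked)
  sample(ranked, sample_size)
}

# Internal: 11 x n_pathway hallmark incidence matrix aligned to a library
# index. Multi-label pathways get a 1 in every hallmark row they carry.
hallmark_incidence <- function(ann, idx) {
  vocab <- aging_hallmarks()
  H <- matrix(0, nrow = length(vocab), ncol = length(idx$ids),
              dimnames = list(vocab, idx$ids))
  pmap <- ann$pathway_map
  common <- intersect(names(pmap), idx$ids)
  for (pid in common) H[pmap[[pid]], pid] <- 1
  H
}

# Internal: 11 x n_gene incidence for the optional gene map, aligned to the
# universe. NULL when the component is disabled.
genelist_incidence <- function(ann, idx) {
  if (is.null(ann$gene_map)) return(NULL)
  vocab <- aging_hallmarks()
  G <- matrix(0, nrow = length(vocab), ncol = idx$N, dimnames = list(vocab, NULL))
  pos <- match(names(ann$gene_map), idx$universe)
  keep <- !is.na(pos)
  gm <- ann$gene_map[keep]
  pos <- pos[keep]
  for (i in seq_along(gm)) G[gm[[i]], pos[i]] <- 1
  G
}

# Internal vectorized pipeline: scores a list of gene draws in one pass.
# Exactly equivalent to enrich() -> partial_hallmark_scores() ->
# genelist_component() -> total_score() per draw (asserted by tests).
score_draws <- function(draws, idx, Hmat, Gmat, norms, config) {
  nd <- length(draws)
  vocab <- aging_hallmarks()
  Q <- matrix(0, nrow = idx$N, ncol = nd)
  n_vec <- integer(nd)
  for (j in seq_len(nd)) {
    pos <- match(draws[[j]], idx$universe)
    pos <- pos[!is.na(pos)]
    Q[pos, j] <- 1
    n_vec[j] <- length(pos)
  }
  k <- overlap_counts(idx, Q)                       # n_path x nd
  nmat <- matrix(n_vec, nrow = nrow(k), ncol = nd, byrow = TRUE)
  p <- stats::phyper(k - 1, idx$K, idx$N - idx$K, nmat, lower.tail = FALSE)
  gate <- (p < config$enrich_alpha) * 1
  mlog <- -log10(p) * gate
  S <- Hmat %*% mlog                                # 11 x nd
  R <- Hmat %*% gate
  P <- S * norms$N * (1 + log2(R + 1) / 4)
  if (!is.null(Gmat) && config$w_genelist > 0) {
    kG <- Gmat %*% Q
    KG <- rowSums(Gmat)
    nG <- matrix(n_vec, nrow = length(vocab), ncol = nd, byrow = TRUE)
    pG <- stats::phyper(kG - 1, KG, idx$N - KG, nG, lower.tail = FALSE)
    G <- ifelse(kG == 0, 0, -log10(pG))
  } else {
    G <- matrix(0, nrow = length(vocab), ncol = nd)
  }
  combined <- config$w_pathway * P + config$w_genelist * G
  rownames(combined) <- rownames(P) <- rownames(G) <- vocab
  # per-draw diversity factor and total on the combined scores
  csum <- colSums(combined)
  nnz <- colSums(combined > 0)
  qprop <- sweep(combined, 2, ifelse(csum > 0, csum, 1), "/")
  Hent <- -colSums(ifelse(combined > 0, qprop * log2(qprop), 0))
  denom <- if (config$entropy_base_total) {
    rep(log2(length(vocab)), nd)
  } else {
    ifelse(nnz > 1, log2(pmax(nnz, 2)), Inf)
  }
  En <- ifelse(nnz > 0, Hent / denom, 0)
  df <- ifelse(nnz > 0, (nnz / length(vocab)) * (1 + En), 0)
  total <- csum * df
  excl <- p[gate == 0]
  list(partial = t(P), genelist = t(G), combined = t(combined),
       n_enriched_pathways = t(R), d_f = df, total = total,
       draw_sizes = n_vec,
       max_retained_p = if (any(gate == 1)) max(p[gate == 1]) else NA_real_,
       min_excluded_p = if (length(excl) > 0) min(excl) else NA_real_)
}

# Internal: null combined-score matrix from random same-size gene sets.
perm_null_scores <- function(idx, Hmat, Gmat, norms, config, size, seed) {
  draws <- with_seed(seed, {
    lapply(seq_len(config$n_perm), function(i) sample(idx$universe, size))
  })
  score_draws(draws, idx, Hmat, Gmat, norms, config)$combined
}

#' Permutation significance of a non-zero hallmark score
#'
#' Tests whether an observed mean hallmark score exceeds what random gene
#' sets of the same size achieve: draws `config$n_perm` uniform gene sets
#' from the library universe, scores each through the identical pipeline,
#' and returns the add-one estimate
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`. Note the estimate
#' cannot fall below `1/(n_perm + 1)`.
#'
#' @param observed_mean observed mean score for the hallmark.
#' @param library a [gene_set_library()].
#' @param ann a [hallmark_annotation()].
#' @param config a [scoring_config()]; `n_perm` and the scoring constants
#'   are taken from it.
#' @param hallmark hallmark label (normalized to the vocabulary).
#' @param size gene-set size of the null draws (default
#'   `config$sample_size`).
#' @param seed RNG seed for the null stream (default derived from
#'   `config$seed`).
#' @return Add-one permutation p-value in (0, 1].
#' @export
permutation_significance <- function(observed_mean, library, ann,
                                     config = scoring_config(),
                                     hallmark, size = config$sample_size,
                                     seed = derive_seed(config$seed, "perm")) {
  hallmark <- normalize_hallmark_label(hallmark)
  stopifnot(hallmark %in% aging_hallmarks())
  idx <- library_index(library)
  Hmat <- hallmark_incidence(ann, idx)
  Gmat <- genelist_incidence(ann, idx)
  norms <- hallmark_normalizers(library, ann, config$norm_strategy)
  null <- perm_null_scores(idx, Hmat, Gmat, norms, config, size, seed)
  (1 + sum(null[, hallmark] >= observed_mean)) / (1 + config$n_perm)
}

# Internal: one-sided sign (binomial) test that the hallmark score is
# positive in a majority of resamples. k = resamples with score > 0.
sign_test_p <- function(k_positive, n_samples) {
  stats::pbinom(k_positive - 1, n_samples, 0.5, lower.tail = FALSE)
}

#' Fit the aging-alignment score for one disease
#'
#' The central fitting function. High-evidence targets (association score
#' > `min_assoc`) are ranked and capped at `top_k`; `n_samples` subsamples
#' of `sample_size` genes are drawn; each subsample is tested for pathway
#' over-representation (hypergeometric, raw `p < enrich_alpha`), enriched
#' pathways are aggregated into per-hallmark partial scores, and the
#' diversity-weighted total is computed. Per-hallmark means, SDs and 95%
#' confidence intervals summarize the resampling distribution; significance
#' of "hallmark score > 0" is assessed per `config$sig_method` and
#' BH-corrected within the disease (joint correction across diseases is
#' available via [hallmark_screen()] / [significance_table()]).
#'
#' @param table a [target_table()] for one disease.
#' @param library a [gene_set_library()].
#' @param ann a [hallmark_annotation()].
#' @param config a [scoring_config()].
#' @param keep_draws logical; retain the sampled gene sets in the fit
#'   (default FALSE).
#' @return An object of class `hallmark_score`: list with `disease_id`,
#'   `stats` (per-hallmark data frame: mean, sd, ci_lo, ci_hi, n_nonzero,
#'   p, q, ns, norm_mean), `total` (list of the same statistics for A_d),
#'   `samples` (per-draw matrices: combined, partial, genelist, d_f,
#'   total), `meta` (instrumented pipeline counters), `config`, `seed`.
#' @seealso [hallmark_screen()] for several diseases with joint BH and
#'   cross-disease normalization.
#' @export
hallmark_score <- function(table, library, ann, config = scoring_config(),
                           keep_draws = FALSE) {
  stopifnot(inherits(table, "target_table"),
            inherits(library, "gene_set_library"),
            inherits(ann, "hallmark_annotation"),
            inherits(config, "scoring_config"))
  disease_id <- attr(table, "disease_id")
  vocab <- aging_hallmarks()

  ranked <- select_targets(table, config$min_assoc, config$top_k,
                           sample_size = config$sample_size)
  size_used <- min(config$sample_size, length(ranked))
  degenerate <- length(ranked) <= config$sample_size

  idx <- library_index(library)
  Hmat <- hallmark_incidence(ann, idx)
  Gmat <- genelist_incidence(ann, idx)
  norms <- hallmark_normalizers(library, ann, config$norm_strategy)

  seed_d <- derive_seed(config$seed, paste0("disease::", disease_id))
  if (degenerate) {
    scored1 <- score_draws(list(ranked), idx, Hmat, Gmat, norms, config)
    rep_mat <- function(m) m[rep(1L, config$n_samples), , drop = FALSE]
    scored <- list(partial = rep_mat(scored1$partial),
                   genelist = rep_mat(scored1$genelist),
                   combined = rep_mat(scored1$combined),
                   n_enriched_pathways = rep_mat(scored1$n_enriched_pathways),
                   d_f = rep(scored1$d_f, config$n_samples),
                   total = rep(scored1$total, config$n_samples),
                   draw_sizes = rep(scored1$draw_sizes, config$n_samples),
                   max_retained_p = scored1$max_retained_p,
                   min_excluded_p = scored1$min_excluded_p)
    draws <- rep(list(ranked), config$n_samples)
  } else {
    draws <- with_seed(seed_d, {
      lapply(seq_len(config$n_samples), function(i) {
        sample_targets(ranked, config$sample_size)
      })
    })
    scored <- score_draws(draws, idx, Hmat, Gmat, norms, config)
  }

  comb <- scored$combined                      # n_samples x 11
  means <- colMeans(comb)
  if (config$n_samples == 1) {
    warning("n_samples = 1: standard deviations reported as 0")
    sds <- rep(0, length(vocab))
    tot_sd <- 0
  } else {
    sds <- apply(comb, 2, stats::sd)
    tot_sd <- stats::sd(scored$total)
  }
  ci <- function(x, m, s) {
    if (config$ci_method == "percentile") {
      as.numeric(stats::quantile(x, c(0.025, 0.975), names = FALSE))
    } else {
      c(m - 1.96 * s, m + 1.96 * s)
    }
  }
  cis <- vapply(seq_along(vocab),
                function(i) ci(comb[, i], means[i], sds[i]), numeric(2))
  n_pos <- colSums(comb > 0)

  p <- if (config$sig_method == "binomial") {
    sign_test_p(n_pos, config$n_samples)
  } else {
    null <- perm_null_scores(idx, Hmat, Gmat, norms, config, size_used,
                             derive_seed(config$seed,
                                         paste0("perm::", disease_id)))
    vapply(seq_along(vocab), function(i) {
      (1 + sum(null[, i] >= means[i])) / (1 + config$n_perm)
    }, numeric(1))
  }
  q <- bh_adjust(p)

  stats_df <- data.frame(
    hallmark = vocab, mean = means, sd = sds,
    ci_lo = cis[1, ], ci_hi = cis[2, ], n_nonzero = as.integer(n_pos),
    p = p, q = q, ns = q >= config$q_threshold,
    norm_mean = NA_real_, stringsAsFactors = FALSE
  )
  rownames(stats_df) <- NULL
  tot_ci <- ci(scored$total, mean(scored$total), tot_sd)
  total <- list(mean = mean(scored$total), sd = tot_sd,
                ci_lo = tot_ci[1], ci_hi = tot_ci[2], norm_mean = NA_real_)

  structure(list(
    disease_id = disease_id,
    stats = stats_df,
    total = total,
    samples = list(combined = comb, partial = scored$partial,
                   genelist = scored$genelist,
                   n_enriched_pathways = scored$n_enriched_pathways,
                   d_f = scored$d_f, total = scored$total),
    meta = list(
      n_input = nrow(table),
      n_pass_filter = sum(table$score > config$min_assoc),
      n_ranked = length(ranked), ranked = ranked,
      sample_size_used = size_used, degenerate = degenerate,
      n_samples = config$n_samples,
      draw_sizes = scored$draw_sizes,
      enrich_alpha = config$enrich_alpha,
      max_retained_p = scored$max_retained_p,
      min_excluded_p = scored$min_excluded_p,
      normalizers = norms,
      genelist_enabled = !is.null(Gmat) && config$w_genelist > 0
    ),
    draws = if (keep_draws) draws else NULL,
    library = library,
    annotation = ann,
    config = config,
    seed = seed_d
  ), class = "hallmark_score")
}

#' Joint BH correction across fitted diseases
#'
#' Pools the per-hallmark p-values of several fits into one family
#' (`config$bh_family = "global"`, the default) or corrects within each
#' disease (`"per_disease"`), refills `q` and the NS flag, and returns the
#' fits.
#'
#' @param fits list of [hallmark_score()] objects.
#' @param config a [scoring_config()].
#' @return The list of fits with updated `stats$q` and `stats$ns`.
#' @export
significance_table <- function(fits, config = scoring_config()) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "hallmark_score")))
  if (config$bh_family == "global") {
    ps <- unlist(lapply(fits, function(f) f$stats$p), use.names = FALSE)
    qs <- bh_adjust(ps)
    off <- 0
    for (i in seq_along(fits)) {
      m <- nrow(fits[[i]]$stats)
      fits[[i]]$stats$q <- qs[off + seq_len(m)]
      fits[[i]]$stats$ns <- fits[[i]]$stats$q >= config$q_threshold
      off <- off + m
    }
  } else {
    for (i in seq_along(fits)) {
      fits[[i]]$stats$q <- bh_adjust(fits[[i]]$stats$p)
      fits[[i]]$stats$ns <- fits[[i]]$stats$q >= config$q_threshold
    }
  }
  fits
}

#' Normalize fitted scores to a 0-100 scale across diseases
#'
#' All reported scores are scaled relative to the maximal score achieved in
#' sampling: per-hallmark statistics are divided by the maximum sampled
#' hallmark score across all diseases, hallmarks and resamples; totals by
#' the maximum sampled total. The maxima are returned so the scaling is
#' reproducible.
#'
#' @param fits list of [hallmark_score()] objects.
#' @return List with `fits` (with `norm_mean` columns filled, plus
#'   `norm_ci_lo`/`norm_ci_hi`) and `norm` (the two maxima).
#' @export
normalize_scores <- function(fits) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "hallmark_score")))
  max_hallmark <- max(vapply(fits, function(f) max(f$samples$combined), numeric(1)))
  max_total <- max(vapply(fits, function(f) max(f$samples$total), numeric(1)))
  if (max_hallmark <= 0 || max_total <= 0) {
    warning("all sampled scores are zero; normalized scores set to 0")
  }
  hden <- if (max_hallmark > 0) max_hallmark else 1
  tden <- if (max_total > 0) max_total else 1
  for (i in seq_along(fits)) {
    s <- fits[[i]]$stats
    s$norm_mean <- s$mean / hden * 100
    s$norm_ci_lo <- s$ci_lo / hden * 100
    s$norm_ci_hi <- s$ci_hi / hden * 100
    fits[[i]]$stats <- s
    fits[[i]]$total$norm_mean <- fits[[i]]$total$mean / tden * 100
  }
  list(fits = fits, norm = list(max_hallmark_sample = max_hallmark,
                                max_total_sample = max_total))
}

#' Score several diseases with joint correction and normalization
#'
#' Fits every disease with [hallmark_score()] (per-disease RNG substreams
#' derived from the master seed make the result independent of input
#' order), applies BH across the disease x hallmark family, and fills the
#' cross-disease 0-100 normalization.
#'
#' @param tables list of [target_table()] objects (one per disease).
#' @param library a [gene_set_library()].
#' @param ann a [hallmark_annotation()].
#' @param config a [scoring_config()].
#' @return An object of class `hallmark_screen`: list with `fits`, `table`
#'   (long disease x hallmark data frame), `totals`, `norm`, `config`,
#'   `library_checksum`.
#' @export
hallmark_screen <- function(tables, library, ann, config = scoring_config()) {
  if (inherits(tables, "target_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "target_table")))
  fits <- lapply(tables, hallmark_score, library = library, ann = ann,
                 config = config)
  fits <- significance_table(fits, config)
  nz <- normalize_scores(fits)
  fits <- nz$fits
  long <- do.call(rbind, lapply(fits, function(f) {
    cbind(data.frame(disease = f$disease_id, stringsAsFactors = FALSE),
          f$stats)
  }))
  rownames(long) <- NULL
  totals <- data.frame(
    disease = vapply(fits, `[[`, character(1), "disease_id"),
    mean_total = vapply(fits, function(f) f$total$mean, numeric(1)),
    sd_total = vapply(fits, function(f) f$total$sd, numeric(1)),
    ci_lo = vapply(fits, function(f) f$total$ci_lo, numeric(1)),
    ci_hi = vapply(fits, function(f) f$total$ci_hi, numeric(1)),
    norm_total = vapply(fits, function(f) f$total$norm_mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(fits = fits, table = long, totals = totals, norm = nz$norm,
                 config = config,
                 library_checksum = library_checksum(library)),
            class = "hallmark_screen")
}
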