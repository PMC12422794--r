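#' @export
print.hallmark_score <- function(x, ...) {
  cat("Aging-alignment fit for '", x$disease_id, "'\n", sep = "")
  cat("  targets: ", x$meta$n_pass_filter, " high-evidence, pool of ",
      x$meta$n_ranked, ", ", x$config$n_samples, " resamples of ",
      x$meta$sample_size_used, "\n", sep = "")
  cat("  total A_d = ", fmt_num(x$total$mean), " ± ", fmt_num(x$total$sd),
      " (95% CI ", fmt_num(x$total$ci_lo), "-", fmt_num(x$total$ci_hi), ")\n",
      sep = "")
  top <- x$stats[order(-x$stats$mean), ]
  top <- top[top$mean > 0, , drop = FALSE]
  if (nrow(top) > 0) {
    cat("  leading hallmarks:\n")
    for (i in seq_len(min(3, nrow(top)))) {
      cat("    ", format(top$hallmark[i], width = 36),
          fmt_num(top$mean[i]),
          if (top$ns[i]) "  (NS)" else paste0("  q=", fmt_num(top$q[i])),
          "\n", sep = "")
    }
  } else {
    cat("  no hallmark attained a positive score\n")
  }
  invisible(x)
}

#' Summarize a fitted aging-alignment score
#'
#' @param object a [hallmark_score()] fit.
#' @param ... unused.
#' @return The per-hallmark statistics data frame, with the total score
#'   statistics attached as attribute `total`.
#' @export
summary.hallmark_score <- function(object, ...) {
  out <- object$stats
  attr(out, "total") <- object$total
  attr(out, "disease_id") <- object$disease_id
  out
}

#' Per-hallmark mean scores of a fit
#'
#' @param object a [hallmark_score()] fit.
#' @param ... unused.
#' @return Named numeric vector of mean hallmark scores.
#' @export
coef.hallmark_score <- function(object, ...) {
  stats::setNames(object$stats$mean, object$stats$hallmark)
}

#' Bar plot of per-hallmark scores with SD whiskers
#'
#' @param x a [hallmark_score()] fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.hallmark_score <- function(x, ...) {
  s <- x$stats
  op <- graphics::par(mar = c(11, 4, 3, 1))
  on.exit(graphics::par(op))
  mids <- graphics::barplot(s$mean, names.arg = s$hallmark, las = 2,
                            cex.names = 0.7,
                            ylim = c(0, max(s$mean + s$sd, 1e-9) * 1.1),
                            ylab = "mean hallmark score",
                            main = x$disease_id, ...)
  graphics::arrows(mids, pmax(s$mean - s$sd, 0), mids, s$mean + s$sd,
                   angle = 90, code = 3, length = 0.03)
  invisible(mids)
}

#' Draw fresh resampled score vectors from a fit
#'
#' Repeats the fit's subsample-and-score step `nsim` more times with a new
#' RNG stream, returning the per-hallmark combined scores of each draw.
#'
#' @param object a [hallmark_score()] fit.
#' @param nsim number of new resamples (default 1).
#' @param seed RNG seed (default derived from the fit's seed).
#' @param ... unused.
#' @return `nsim` x 11 matrix of hallmark scores with attribute `total`
#'   (per-draw total scores).
#' @export
simulate.hallmark_score <- function(object, nsim = 1,
                                    seed = derive_seed(object$seed, "simulate"),
                                    ...) {
  ranked <- object$meta$ranked
  draws <- with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      sample_targets(ranked, object$config$sample_size)
    })
  })
  scored <- refit_draws(draws, object$library, object$annotation, object$config)
  out <- scored$combined
  attr(out, "total") <- scored$total
  out
}

#' Score arbitrary gene draws under a fitted configuration
#'
#' Utility behind property tests and [simulate()]-style workflows: scores a
#' list of gene sets with the same library, annotation and configuration as
#' an existing analysis.
#'
#' @param draws list of character vectors of gene symbols.
#' @param library a [gene_set_library()].
#' @param ann a [hallmark_annotation()].
#' @param config a [scoring_config()].
#' @return List with matrices `combined`, `partial`, `genelist` (draws x
#'   hallmarks) and vectors `d_f`, `total`.
#' @export
refit_draws <- function(draws, library, ann, config = scoring_config()) {
  idx <- library_index(library)
  scored <- score_draws(draws, idx, hallmark_incidence(ann, idx),
                        genelist_incidence(ann, idx),
                        hallmark_normalizers(library, ann, config$norm_strategy),
                        config)
  scored[c("combined", "partial", "genelist", "d_f", "total")]
}

#' @export
print.hallmark_screen <- function(x, ...) {
  cat("Aging-alignment screen: ", length(x$fits), " disease(s), ",
      nrow(x$table), " hallmark cells (BH family: ", x$config$bh_family,
      ")\n", sep = "")
  o <- order(-x$totals$mean_total)
  cat("  disease totals (normalized 0-100):\n")
  for (i in utils::head(o, 10)) {
    cat("    ", format(x$totals$disease[i], width = 30),
        fmt_num(x$totals$norm_total[i]), "  (raw ",
        fmt_num(x$totals$mean_total[i]), " ± ",
        fmt_num(x$totals$sd_total[i]), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.hallmark_screen <- function(object, ...) {
  list(table = object$table, totals = object$totals, norm = object$norm)
}

#' Heatmap of normalized hallmark scores across diseases
#'
#' Diseases as rows, the 11 hallmarks as columns, cell color by normalized
#' mean score; cells not reaching the significance threshold are marked
#' "NS".
#'
#' @param x a [hallmark_screen()].
#' @param ... unused.
#' @export
plot.hallmark_screen <- function(x, ...) {
  vocab <- aging_hallmarks()
  dids <- vapply(x$fits, `[[`, character(1), "disease_id")
  M <- t(vapply(x$fits, function(f) {
    stats::setNames(f$stats$norm_mean, f$stats$hallmark)[vocab]
  }, numeric(length(vocab))))
  NSm <- t(vapply(x$fits, function(f) {
    stats::setNames(f$stats$ns, f$stats$hallmark)[vocab]
  }, logical(length(vocab))))
  op <- graphics::par(mar = c(13, 10, 3, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(seq_along(vocab), seq_along(dids), t(M[rev(seq_along(dids)), ,
                  drop = FALSE]),
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = "Normalized hallmark scores (0-100)")
  graphics::axis(1, at = seq_along(vocab), labels = vocab, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_along(dids), labels = rev(dids), las = 2,
                 cex.axis = 0.7)
  for (i in seq_along(dids)) {
    for (j in seq_along(vocab)) {
      if (NSm[i, j]) {
        graphics::text(j, length(dids) - i + 1, "NS", cex = 0.6)
      }
    }
  }
  invisible(M)
}
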