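#' Specification of a synthetic input world
#'
#' Describes a complete, self-contained input set — gene universe, pathway
#' library, hallmark annotations, and one disease target table — with
#' controlled hallmark signal. Signal is planted at the membership level:
#' with probability equal to the planted strength, a target gene is drawn
#' from the union of the planted hallmark's pathways rather than uniformly
#' from the universe, so every downstream statistic is exercised honestly
#' rather than rigged.
#'
#' @param n_genes universe size (default 2000).
#' @param pathways_per_hallmark pathways annotated to each hallmark; scalar
#'   or named vector over [aging_hallmarks()] (default 20).
#' @param pathway_size_range min/max pathway size (default c(10, 50)).
#' @param planted_hallmarks character vector of hallmarks with planted
#'   signal, or a named numeric vector of per-hallmark strengths in
#'   \[0, 1\] (strength defaults to `planted_strength`). Strengths must sum
#'   to at most 1.
#' @param planted_strength default strength for unnamed planted hallmarks
#'   (default 0.9: a strong planted signal with a 10% background admixture).
#' @param n_targets disease target count (default 80).
#' @param assoc_range background association-score range (default
#'   c(0.2, 1.0), so the 0.4 evidence filter is non-trivial).
#' @param planted_assoc_range association-score range for planted targets
#'   (default c(0.5, 1.0), so the filter retains them).
#' @param multilabel_fraction fraction of pathways carrying a second
#'   hallmark label (default 0.1).
#' @param disease_id identifier for the generated target table.
#' @param seed RNG seed; worlds are fully deterministic given the spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 2000, pathways_per_hallmark = 20,
                         pathway_size_range = c(10, 50),
                         planted_hallmarks = character(),
                         planted_strength = 0.9,
                         n_targets = 80, assoc_range = c(0.2, 1.0),
                         planted_assoc_range = c(0.5, 1.0),
                         multilabel_fraction = 0.1,
                         disease_id = NULL, seed = 1) {
  vocab <- aging_hallmarks()
  if (length(pathways_per_hallmark) == 1) {
    pathways_per_hallmark <- stats::setNames(
      rep(as.integer(pathways_per_hallmark), length(vocab)), vocab)
  } else {
    stopifnot(all(sort(names(pathways_per_hallmark)) == sort(vocab)))
    pathways_per_hallmark <- pathways_per_hallmark[vocab]
  }
  if (is.numeric(planted_hallmarks)) {
    strengths <- planted_hallmarks
  } else {
    strengths <- stats::setNames(rep(planted_strength,
                                     length(planted_hallmarks)),
                                 planted_hallmarks)
  }
  if (length(strengths) > 0) {
    names(strengths) <- normalize_hallmark_label(names(strengths))
    stopifnot(all(names(strengths) %in% vocab),
              all(strengths >= 0), all(strengths <= 1),
              sum(strengths) <= 1)
  }
  stopifnot(n_genes >= 1, n_targets >= 1, n_targets <= n_genes,
            length(pathway_size_range) == 2,
            pathway_size_range[1] >= 1,
            pathway_size_range[1] <= pathway_size_range[2],
            multilabel_fraction >= 0, multilabel_fraction <= 1,
            assoc_range[1] >= 0, assoc_range[2] <= 1,
            planted_assoc_range[1] >= 0, planted_assoc_range[2] <= 1)
  if (pathway_size_range[2] > n_genes) {
    stop("infeasible spec: maximum pathway size exceeds the universe size")
  }
  if (is.null(disease_id)) {
    disease_id <- if (length(strengths) > 0) {
      paste0("synthetic_", paste(names(strengths), collapse = "+"))
    } else "synthetic_null"
  }
  structure(list(n_genes = as.integer(n_genes),
                 pathways_per_hallmark = pathways_per_hallmark,
                 pathway_size_range = as.integer(pathway_size_range),
                 planted = strengths, n_targets = as.integer(n_targets),
                 assoc_range = assoc_range,
                 planted_assoc_range = planted_assoc_range,
                 multilabel_fraction = multilabel_fraction,
                 disease_id = disease_id, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic input world
#'
#' Builds a gene universe (`G0001`, `G0002`, ...), a pathway library with
#' the requested per-hallmark pathway counts and sizes, a multi-label
#' hallmark annotation map, and one disease target table. Planted targets
#' are drawn from the planted hallmark's pathway union with association
#' scores in the planted range; the remainder are uniform background.
#'
#' @param spec a [fixture_spec()].
#' @return List with `library` ([gene_set_library()]), `annotations`
#'   ([hallmark_annotation()]), `targets` ([target_table()]), and `spec`.
#' @export
make_world <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  vocab <- aging_hallmarks()
  with_seed(spec$seed, {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    sets <- list()
    pmap <- list()
    pw_i <- 0
    for (h in vocab) {
      for (j in seq_len(spec$pathways_per_hallmark[[h]])) {
        pw_i <- pw_i + 1
        id <- sprintf("PW%04d", pw_i)
        size_choices <- spec$pathway_size_range[1]:spec$pathway_size_range[2]
        size <- size_choices[sample.int(length(size_choices), 1)]
        sets[[id]] <- list(description = paste0("synthetic pathway for ", h),
                           members = sample(genes, size))
        labs <- h
        if (stats::runif(1) < spec$multilabel_fraction) {
          labs <- c(labs, sample(setdiff(vocab, h), 1))
        }
        pmap[[id]] <- labs
      }
    }
    library <- gene_set_library(sets, universe = genes)
    ann <- hallmark_annotation(pmap)

    # targets: multinomial split between planted components and background
    comp <- if (length(spec$planted) > 0) {
      probs <- c(spec$planted, background = 1 - sum(spec$planted))
      sample(names(probs), spec$n_targets, replace = TRUE, prob = probs)
    } else {
      rep("background", spec$n_targets)
    }
    chosen <- character(0)
    tg <- character(spec$n_targets)
    sc <- numeric(spec$n_targets)
    unions <- lapply(names(spec$planted), function(h) {
      hp <- names(pmap)[vapply(pmap, function(x) h %in% x, logical(1))]
      sort(unique(unlist(lapply(library$sets[hp], `[[`, "members"),
                         use.names = FALSE)))
    })
    names(unions) <- names(spec$planted)
    for (i in seq_len(spec$n_targets)) {
      pool <- if (comp[i] == "background") genes else unions[[comp[i]]]
      pool <- setdiff(pool, chosen)
      if (length(pool) == 0) {  # planted union exhausted; fall back
        pool <- setdiff(genes, chosen)
        comp[i] <- "background"
      }
      g <- if (length(pool) == 1) pool else sample(pool, 1)
      chosen <- c(chosen, g)
      tg[i] <- g
      rng <- if (comp[i] == "background") spec$assoc_range else spec$planted_assoc_range
      sc[i] <- stats::runif(1, rng[1], rng[2])
    }
    targets <- target_table(tg, sc, spec$disease_id)
    list(library = library, annotations = ann, targets = targets, spec = spec)
  })
}

#' Write a synthetic world to disk
#'
#' Materializes a world in the exact dialects the package readers consume:
#' `library.gmt`, `annotations.tsv`, `targets.tsv`.
#'
#' @param world output of [make_world()] or [worked_example_world()].
#' @param dir output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "library.gmt")
  p2 <- file.path(dir, "annotations.tsv")
  p3 <- file.path(dir, "targets.tsv")
  write_gmt(world$library, p1)
  write_hallmark_annotations(world$annotations, p2)
  write_target_table(world$targets, p3)
  invisible(c(p1, p2, p3))
}

#' The fixed micro-world behind the worked example
#'
#' A hard-coded 20-gene universe, 4 pathways across 2 hallmarks, and a
#' 7-target table. Small enough that every pipeline intermediate (each
#' enrichment p-value, each partial score, the diversity factor and the
#' total) has an exact closed-form value that the test suite recomputes
#' with independent oracles:
#' \itemize{
#'   \item PW_A overlaps the 5 high-evidence targets in 3 of its 5 genes:
#'     p = 1126/15504.
#'   \item PW_B (4 genes, all targets): p = 16/15504.
#'   \item PW_C (the 5 targets exactly): p = 1/15504.
#'   \item PW_D is disjoint from the targets: p = 1.
#' }
#' With the example configuration (`enrich_alpha = 0.01`, pool equal to the
#' sample so sampling is degenerate) the enriched set is \{PW_B, PW_C\},
#' one pathway per hallmark.
#'
#' @return List with `library`, `annotations`, `targets` (same shape as
#'   [make_world()]) plus `config`, the example [scoring_config()].
#' @export
worked_example_world <- function() {
  genes <- sprintf("G%02d", 1:20)
  sets <- list(
    PW_A = list(description = "senescence program A",
                members = c("G01", "G02", "G03", "G11", "G12")),
    PW_B = list(description = "senescence program B",
                members = c("G01", "G02", "G03", "G04")),
    PW_C = list(description = "inflammatory program C",
                members = c("G01", "G02", "G03", "G04", "G05")),
    PW_D = list(description = "inflammatory program D",
                members = c("G13", "G14", "G15", "G16", "G17", "G18"))
  )
  library <- gene_set_library(sets, universe = genes)
  ann <- hallmark_annotation(list(
    PW_A = "cellular_senescence",
    PW_B = "cellular_senescence",
    PW_C = "chronic_inflammation",
    PW_D = "chronic_inflammation"
  ))
  targets <- target_table(
    genes = c("G01", "G02", "G03", "G04", "G05", "G06", "G07"),
    scores = c(0.95, 0.90, 0.85, 0.80, 0.75, 0.40, 0.10),
    disease_id = "worked_example"
  )
  config <- scoring_config(min_assoc = 0.4, top_k = 60, sample_size = 5,
                           n_samples = 10, enrich_alpha = 0.01, seed = 7)
  list(library = library, annotations = ann, targets = targets,
       config = config)
}
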