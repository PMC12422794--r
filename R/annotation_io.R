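#' Construct a gene-set library
#'
#' A gene-set library holds named pathways (each with a free-text description
#' and a set of member genes) over a gene universe that serves as the
#' enrichment background. If no explicit universe is supplied, the universe is
#' the union of all member sets — the background convention of
#' enrichment tools that test against the genes covered by the library.
#'
#' @param sets named list; each element a list with fields `description`
#'   (character scalar) and `members` (character vector of gene symbols).
#' @param universe optional character vector of gene symbols to use as the
#'   enrichment background. Must contain every member gene.
#' @return An object of class `gene_set_library` with elements `sets` and
#'   `universe` (sorted, unique, upper-cased).
#' @export
gene_set_library <- function(sets, universe = NULL) {
  if (!is.list(sets) || length(sets) == 0) {
    stop("a gene-set library needs at least one pathway")
  }
  ids <- names(sets)
  if (is.null(ids) || any(!nzchar(ids))) stop("every pathway needs a non-blank id")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(sets, function(s) {
    members <- unique(toupper(trimws(s$members)))
    members <- members[nzchar(members)]
    if (length(members) == 0) stop("every pathway needs at least one member gene")
    list(description = as.character(s$description %||% ""), members = members)
  })
  union_genes <- sort(unique(unlist(lapply(sets, `[[`, "members"), use.names = FALSE)))
  if (is.null(universe)) {
    universe <- union_genes
  } else {
    universe <- sort(unique(toupper(trimws(universe))))
    universe <- universe[nzchar(universe)]
    if (length(universe) == 0) stop("explicit universe is empty")
    missing <- setdiff(union_genes, universe)
    if (length(missing) > 0) {
      stop("pathway members outside the supplied universe: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  structure(list(sets = sets, universe = universe), class = "gene_set_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gene_set_library <- function(x, ...) {
  sizes <- lengths(lapply(x$sets, `[[`, "members"))
  cat("Gene-set library: ", length(x$sets), " pathways over ",
      length(x$universe), " genes\n", sep = "")
  cat("  set sizes: ", min(sizes), "-", max(sizes),
      " (median ", stats::median(sizes), ")\n", sep = "")
  invisible(x)
}

#' Read a gene-set library from a GMT file
#'
#' GMT is the tab-separated gene-set format: one set per line with fields
#' `set_id`, `description`, then one or more member genes. Gene identifiers
#' are upper-cased and duplicates within a line collapsed.
#'
#' @param path path to a GMT file.
#' @param universe optional character vector giving an explicit enrichment
#'   background; default background is the union of all member sets.
#' @return A [gene_set_library()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    stop("malformed GMT line (fewer than 3 tab-separated fields) at line ", bad[1])
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway_id in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) {
    list(description = f[2], members = f[-(1:2)])
  })
  names(sets) <- ids
  gene_set_library(sets, universe = universe)
}

#' Write a gene-set library to a GMT file
#'
#' Members are written sorted so that identical libraries serialize to
#' byte-identical files.
#'
#' @param library a [gene_set_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library$sets), function(id) {
    s <- library$sets[[id]]
    paste(c(id, s$description, sort(s$members)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a hallmark annotation map
#'
#' Maps pathway ids (and optionally genes) to one or more of the eleven
#' aging hallmarks. Pathways absent from the map are unannotated and
#' contribute to no hallmark.
#'
#' @param pathway_map named list: pathway_id -> character vector of hallmark
#'   labels (each a member of [aging_hallmarks()]).
#' @param gene_map optional named list: gene symbol -> character vector of
#'   hallmark labels; enables the gene-list score component.
#' @return An object of class `hallmark_annotation` with elements
#'   `pathway_map`, `gene_map` and a `coverage` data frame (pathways
#'   annotated per hallmark).
#' @export
hallmark_annotation <- function(pathway_map, gene_map = NULL) {
  vocab <- aging_hallmarks()
  check_map <- function(m, what) {
    if (length(m) == 0) return(m)
    if (is.null(names(m)) || any(!nzchar(names(m)))) {
      stop(what, " map entries need non-blank names")
    }
    m <- lapply(m, function(h) unique(normalize_hallmark_label(h)))
    bad <- unique(unlist(m, use.names = FALSE))
    bad <- setdiff(bad, vocab)
    if (length(bad) > 0) {
      stop("unknown hallmark label(s) in ", what, " map: ",
           paste(bad, collapse = ", "))
    }
    if (any(lengths(m) == 0)) stop(what, " map has an entry with no hallmarks")
    m
  }
  pathway_map <- check_map(as.list(pathway_map), "pathway")
  if (!is.null(gene_map)) {
    gene_map <- as.list(gene_map)
    names(gene_map) <- toupper(trimws(names(gene_map)))
    gene_map <- check_map(gene_map, "gene")
  }
  counts <- vapply(vocab, function(h) {
    sum(vapply(pathway_map, function(x) h %in% x, logical(1)))
  }, integer(1))
  coverage <- data.frame(hallmark = vocab, n_pathways = unname(counts),
                         stringsAsFactors = FALSE)
  structure(list(pathway_map = pathway_map, gene_map = gene_map,
                 coverage = coverage),
            class = "hallmark_annotation")
}

#' @export
print.hallmark_annotation <- function(x, ...) {
  cat("Hallmark annotation map: ", length(x$pathway_map),
      " annotated pathways", sep = "")
  if (!is.null(x$gene_map)) cat("; gene map with ", length(x$gene_map), " genes", sep = "")
  cat("\n")
  print(x$coverage, row.names = FALSE)
  invisible(x)
}

#' Read pathway-to-hallmark annotations from a TSV file
#'
#' Expects a header with columns `pathway_id` and `hallmark`, one
#' (pathway, hallmark) pair per row; a pathway may appear on several rows to
#' carry several hallmarks. Hallmark strings are matched to the 11-label
#' vocabulary after case/space/hyphen normalization; anything else (including
#' "dysbiosis") is a validation error. Rows whose pathway is not in the
#' library are reported and dropped.
#'
#' @param path path to the TSV file.
#' @param library the [gene_set_library()] the annotations refer to.
#' @param gene_map optional named list passed through to
#'   [hallmark_annotation()].
#' @return A [hallmark_annotation()].
#' @export
read_hallmark_annotations <- function(path, library, gene_map = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  stopifnot(inherits(library, "gene_set_library"))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0) stop("annotation file has no rows: ", path)
  need <- c("pathway_id", "hallmark")
  if (!all(need %in% names(df))) {
    stop("annotation TSV must have columns 'pathway_id' and 'hallmark'")
  }
  labels <- normalize_hallmark_label(df$hallmark)
  bad <- which(!(labels %in% aging_hallmarks()))
  if (length(bad) > 0) {
    stop("unknown hallmark label(s) at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), ": ",
         paste(unique(df$hallmark[bad]), collapse = ", "))
  }
  known <- df$pathway_id %in% names(library$sets)
  if (any(!known)) {
    warning(sum(!known), " annotation row(s) with pathway_id not in the library dropped: ",
            paste(utils::head(unique(df$pathway_id[!known]), 5), collapse = ", "))
  }
  df <- df[known, , drop = FALSE]
  labels <- labels[known]
  pathway_map <- split(labels, df$pathway_id)
  hallmark_annotation(pathway_map, gene_map = gene_map)
}

#' Write a hallmark annotation map to a TSV file
#'
#' One (pathway_id, hallmark) pair per row, sorted for byte-stable output.
#'
#' @param ann a [hallmark_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hallmark_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "hallmark_annotation"))
  ids <- rep(names(ann$pathway_map), lengths(ann$pathway_map))
  hs <- unlist(ann$pathway_map, use.names = FALSE)
  o <- order(ids, hs)
  df <- data.frame(pathway_id = ids[o], hallmark = hs[o], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a disease target-association table
#'
#' @param genes character vector of gene symbols (upper-cased internally).
#' @param scores numeric vector of association scores in \[0, 1\] (e.g. Open
#'   Targets overall association scores).
#' @param disease_id identifier of the disease the targets belong to.
#' @return An object of class `target_table`: a data frame with columns
#'   `gene` and `score` and attribute `disease_id`.
#' @export
target_table <- function(genes, scores, disease_id) {
  genes <- toupper(trimws(as.character(genes)))
  scores <- as.numeric(scores)
  if (length(genes) == 0) stop("target table has no rows")
  if (length(genes) != length(scores)) stop("genes and scores differ in length")
  if (any(!nzchar(genes))) stop("blank gene identifier in target table")
  if (any(is.na(scores)) || any(scores < 0 | scores > 1)) {
    stop("association scores must be in [0, 1]")
  }
  if (anyDuplicated(genes)) {
    warning("duplicate gene rows collapsed keeping the maximum score: ",
            paste(utils::head(unique(genes[duplicated(genes)]), 5), collapse = ", "))
    mx <- tapply(scores, genes, max)
    genes <- names(mx)
    scores <- as.numeric(mx)
  }
  o <- order(-scores, genes)
  out <- data.frame(gene = genes[o], score = scores[o], stringsAsFactors = FALSE)
  attr(out, "disease_id") <- as.character(disease_id)
  class(out) <- c("target_table", "data.frame")
  out
}

#' @export
print.target_table <- function(x, ...) {
  cat("Target table for '", attr(x, "disease_id"), "': ", nrow(x),
      " genes, scores ", fmt_num(min(x$score)), "-", fmt_num(max(x$score)),
      "\n", sep = "")
  print(utils::head(as.data.frame(x), 5), row.names = FALSE)
  if (nrow(x) > 5) cat("  ... ", nrow(x) - 5, " more rows\n", sep = "")
  invisible(x)
}

#' Read a disease target-association table
#'
#' Accepts either a TSV with a header (columns `gene` and the score column)
#' or an Open Targets style JSON-lines export (one JSON object per line with
#' a gene symbol field and a numeric score field). Duplicate genes keep the
#' maximum score with a warning.
#'
#' @param path path to the file; `.json`/`.jsonl` extensions select the
#'   JSON-lines reader.
#' @param disease_id identifier for the disease.
#' @param score_column name of the score column/field (default `"score"`).
#' @param gene_column name of the gene column/field (default `"gene"`;
#'   JSON-lines also falls back to `symbol` or `target`).
#' @return A [target_table()].
#' @export
read_target_table <- function(path, disease_id, score_column = "score",
                              gene_column = "gene") {
  if (!file.exists(path)) stop("target table not found: ", path)
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("target table has no rows: ", path)
    recs <- lapply(lines, jsonlite::fromJSON)
    get_gene <- function(r) {
      for (f in c(gene_column, "symbol", "target")) {
        if (!is.null(r[[f]])) return(as.character(r[[f]]))
      }
      stop("JSON-lines record without a gene field")
    }
    genes <- vapply(recs, get_gene, character(1))
    scores <- vapply(recs, function(r) {
      v <- r[[score_column]]
      if (is.null(v)) stop("JSON-lines record without score field '", score_column, "'")
      as.numeric(v)
    }, numeric(1))
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "")
    if (nrow(df) == 0) stop("target table has no rows: ", path)
    if (!(gene_column %in% names(df))) {
      stop("target TSV lacks gene column '", gene_column, "'")
    }
    if (!(score_column %in% names(df))) {
      stop("target TSV lacks score column '", score_column, "'")
    }
    genes <- df[[gene_column]]
    scores <- suppressWarnings(as.numeric(df[[score_column]]))
    if (any(is.na(scores))) stop("non-numeric association score in ", path)
  }
  target_table(genes, scores, disease_id)
}

#' Write a target table to TSV
#'
#' @param table a [target_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(table, path) {
  stopifnot(inherits(table, "target_table"))
  df <- data.frame(gene = table$gene, score = fmt_num(table$score),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# md5 of the canonical GMT serialization of a library (used in run metadata).
library_checksum <- function(library) {
  tf <- tempfile(fileext = ".gmt")
  on.exit(unlink(tf))
  write_gmt(library, tf)
  unname(tools::md5sum(tf))
}

#' Write score tables for a fitted screen
#'
#' Writes three files into `out_dir`:
#' \describe{
#'   \item{score_long.tsv}{one row per disease x hallmark with mean, SD, CI
#'     bounds, permutation/binomial p, BH q, normalized 0-100 score, and an
#'     `ns` flag set where q >= the reporting threshold.}
#'   \item{disease_totals.tsv}{one row per disease with the total score
#'     statistics and the normalized total.}
#'   \item{run_metadata.json}{resolved configuration, seed, library checksum
#'     and normalization maxima.}
#' }
#' Numbers are serialized with 6 significant digits; re-running on identical
#' inputs yields byte-identical files.
#'
#' @param screen a [hallmark_screen()] object (or a single
#'   [hallmark_score()] fit, which is wrapped).
#' @param out_dir output directory, created if needed.
#' @return Character vector of written paths (the file manifest), invisibly.
#' @export
write_score_tables <- function(screen, out_dir) {
  if (inherits(screen, "hallmark_score")) {
    screen <- structure(list(fits = list(screen),
                             config = screen$config,
                             norm = attr(screen$stats, "norm")),
                        class = "hallmark_screen")
  }
  stopifnot(inherits(screen, "hallmark_screen"))
  if (length(screen$fits) == 0) stop("no summaries to write")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)

  long <- do.call(rbind, lapply(screen$fits, function(f) {
    s <- f$stats
    data.frame(disease = f$disease_id, hallmark = s$hallmark,
               mean = fmt_num(s$mean), sd = fmt_num(s$sd),
               ci_lo = fmt_num(s$ci_lo), ci_hi = fmt_num(s$ci_hi),
               p = fmt_num(s$p), q = fmt_num(s$q),
               norm_score = fmt_num(s$norm_mean),
               ns = as.integer(s$ns), stringsAsFactors = FALSE)
  }))
  totals <- do.call(rbind, lapply(screen$fits, function(f) {
    t <- f$total
    data.frame(disease = f$disease_id, mean_total = fmt_num(t$mean),
               sd_total = fmt_num(t$sd), ci_lo = fmt_num(t$ci_lo),
               ci_hi = fmt_num(t$ci_hi),
               norm_total = fmt_num(t$norm_mean %||% NA_real_),
               stringsAsFactors = FALSE)
  }))
  p_long <- file.path(out_dir, "score_long.tsv")
  p_tot <- file.path(out_dir, "disease_totals.tsv")
  p_meta <- file.path(out_dir, "run_metadata.json")
  utils::write.table(long, p_long, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(totals, p_tot, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    config = unclass(screen$config),
    seed = screen$config$seed,
    diseases = vapply(screen$fits, `[[`, character(1), "disease_id"),
    library_checksum = screen$library_checksum %||% NA_character_,
    normalization = screen$norm %||% NULL
  )
  jsonlite::write_json(meta, p_meta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(p_long, p_tot, p_meta))
}
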