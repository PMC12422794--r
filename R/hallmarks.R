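#' The eleven aging hallmarks used for scoring
#'
#' Canonical vocabulary of hallmark labels. The twelfth commonly listed
#' hallmark, dysbiosis, is excluded because it depends on non-human
#' (microbial) targets and cannot be scored from human target genes.
#'
#' Labels are lower-case with underscores; [normalize_hallmark_label()] maps
#' common spellings ("Cellular Senescence", "cellular-senescence") onto this
#' canonical form.
#'
#' @return Character vector of 11 hallmark labels.
#' @export
#' @examples
#' aging_hallmarks()
aging_hallmarks <- function() {
  c(
    "genomic_instability",
    "telomere_attrition",
    "epigenetic_alterations",
    "loss_of_proteostasis",
    "disabled_macroautophagy",
    "deregulated_nutrient_sensing",
    "mitochondrial_dysfunction",
    "cellular_senescence",
    "stem_cell_exhaustion",
    "altered_intercellular_communication",
    "chronic_inflammation"
  )
}

#' Normalize a hallmark label to the canonical vocabulary form
#'
#' Lower-cases, trims, and converts runs of spaces/hyphens to underscores.
#' Does not validate membership in [aging_hallmarks()].
#'
#' @param x character vector of labels.
#' @return character vector of normalized labels.
#' @export
normalize_hallmark_label <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(as.character(x))))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed from a master seed and a string key, so that
# per-disease results do not depend on processing order. Kept < 2^31 - 1.
derive_seed <- function(seed, key) {
  h <- 0
  for (cp in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 31 + cp) %% 1048573
  }
  as.integer(((as.numeric(seed) %% 1048573) * 2039 + h * 7919 + 17) %% 2147483629)
}

# Format a number with 6 significant digits for stable tabular output.
fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}
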