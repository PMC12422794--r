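---
title: "Hallmark-decomposition scoring: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hallmark-decomposition scoring: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hallmarkScore)
```

## The model

`hallmarkScore` measures how much of a disease's target biology is aging
biology. The inputs are a pathway library over a gene universe, a
pathway→hallmark annotation over the eleven human-scorable hallmarks of
aging (dysbiosis is excluded because it is carried by non-human,
microbial targets), and a table of (gene, association score) pairs for
the disease.

The procedure, per disease:

1. **Evidence filter and pool.** Keep genes with association score
   strictly above `min_assoc` (default 0.4), rank by score (ties broken
   alphabetically for determinism), keep the top `top_k` (60).
2. **Resampling.** Draw `sample_size` (50) genes without replacement
   from the pool, `n_samples` (250) times. Subsampling turns a single
   fragile gene list into a distribution of scores, yielding confidence
   intervals and a significance test.
3. **Enrichment.** Each draw is tested against every pathway with the
   one-sided hypergeometric (Fisher) test; pathways with raw
   p < `enrich_alpha` (0.001, strict) form the enriched set. The gate
   uses raw p-values: multiple-testing correction is applied once, at
   the hallmark level, not inside each draw.
4. **Partial hallmark scores.** With $R_h$ the enriched pathways
   annotated to hallmark $h$ (a multi-label pathway counts fully in each
   of its hallmarks — no splitting rule is imposed),
   $$P_h = \Big[\sum_{p\in R_h} -\log_{10}(p_p)\Big]\times N_h \times
   \Big(1+\tfrac{\log_2(|R_h|+1)}{4}\Big).$$
   The $-\log_{10}$ mass aggregates evidence strength; the count bonus
   rewards several independent pathways pointing at the same hallmark;
   $N_h$ corrects annotation-density imbalance (below).
5. **Diversity and total.** $D_f = \frac{N_{nz}}{N_t}(1+E_n)$ with
   $N_{nz}$ the non-zero hallmarks, $N_t = 11$, and $E_n$ the normalized
   Shannon entropy of the score distribution;
   $A_d = (\sum_h P_h)\times D_f$. A disease touching many hallmarks
   evenly is up-weighted (maximum $D_f = 2$); a single-hallmark disease
   is down-weighted ($D_f = 1/11$).
6. **Reporting.** Per-hallmark and total means, SDs, 95% CIs over the
   250 resamples; significance of "hallmark score > 0" per cell; BH
   correction across all disease × hallmark cells; NS flag at
   q ≥ `q_threshold` (0.001); all scores scaled to 0–100 by the maximal
   score achieved in sampling.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_assoc` | 0.4 | strict lower bound on association evidence |
| `top_k` / `sample_size` | 60 / 50 | pool size and resample size |
| `n_samples` | 250 | resamples per disease |
| `enrich_alpha` | 0.001 | raw enrichment p gate (strict `<`) |
| `q_threshold` | 0.001 | NS flag at `q >=` threshold |
| `w_pathway` / `w_genelist` | 1 / 0.25 | component weights |
| `norm_strategy` | inverse_frequency | hallmark density normalizer |
| `sig_method` | binomial | test of "score > 0" |
| `n_perm` | 999 | permutations for the alternative test |

The gene-list component is an optional second evidence channel: direct
over-representation of the sampled genes in per-hallmark gene lists,
expressed as a $-\log_{10}$ p so it is commensurable with the pathway
term. Its default weight is lower (0.25 vs 1) because gene-level
hallmark annotation is sparser and noisier than pathway-level
annotation; the component is off entirely unless a gene map is supplied.

## Design choices where the design was open

**Hallmark normalizer.** Only the purpose of $N_h$ is fixed —
compensating the uneven distribution of pathways across hallmarks. We
use inverse frequency with mean-one scaling: $N_h = \bar{C}/C_h$ over
populated hallmarks, where $C_h$ is the number of library pathways
annotated to $h$. This equalizes the expected $-\log_{10}$ mass a random
enriched pathway contributes per hallmark, reduces to $N_h \equiv 1$
under uniform annotation, and leaves unpopulated hallmarks at zero
permanently. A `"uniform"` strategy (all populated weights 1) is
available for sensitivity analysis.

**Entropy normalization.** $E_n$ uses base-2 entropy divided by
$\log_2 N_t$, so "all eleven hallmarks, perfectly even" gives exactly
$E_n = 1$ and $D_f = 2$, and a point mass gives $E_n = 0$. Normalizing
by $\log_2 N_{nz}$ instead (selectable via `entropy_base_total = FALSE`)
would make any even split score $E_n = 1$ regardless of breadth, which
double-counts breadth already captured by $N_{nz}/N_t$. Entropy over the
non-zero scores equals entropy over all 11 with $0\log 0 := 0$.

**Enrichment background.** By default the universe is the union of the
library's member genes — the background convention of enrichment servers
that test against covered genes. An explicit genome-wide background can
be passed to `read_gmt()`/`gene_set_library()`; with the default, every
enrichment uses only universe genes and out-of-universe query genes are
dropped with a recorded count.

**Significance of non-zero hallmark scores.** The hypothesis is that a
hallmark's true score exceeds zero; the test construction is an open
design point, and two are provided. The default is a one-sided sign
(binomial) test on the number of resamples with a positive score: under
the null the hallmark is positive in at most half of the resamples, so
$p = P(\mathrm{Bin}(n_{\mathrm{samples}}, 1/2) \ge k)$. This is crude
but robust to the strong correlation between resamples (they share the
same 60-gene pool), and its p-values can be arbitrarily small, which a
reporting threshold of q < 0.001 requires. The alternative
(`sig_method = "permutation"`) scores random same-size gene sets through
the identical pipeline and uses the add-one estimator
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$;
note its p cannot fall below $1/(n_{\mathrm{perm}}+1)$, so with
practical permutation counts no cell can clear q < 0.001 after BH — use
it with a more lenient `q_threshold`, or for effect-size context.

**BH family.** The default corrects all disease × hallmark cells of a
screen as one family, matching a single corrected report panel across
diseases; per-disease families are available (`bh_family`).

**Confidence intervals.** 2.5/97.5 empirical percentiles of the
resampled scores by default; a normal approximation (mean ± 1.96 SD) is
selectable. Both SD and CI are reported since whisker conventions
differ between plots.

**Normalization.** Totals and per-hallmark scores are normalized by
*separate* maxima (the largest sampled total, and the largest sampled
per-hallmark score, across all diseases and resamples), since the two
live on different scales; the maxima are recorded in the run metadata.

## Numerical and degenerate-input conventions

- Strict inequalities everywhere the constants are stated as bounds: a
  score of exactly 0.4 is filtered out; a pathway at p = 0.001 exactly
  is not enriched; q = 0.001 exactly is NS.
- Ties in target ranking and enrichment ordering are broken
  alphabetically; results are invariant to pathway insertion order.
- If fewer than `sample_size` genes pass the filter, every resample is
  the whole pool (warning; SDs and CI widths are 0). `n_samples = 1`
  reports SD 0 with a warning.
- Per-disease RNG substreams are derived from (master seed, disease id),
  so multi-disease results do not depend on processing order, and
  identical inputs + seed give byte-identical output files. Tabular
  numbers are serialized with 6 significant digits.
- The hypergeometric tail is computed by `stats::phyper` (log-scale
  internals); BH by `stats::p.adjust`. The test suite checks both
  against independent implementations (exhaustive subset enumeration;
  a hand-coded step-up).

## What the synthetic generator emulates — and what it does not

`make_world()` builds a universe (default 2,000 genes), 20 pathways per
hallmark with sizes 10–50, a 10% multi-label fraction, and an 80-gene
target table. Signal is planted at the membership level: with
probability equal to the planted strength, a target is drawn from the
planted hallmark's pathway union (association score in [0.5, 1], so the
evidence filter keeps it); otherwise uniformly from the universe (score
in [0.2, 1], so filtering is non-trivial). The default strength of 0.9
models a strongly hallmark-driven disease with a 10% admixture of
unrelated targets. Because signal enters only through membership, the
entire statistical chain — filtering, sampling, enrichment, scoring,
significance — is exercised honestly.

The generator does **not** emulate the GO term hierarchy or its
correlated, nested pathways, gene-length or annotation-depth biases,
inter-pathway co-membership structure beyond chance, or evidence-score
correlations. Passing tests on these worlds therefore demonstrate the
machinery's correctness and calibration under clean conditions, not
performance on real Open Targets / GO:BP inputs, where annotation bias
is a first-order concern.

## Known limitations

- **Persistent chance enrichment.** The resamples share one 60-gene
  pool. If a null pool happens to overlap some pathway strongly, every
  resample inherits that enrichment and the cell is called significant
  with extreme confidence — the test answers "is this realized pool
  enriched?", not "would a fresh pool be?". On null synthetic worlds
  this yields a small per-cell false-positive rate (on the order of
  0.2%, i.e. a couple of cells per few hundred diseases) that no
  resample-level test can remove; only an (infeasibly expensive)
  pool-level permutation null would.
- Hallmarks with sparse pathway annotation can never accumulate mass;
  the inverse-frequency normalizer rescales but cannot create coverage.
- The component weights are configuration, not estimates; no fitting of
  weights is attempted.
- Scores depend on the annotation set and library version used; they
  are comparable within one run, not across runs with different inputs.

## Problem sizes used by the test suite

Module tests run on micro-libraries (tens of genes) where oracles are
exact. The end-to-end validation uses the generator at its default
scale (2,000 genes, 220 pathways) with 250 resamples per disease: 100
planted worlds for recovery/power and 200 null worlds for calibration,
sizes chosen so the whole suite completes in well under half an hour on
one core while keeping the binomial test's granularity fine enough for
q < 0.001 calls.
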