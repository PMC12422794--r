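test_that("sample_targets draws without replacement and degenerates gracefully", {
  pool <- sprintf("X%02d", 1:60)
  set.seed(5)
  s <- sample_targets(pool, 50)
  expect_length(s, 50)
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s %in% pool))
  expect_identical(sample_targets(pool[1:40], 50), pool[1:40])
  s1 <- with(list(), {set.seed(99); sample_targets(pool, 50)})
  s2 <- with(list(), {set.seed(99); sample_targets(pool, 50)})
  expect_identical(s1, s2)
  expect_error(sample_targets(character(0), 5), "empty")
})

test_that("a degenerate pool gives identical draws with zero spread", {
  w <- worked_example_world()
  fit <- hallmark_score(w$targets, w$library, w$annotations, w$config)
  expect_true(fit$meta$degenerate)
  expect_true(all(fit$stats$sd == 0))
  expect_true(all(fit$stats$ci_hi - fit$stats$ci_lo == 0))
  expect_equal(fit$total$sd, 0)
  expect_identical(nrow(fit$samples$combined), w$config$n_samples)
})

test_that("n_samples = 1 reports SD 0 with a warning", {
  w <- worked_example_world()
  cfg <- scoring_config(min_assoc = 0.4, top_k = 6, sample_size = 4,
                        n_samples = 1, enrich_alpha = 0.01, seed = 3)
  expect_warning(fit <- hallmark_score(w$targets, w$library, w$annotations, cfg),
                 "n_samples = 1")
  expect_true(all(fit$stats$sd == 0))
  expect_equal(fit$total$mean, fit$samples$total[1])
})

test_that("the vectorized sampling path equals the compositional pipeline", {
  sp <- fixture_spec(n_genes = 300, pathways_per_hallmark = 4,
                     pathway_size_range = c(5, 15), n_targets = 40,
                     planted_hallmarks = "telomere_attrition", seed = 13)
  world <- make_world(sp)
  cfg <- scoring_config(top_k = 30, sample_size = 20, n_samples = 15,
                        enrich_alpha = 0.05, seed = 13)
  fit <- hallmark_score(world$targets, world$library, world$annotations, cfg,
                        keep_draws = TRUE)
  norms <- hallmark_normalizers(world$library, world$annotations,
                                cfg$norm_strategy)
  for (j in seq_along(fit$draws)) {
    es <- enrich(fit$draws[[j]], world$library, alpha = cfg$enrich_alpha)
    ps <- partial_hallmark_scores(es, world$annotations, norms)
    ts <- total_score(ps, config = cfg)
    expect_equal(unname(fit$samples$combined[j, ]), unname(ts$combined),
                 tolerance = 1e-12)
    expect_equal(fit$samples$total[j], ts$total, tolerance = 1e-12)
    expect_equal(fit$samples$d_f[j], ts$d_f, tolerance = 1e-12)
  }
})

test_that("fits are deterministic and independent of disease processing order", {
  sp <- fixture_spec(n_genes = 300, pathways_per_hallmark = 4,
                     pathway_size_range = c(5, 15), n_targets = 40,
                     planted_hallmarks = "cellular_senescence", seed = 4)
  w1 <- make_world(sp)
  sp2 <- fixture_spec(n_genes = 300, pathways_per_hallmark = 4,
                      pathway_size_range = c(5, 15), n_targets = 40,
                      seed = 5, disease_id = "null_dz")
  w2 <- make_world(sp2)
  cfg <- scoring_config(top_k = 30, sample_size = 20, n_samples = 10, seed = 2)
  fit_a <- hallmark_score(w1$targets, w1$library, w1$annotations, cfg)
  fit_b <- hallmark_score(w1$targets, w1$library, w1$annotations, cfg)
  expect_identical(fit_a$stats, fit_b$stats)
  expect_identical(fit_a$samples, fit_b$samples)
  # same fit inside a screen, regardless of companion diseases and order
  scr1 <- suppressWarnings(
    hallmark_screen(list(w1$targets, w2$targets), w1$library, w1$annotations, cfg))
  scr2 <- suppressWarnings(
    hallmark_screen(list(w2$targets, w1$targets), w1$library, w1$annotations, cfg))
  expect_identical(scr1$fits[[1]]$samples, scr2$fits[[2]]$samples)
})

test_that("permutation significance follows the add-one estimator", {
  lib <- tiny_library()
  ann <- tiny_annotation()
  cfg <- scoring_config(top_k = 4, sample_size = 3, n_perm = 1, seed = 1)
  # a zero observed mean can never beat non-negative null scores
  expect_equal(permutation_significance(0, lib, ann, cfg,
                                        "cellular_senescence"), 1.0)
  # n_perm = 1 with the null below the observation -> (1 + 0) / 2
  expect_equal(permutation_significance(1e9, lib, ann, cfg,
                                        "cellular_senescence"), 0.5)
  cfg999 <- scoring_config(top_k = 4, sample_size = 3, n_perm = 999, seed = 1)
  expect_equal(permutation_significance(1e9, lib, ann, cfg999,
                                        "cellular_senescence"), 1 / 1000)
})

test_that("the binomial sign test is monotone and exact at the extremes", {
  p_all <- hallmarkScore:::sign_test_p(50, 50)
  expect_equal(p_all, 0.5^50, tolerance = 1e-10)
  expect_equal(hallmarkScore:::sign_test_p(0, 50), 1)
  ks <- 0:50
  ps <- hallmarkScore:::sign_test_p(ks, 50)
  expect_true(all(diff(ps) < 0))
})

test_that("joint BH across diseases corrects one family and flags NS", {
  sp <- function(seed) fixture_spec(n_genes = 300, pathways_per_hallmark = 4,
                                    pathway_size_range = c(5, 15),
                                    n_targets = 40, seed = seed,
                                    disease_id = paste0("dz", seed))
  cfg <- scoring_config(top_k = 30, sample_size = 20, n_samples = 10, seed = 8)
  worlds <- lapply(1:3, function(s) make_world(sp(s)))
  lib <- worlds[[1]]$library; ann <- worlds[[1]]$annotations
  fits <- suppressWarnings(
    lapply(worlds, function(w) hallmark_score(w$targets, lib, ann, cfg)))
  joint <- significance_table(fits, cfg)
  ps <- unlist(lapply(fits, function(f) f$stats$p))
  qs <- unlist(lapply(joint, function(f) f$stats$q))
  expect_equal(qs, oracle_bh(ps), tolerance = 1e-12)  # 3 x 11 = one family
  for (f in joint) expect_identical(f$stats$ns, f$stats$q >= cfg$q_threshold)
  # all-equal p-values are a BH fixed point
  fits_eq <- fits
  for (i in seq_along(fits_eq)) fits_eq[[i]]$stats$p <- rep(0.25, 11)
  joint_eq <- significance_table(fits_eq, cfg)
  expect_true(all(vapply(joint_eq, function(f) all(f$stats$q == 0.25),
                         logical(1))))
})

test_that("per-disease BH families are available by configuration", {
  w <- worked_example_world()
  cfg <- scoring_config(min_assoc = 0.4, top_k = 60, sample_size = 5,
                        n_samples = 5, enrich_alpha = 0.01, seed = 7,
                        bh_family = "per_disease")
  fit <- hallmark_score(w$targets, w$library, w$annotations, cfg)
  out <- significance_table(list(fit), cfg)
  expect_equal(out[[1]]$stats$q, oracle_bh(fit$stats$p), tolerance = 1e-12)
})

test_that("normalization maps the global sampling max to 100 and is scale-invariant", {
  scr <- example_screen()
  fits <- scr$fits
  nz <- normalize_scores(fits)
  expect_equal(max(fits[[1]]$samples$combined) / nz$norm$max_hallmark_sample * 100,
               100)
  expect_equal(max(fits[[1]]$samples$total) / nz$norm$max_total_sample * 100,
               100)
  # doubling every raw score leaves normalized outputs unchanged
  fits2 <- fits
  fits2[[1]]$samples$combined <- fits2[[1]]$samples$combined * 2
  fits2[[1]]$samples$total <- fits2[[1]]$samples$total * 2
  fits2[[1]]$stats$mean <- fits2[[1]]$stats$mean * 2
  fits2[[1]]$stats$ci_lo <- fits2[[1]]$stats$ci_lo * 2
  fits2[[1]]$stats$ci_hi <- fits2[[1]]$stats$ci_hi * 2
  fits2[[1]]$total$mean <- fits2[[1]]$total$mean * 2
  nz2 <- normalize_scores(fits2)
  expect_equal(nz2$fits[[1]]$stats$norm_mean, nz$fits[[1]]$stats$norm_mean,
               tolerance = 1e-12)
  expect_equal(nz2$fits[[1]]$total$norm_mean, nz$fits[[1]]$total$norm_mean,
               tolerance = 1e-12)
  # an all-zero screen normalizes to zero with a warning
  fits0 <- fits
  fits0[[1]]$samples$combined[] <- 0
  fits0[[1]]$samples$total[] <- 0
  fits0[[1]]$stats$mean[] <- 0
  fits0[[1]]$stats$ci_lo[] <- 0; fits0[[1]]$stats$ci_hi[] <- 0
  fits0[[1]]$total$mean <- 0
  expect_warning(nz0 <- normalize_scores(fits0), "zero")
  expect_true(all(nz0$fits[[1]]$stats$norm_mean == 0))
})

test_that("percentile intervals are ordered and bracket the median", {
  sp <- fixture_spec(n_genes = 300, pathways_per_hallmark = 4,
                     pathway_size_range = c(5, 15), n_targets = 60,
                     planted_hallmarks = "cellular_senescence", seed = 17)
  world <- make_world(sp)
  cfg <- scoring_config(top_k = 40, sample_size = 25, n_samples = 40,
                        enrich_alpha = 0.01, seed = 17)
  fit <- hallmark_score(world$targets, world$library, world$annotations, cfg)
  s <- fit$stats
  expect_true(all(s$ci_lo <= s$ci_hi))
  med <- apply(fit$samples$combined, 2, median)
  expect_true(all(s$ci_lo <= med + 1e-12 & med <= s$ci_hi + 1e-12))
  expect_true(fit$total$ci_lo <= fit$total$mean &&
              fit$total$mean <= fit$total$ci_hi)
})

test_that("fit accessors expose coefficients, summaries, and simulations", {
  w <- worked_example_world()
  fit <- hallmark_score(w$targets, w$library, w$annotations, w$config)
  co <- coef(fit)
  expect_named(co, aging_hallmarks())
  expect_equal(unname(co["chronic_inflammation"]),
               fit$stats$mean[fit$stats$hallmark == "chronic_inflammation"])
  sm <- summary(fit)
  expect_s3_class(sm, "data.frame")
  expect_identical(attr(sm, "disease_id"), "worked_example")
  sims <- simulate(fit, nsim = 3)
  expect_identical(dim(sims), c(3L, 11L))
  # degenerate pool: simulations reproduce the fitted draws exactly
  expect_equal(unname(sims[1, ]), unname(fit$samples$combined[1, ]),
               tolerance = 1e-12)
  expect_output(print(fit), "worked_example")
})
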