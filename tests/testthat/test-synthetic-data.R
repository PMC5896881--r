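test_that("generation is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 61, n_genes = 200, n_cohorts = 5,
                    cohort_size_range = c(3, 6))
  d1 <- sim_dataset(cfg, with_cohorts = TRUE)
  d2 <- sim_dataset(cfg, with_cohorts = TRUE)
  expect_identical(d1$cds, d2$cds)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$evidence, d2$evidence)
  expect_identical(d1$cohorts, d2$cohorts)
  d3 <- sim_dataset(sim_config(seed = 62, n_genes = 200))
  expect_false(identical(d1$cds$seq, d3$cds$seq))
  expect_error(sim_config(), "seed")
})

test_that("generated sequences satisfy the coding-sequence invariants", {
  cfg <- sim_config(seed = 63, n_genes = 80)
  genes <- sim_genes(cfg)
  expect_equal(genes$cds$length_bp, nchar(genes$cds$seq))
  expect_true(all(genes$cds$length_bp %% 3 == 0))
  stops <- c("TAA", "TAG", "TGA")
  for (s in genes$cds$seq) {
    cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    expect_false(any(cods[-length(cods)] %in% stops))
    expect_true(cods[length(cods)] %in% stops)
  }
})

test_that("codon-bias propensity drives CAI monotonically", {
  cfg <- sim_config(seed = 64, n_genes = 600, ssr_factor = 1)
  genes <- sim_genes(cfg)
  w <- cai_weights(codonexpress:::usage_to_counts(cfg$optimal_usage))
  scores <- cai(genes$cds$seq, w)
  quart <- cut(genes$truth$propensity, breaks = 4)
  means <- tapply(scores, quart, mean)
  expect_true(all(diff(means) > 0))
  # degenerate optimal table at t == 1 drives CAI to 1
  top <- cfg$optimal_usage |>
    dplyr::group_by(aa) |>
    dplyr::mutate(fraction = as.numeric(fraction == max(fraction)),
                  fraction = fraction / sum(fraction)) |>
    dplyr::ungroup()
  cfg1 <- sim_config(seed = 64, n_genes = 20, optimal_usage = top,
                     propensity_shape1 = 1e9, propensity_shape2 = 1e-4)
  genes1 <- sim_genes(cfg1)
  w1 <- cai_weights(codonexpress:::usage_to_counts(top))
  expect_true(all(cai(genes1$cds$seq, w1) > 0.95))
})

test_that("chromosome layout plants recoverable strand-switch genes", {
  cfg <- sim_config(seed = 65, n_genes = 300)
  genes <- sim_genes(cfg)
  called <- strand_switch_genes(genes$annotation)
  planted <- genes$truth$gene_id[genes$truth$is_ssr_adjacent]
  expect_setequal(called, planted)
  expect_gt(length(planted), 0)
})

test_that("noise controls the score-expression correlation as designed", {
  base <- sim_config(seed = 66, n_genes = 300)
  genes <- sim_genes(base)
  # noiseless limit: perfect correlation
  expr0 <- sim_expression(genes, sim_config(seed = 66, n_genes = 300,
                                            sigma = 0))
  ev0 <- evaluate_scores(expr0, score = "score", observed = "mrna")
  expect_equal(ev0$r, 1, tolerance = 1e-9)
  # r decreases as sigma grows
  rs <- vapply(c(0.1, 0.3, 0.6), function(sg) {
    e <- sim_expression(genes, sim_config(seed = 66, n_genes = 300,
                                          sigma = sg))
    evaluate_scores(e, score = "score", observed = "mrna")$r
  }, 0)
  expect_true(all(diff(rs) < 0))
})

test_that("flat expression slope yields near-zero correlation", {
  cfg <- sim_config(seed = 67, n_genes = 1000, beta = 0, sigma = 0.5)
  genes <- sim_genes(cfg)
  expr <- sim_expression(genes, cfg)
  ev <- evaluate_scores(expr, score = "score", observed = "mrna")
  expect_lt(abs(ev$r), 0.07)
})

test_that("proteome evidence reflects abundance, with under-sampling", {
  cfg <- sim_config(seed = 68, n_genes = 300, depth = 1e5)
  d <- sim_dataset(cfg)
  # saturated depth: peptide ranks track protein abundance x length
  lam <- d$expression$protein * d$expression$length_kbp
  rho <- cor(rank(d$evidence$unique_peptides), rank(lam))
  expect_gt(rho, 0.99)
  expect_true(all(d$evidence$coverage >= 0 & d$evidence$coverage <= 1))
  expect_equal(d$evidence$protein_length_aa,
               d$expression$length_bp / 3 - 1)
  # zero depth: no peptides at all
  cfg0 <- sim_config(seed = 68, n_genes = 50, depth = 0)
  d0 <- sim_dataset(cfg0)
  expect_true(all(d0$evidence$unique_peptides == 0))
  expect_true(all(d0$evidence$coverage == 0))
})

test_that("cohorts share one true abundance and echo their configuration", {
  cfg <- sim_config(seed = 69, n_genes = 1200, n_cohorts = 23,
                    cohort_size_range = c(3, 30))
  d <- sim_dataset(cfg, with_cohorts = TRUE)
  sizes <- table(d$cohorts$cohort)
  expect_length(sizes, 23)
  expect_true(all(sizes >= 3 & sizes <= 30))
  # zero within-cohort variance of true protein abundance before sampling
  joined <- merge(d$cohorts, d$expression, by = "gene_id")
  vr <- tapply(joined$true_protein, joined$cohort, stats::var)
  expect_true(all(vr == 0))
  expect_false(anyDuplicated(d$cohorts$gene_id) > 0)
})

test_that("cohort-level aggregation beats gene-level under under-sampling", {
  cfg <- sim_config(seed = 70, n_genes = 1200, n_cohorts = 20,
                    cohort_size_range = c(8, 25), depth = 1,
                    protein_sigma = 0.8)
  d <- sim_dataset(cfg, with_cohorts = TRUE)
  fit <- fit_trend(d$expression, score, mrna)
  pred <- predict_relative(d$expression, fit)
  members <- d$cohorts$gene_id
  ev <- d$evidence[match(members, d$evidence$gene_id), ]
  pr <- pred[match(members, pred$gene_id), ]
  gene_r <- suppressWarnings(cor(log1p(ev$unique_peptides /
                                         (ev$cds_length_bp / 1000)),
                                 log(pr$relative_share)))
  cs <- cohort_summary(d$cohorts, d$evidence, pred)
  cohort_r <- cor(log1p(cs$observed_peptides_per_kbp),
                  log(cs$predicted_abundance))
  expect_gt(cohort_r, gene_r)
})
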