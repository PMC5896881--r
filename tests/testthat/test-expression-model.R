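test_that("length-adjusted score is direct substitution into the formula", {
  d <- length_adjusted_cai(tibble::tibble(
    cai = c(0.782, 0.70, 0.50), length_bp = c(1000, 4000, 250)))
  expect_equal(d$score, c(0.752, 0.64, 0.485), tolerance = 1e-12)
  # invariant form: score == cai - c * sqrt(L_kbp)
  expect_equal(d$score, d$cai - 0.03 * sqrt(d$length_kbp),
               tolerance = 1e-12)
  expect_error(length_adjusted_cai(tibble::tibble(cai = 0.5,
                                                  length_bp = 0)),
               "positive")
})

test_that("trend fitting recovers a collinear line exactly", {
  d <- tibble::tibble(score = c(0, 0.5, 1), observed = exp(c(0, 1, 2)))
  fit <- fit_trend(d)
  expect_equal(fit$alpha, 0, tolerance = 1e-9)
  expect_equal(fit$beta, 2, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(glance(fit)$n_fit, 3L)
  expect_equal(tidy(fit)$estimate, c(fit$alpha, fit$beta))
})

test_that("noiseless synthetic data is recovered to near machine precision", {
  set.seed(31)
  s <- runif(200, 0.3, 0.9)
  d <- tibble::tibble(score = s, observed = exp(1.7 + 4.2 * s))
  fit <- fit_trend(d)
  expect_equal(fit$alpha, 1.7, tolerance = 1e-9)
  expect_equal(fit$beta, 4.2, tolerance = 1e-9)
})

test_that("degenerate designs are flagged or rejected", {
  flat <- tibble::tibble(score = c(1, 1, 1), observed = c(1, 2, 3))
  expect_error(fit_trend(flat), "identical")
  same_y <- tibble::tibble(score = c(0, 1, 2), observed = c(5, 5, 5))
  fit <- fit_trend(same_y)
  expect_equal(fit$beta, 0, tolerance = 1e-12)
  expect_equal(fit$r, 0)
  expect_false(fit$r_defined)
  # zero observations are dropped, with the count recorded
  d <- tibble::tibble(score = c(0, 0.5, 1, 0.7), observed = c(1, 2, 3, 0))
  expect_equal(fit_trend(d)$n_dropped, 1L)
  expect_error(fit_trend(d[c(1, 4), ]), "at least 3")
})

test_that("top-fraction exclusion removes the most expressed genes", {
  d <- tibble::tibble(score = seq(0, 1, length.out = 10),
                      observed = exp(seq(0, 1, length.out = 10) * 2))
  fit <- fit_trend(d, exclude_top_fraction = 0.2)
  expect_equal(fit$n_fit, 8L)
})

test_that("relative shares follow the fitted exponential and sum to 1", {
  model <- structure(list(alpha = 0, beta = log(4)), class = "trend_fit")
  d <- tibble::tibble(gene_id = c("a", "b"), score = c(0, 1))
  pred <- predict_relative(d, model)
  expect_equal(pred$relative_share, c(0.2, 0.8), tolerance = 1e-12)
  # beta = 0 -> uniform shares
  flat <- structure(list(alpha = 2, beta = 0), class = "trend_fit")
  pred2 <- predict_relative(tibble::tibble(gene_id = letters[1:4],
                                           score = runif(4)), flat)
  expect_equal(pred2$relative_share, rep(0.25, 4))
  expect_equal(sum(pred$relative_share), 1, tolerance = 1e-9)
  expect_error(predict_relative(d[0, ], model), "no genes")
})

test_that("molecules per cell scale shares to the configured total", {
  est <- tibble::tibble(gene_id = c("a", "b"),
                        relative_share = c(0.25, 0.75))
  m <- molecules_per_cell(est, total = 19000)
  expect_equal(m$molecules_per_cell, c(4750, 14250))
  expect_equal(sum(m$molecules_per_cell), 19000, tolerance = 1e-6)
  # excluded gene removed, remainder renormalized
  est3 <- tibble::tibble(gene_id = c("a", "b", "vsg1"),
                         relative_share = c(0.2, 0.3, 0.5))
  m2 <- molecules_per_cell(est3, total = 100, exclude = "vsg1")
  expect_equal(m2$gene_id, c("a", "b"))
  expect_equal(m2$molecules_per_cell, c(40, 60))
  # single gene takes the whole total
  expect_equal(molecules_per_cell(est[1, ], 50)$molecules_per_cell, 50)
})

test_that("mRNA adjustment rescales protein shares by observed/predicted", {
  d <- tibble::tibble(gene_id = c("a", "b"), protein_share = c(0.5, 0.5),
                      observed_mrna = c(10, 10), predicted_mrna = c(10, 10))
  expect_equal(mrna_adjusted_protein(d)$adjusted_share, c(0.5, 0.5))
  d2 <- d
  d2$observed_mrna[1] <- 20  # doubled mRNA doubles the share pre-normalization
  adj <- mrna_adjusted_protein(d2)
  expect_equal(adj$adjusted_share, c(2, 1) / 3, tolerance = 1e-12)
  d3 <- d
  d3$predicted_mrna[2] <- 0
  expect_message(adj3 <- mrna_adjusted_protein(d3), "dropping 1")
  expect_equal(adj3$gene_id, "a")
})

test_that("mRNA adjustment recovers copy-number signal in simulation", {
  cfg <- sim_config(seed = 33, n_genes = 400, n_multicopy = 60,
                    copy_max = 10, sigma = 0.3)
  genes <- sim_genes(cfg)
  expr <- sim_expression(genes, cfg)
  fit <- fit_trend(expr, score, mrna)
  pred <- predict_relative(expr, fit)
  d <- tibble::tibble(gene_id = expr$gene_id,
                      protein_share = pred$relative_share,
                      observed_mrna = expr$mrna,
                      predicted_mrna = pred$predicted)
  adj <- mrna_adjusted_protein(d)
  truth <- expr$true_protein
  r_un <- cor(rank(pred$relative_share), rank(truth))
  r_adj <- cor(rank(adj$adjusted_share), rank(truth))
  expect_gt(r_adj, r_un)
})

test_that("fold agreement uses inclusive boundaries and is monotone in k", {
  same <- tibble::tibble(predicted = c(1, 2, 3), observed = c(1, 2, 3))
  expect_equal(fold_agreement(same)$fraction, rep(1, 4))
  twice <- tibble::tibble(predicted = c(2, 4), observed = c(1, 2))
  expect_equal(fold_agreement(twice, k = 2)$fraction, 1)  # boundary counts
  mixed <- tibble::tibble(predicted = c(1, 3, 10), observed = c(1, 1, 1))
  expect_equal(fold_agreement(mixed, k = 2)$fraction, 1 / 3)
  fa <- fold_agreement(tibble::tibble(predicted = exp(rnorm(50, 0, 1)),
                                      observed = 1), k = 1:6)
  expect_true(all(diff(fa$fraction) >= 0))
  expect_error(fold_agreement(same, k = 0.5), ">= 1")
})

test_that("evaluation reports r and improvement over a baseline score", {
  s <- seq(0.2, 0.9, length.out = 20)
  d <- tibble::tibble(score = s, cai = s + rnorm(20, 0, 0.05),
                      observed = exp(3 * s))
  ev <- evaluate_scores(d, score = "score", observed = "observed",
                        baseline = "cai")
  expect_equal(ev$r, 1, tolerance = 1e-9)
  expect_true(ev$improvement_percent > 0)
  # half-life mode: no log transform applied
  d2 <- tibble::tibble(score = s, observed = 5 + 2 * s)
  ev2 <- evaluate_scores(d2, log_observed = FALSE)
  expect_equal(ev2$r, 1, tolerance = 1e-9)
  expect_error(evaluate_scores(d[1:2, ]), "at least 3")
})

test_that("cohort summaries aggregate peptides per kbp and mean prediction", {
  cohorts <- tibble::tibble(cohort = c("c1", "c1", "c2"),
                            gene_id = c("a", "b", "c"))
  evidence <- tibble::tibble(gene_id = c("a", "b", "c"),
                             unique_peptides = c(10, 20, 7),
                             cds_length_bp = c(1000, 2000, 700))
  pred <- tibble::tibble(gene_id = c("a", "b", "c"),
                         relative_share = c(0.3, 0.5, 0.2))
  cs <- cohort_summary(cohorts, evidence, pred)
  c1 <- cs[cs$cohort == "c1", ]
  expect_equal(c1$observed_peptides_per_kbp, 10)  # 30 peptides / 3 kbp
  expect_equal(c1$predicted_abundance, 0.4)
  expect_equal(c1$n_proteins, 2L)
  # identical members give the single-gene prediction back
  cs2 <- cohort_summary(tibble::tibble(cohort = "c", gene_id = c("a", "a")),
                        evidence, pred)
  expect_equal(cs2$predicted_abundance, 0.3)
  # members lacking evidence are reported
  expect_message(
    cs3 <- cohort_summary(tibble::tibble(cohort = "c",
                                         gene_id = c("a", "zz")),
                          evidence, pred),
    "lack proteome evidence")
  expect_equal(cs3$n_missing_evidence, 1L)
  expect_error(cohort_summary(cohorts[0, ], evidence, pred), "empty")
})
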