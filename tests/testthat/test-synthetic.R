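test_that("expression generator is deterministic and validates its config", {
  cfg <- synthetic_expr_config(n_genes = 40L, n_tumor = 10L, n_normal = 10L,
                               n_planted_pairs = 4L, seed = 9L)
  a <- gen_labeled_expression(cfg)
  b <- gen_labeled_expression(cfg)
  expect_identical(a$values, b$values)
  expect_identical(attr(a, "planted"), attr(b, "planted"))
  expect_error(synthetic_expr_config(n_planted_pairs = 30L, n_genes = 40L),
               "n_planted_pairs")
  expect_error(synthetic_expr_config(reversal_strength = 0.85), "reversal_strength")
  expect_error(synthetic_expr_config(noise_sd = -1), "noise_sd")
})

test_that("planted pairs hit their target order probability on average", {
  # realized within-class order frequencies should concentrate near the target
  strength <- 0.98
  freqs <- c()
  for (seed in 1:5) {
    m <- gen_labeled_expression(synthetic_expr_config(
      n_genes = 60L, n_tumor = 150L, n_normal = 150L, n_planted_pairs = 5L,
      reversal_strength = strength, seed = seed))
    pl <- attr(m, "planted")
    tum <- m$label == "tumor"
    for (r in seq_len(nrow(pl))) {
      x <- m$values[pl$gene_i[r], ]; y <- m$values[pl$gene_j[r], ]
      p_tum <- if (pl$tumor_direction[r] == "gt") mean(x[tum] > y[tum]) else mean(x[tum] < y[tum])
      p_nor <- if (pl$tumor_direction[r] == "gt") mean(x[!tum] < y[!tum]) else mean(x[!tum] > y[!tum])
      freqs <- c(freqs, p_tum, p_nor)
    }
  }
  expect_gt(mean(freqs), strength - 0.01)
  expect_true(all(freqs > 0.9))
})

test_that("cohorts with different seeds share planted structure but not noise", {
  cfg1 <- synthetic_expr_config(n_genes = 40L, n_planted_pairs = 4L, seed = 1L,
                                n_tumor = 10L, n_normal = 10L)
  cfg2 <- synthetic_expr_config(n_genes = 40L, n_planted_pairs = 4L, seed = 2L,
                                n_tumor = 10L, n_normal = 10L)
  a <- gen_labeled_expression(cfg1); b <- gen_labeled_expression(cfg2)
  expect_identical(attr(a, "planted"), attr(b, "planted"))
  expect_false(identical(a$values, b$values))
})

test_that("CNV generator plants scoreable clusters and validates config", {
  cfg <- synthetic_cnv_config(n_genes = 60L, n_cells_per_cluster = c(20L, 20L),
                              amplitudes = c(0.1, 0.4), segment_length = 15L,
                              noise_sd = 0.01, n_reference_cells = 10L, seed = 2L)
  cnv <- gen_cnv_matrix(cfg)
  expect_s3_class(cnv, "cnv_matrix")
  truth <- attr(cnv, "true_labels")
  expect_equal(sum(truth == "reference"), 10L)
  expect_equal(ncol(cnv$values), 50L)
  # the amplitude-0.4 cluster receives the higher mean score
  sc <- cnv_cluster_scores(cnv, truth[truth != "reference"])
  expect_equal(sc$nominated, "2")
  expect_gt(sc$scores["2"], sc$scores["1"])
  # reference cells hug the diploid baseline
  ref_scores <- cnv_cell_score(cnv$values[, truth == "reference", drop = FALSE])
  expect_lt(max(ref_scores), 1e-3)
  expect_error(synthetic_cnv_config(n_cells_per_cluster = integer()), "zero clusters")
  expect_error(synthetic_cnv_config(amplitudes = c(0.3, 0.3),
                                    n_cells_per_cluster = c(5L, 5L)), "distinct")
})

test_that("zero-amplitude CNV matrix is diploid up to noise", {
  cnv <- gen_cnv_matrix(synthetic_cnv_config(
    n_genes = 50L, n_cells_per_cluster = 30L, amplitudes = 0, segment_length = 10L,
    noise_sd = 1e-4, seed = 3L))
  expect_lt(max(abs(cnv$values - 1)), 1e-3)
  expect_lt(max(cnv_cell_score(cnv$values)), 1e-6)
})

test_that("pathway-cell generator shifts exactly the chosen cells and genes", {
  set <- sprintf("g%04d", 1:10)
  pc <- gen_pathway_cells(40L, 100L, set, effect = 5, frac_active = 0.25, seed = 4L)
  expect_equal(sum(pc$active), 10L)
  in_set <- rownames(pc$values) %in% set
  gap <- mean(pc$values[in_set, pc$active]) - mean(pc$values[in_set, !pc$active])
  expect_equal(gap, 5, tolerance = 0.2)
  off_gap <- mean(pc$values[!in_set, pc$active]) - mean(pc$values[!in_set, !pc$active])
  expect_lt(abs(off_gap), 0.2)
  expect_error(gen_pathway_cells(10L, 20L, character(), effect = 1), "empty gene_set")
  all_active <- gen_pathway_cells(10L, 50L, sprintf("g%04d", 1:3), effect = 1,
                                  frac_active = 1, seed = 1L)
  expect_true(all(all_active$active))
})

test_that("survival generator respects censoring limits and determinism", {
  expr <- matrix(rnorm(200), 2, 100,
                 dimnames = list(c("gA", "gB"), sprintf("s%03d", 1:100)))
  cfg0 <- synthetic_survival_config(n_samples = 100L, betas = c(gA = 0.5),
                                    censor_rate = 0, seed = 6L)
  sv0 <- gen_survival(cfg0, expr)
  expect_true(all(sv0$event == 1L))       # no censoring -> all events
  expect_true(all(sv0$time > 0))
  cfg <- synthetic_survival_config(n_samples = 100L, betas = c(gA = 0.5), seed = 6L)
  expect_identical(gen_survival(cfg, expr), gen_survival(cfg, expr))
  bad <- synthetic_survival_config(n_samples = 100L, betas = c(missing_gene = 1))
  expect_error(gen_survival(bad, expr), "missing")
})
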