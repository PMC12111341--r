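test_that("combo enumeration follows the documented grid rule", {
  expect_equal(nrow(enumerate_combos()), 9L + 8L * 8L)
  two <- enumerate_combos(c("Lasso", "RF"))
  expect_setequal(two$name, c("Lasso", "RF", "Lasso+RF", "RF+Lasso"))
  expect_equal(nrow(enumerate_combos("SVM")), 1L)        # SVM is not a selector
  expect_equal(nrow(enumerate_combos(c("Lasso", "Lasso"))), 1L)  # dedup
  expect_equal(nrow(enumerate_combos(mode = "classifiers")), 9L)
  expect_error(enumerate_combos(character()), "empty")
  expect_error(enumerate_combos("nonsense"), "unknown")
})

test_that("AUC matches the brute-force pairwise concordance count", {
  expect_equal(compute_auc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  withr::with_seed(31, {
    for (i in 1:30) {
      n <- sample(5:50, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
      labels <- rbinom(n, 1, 0.5)
      if (sum(labels) %in% c(0, n)) next
      expect_identical(compute_auc(scores, labels), oracle_auc(scores, labels))
    }
  })
  expect_warning(a <- compute_auc(1:3, c(1, 1, 1)), "single class")
  expect_true(is.na(a))
})

test_that("a perfectly separating feature yields AUC 1 in every cohort", {
  prof <- matrix(rep(c(1L, 0L), each = 10), 1, 20,
                 dimnames = list("A|B", paste0("s", 1:20)))
  class(prof) <- c("pair_profile", class(prof))
  labels <- rep(c("tumor", "normal"), each = 10)
  co <- list(v1 = list(profile = prof, labels = labels))
  res <- fit_eval_combo(enumerate_combos("glm")[1, ], prof, labels, co, seed = 2L)
  expect_equal(unname(res$auc["v1"]), 1.0)
  expect_equal(unname(res$auc["train"]), 1.0)
})

test_that("single-class cohorts give a missing AUC with a warning", {
  prof <- matrix(rbinom(40, 1, 0.5), 2, 20,
                 dimnames = list(c("A|B", "C|D"), paste0("s", 1:20)))
  labels <- rep(c("tumor", "normal"), each = 10)
  co <- list(allpos = list(profile = prof, labels = rep("tumor", 20)))
  expect_warning(
    res <- fit_eval_combo(enumerate_combos("rpart")[1, ], prof, labels, co, seed = 3L),
    "single class")
  expect_true(is.na(res$auc["allpos"]))
  expect_false(is.na(res$mean_auc))  # mean over defined AUCs only
})

test_that("model ranking sorts by mean AUC with deterministic tie-breaks", {
  mk <- function(name, selector, aucs, n_feat = 3L) {
    structure(list(combo = list(selector = selector, classifier = name,
                                name = if (is.na(selector)) name else paste(selector, name, sep = "+")),
                   auc = aucs, mean_auc = mean(aucs, na.rm = TRUE),
                   n_features = n_feat), class = "combo_result")
  }
  a <- mk("glm", NA_character_, c(train = 0.9, v = 0.8))
  b <- mk("RF", NA_character_, c(train = 0.85, v = 0.95))
  tbl <- rank_models(list(a, b))
  expect_equal(tbl$name, c("RF", "glm"))          # 0.90 > 0.85
  expect_equal(tbl$rank, 1:2)
  # exact tie: single-stage model precedes two-stage, then lexicographic
  c1 <- mk("rpart", NA_character_, c(train = 0.8, v = 0.8))
  c2 <- mk("rpart", "Lasso", c(train = 0.8, v = 0.8))
  c3 <- mk("SVM", NA_character_, c(train = 0.8, v = 0.8))
  tbl2 <- rank_models(list(c2, c3, c1))
  expect_equal(tbl2$name, c("SVM", "rpart", "Lasso+rpart"))
  expect_equal(rank_models(list(a))$rank, 1L)
})

test_that("every engine fits, scores, and selects deterministically", {
  withr::with_seed(41, {
    X <- matrix(rbinom(600, 1, 0.5), 100, 6,
                dimnames = list(NULL, paste0("p", 1:6, "|q", 1:6)))
    y <- X[, 1] == 1L
    y[sample(100, 10)] <- !y[sample(100, 10)]
  })
  for (m in c("glm", "Lasso", "Ridge", "Enet", "RF", "GBM", "SVM", "rpart", "plsRglm")) {
    e1 <- reopair:::fit_engine(m, X, y, seed = 7L)
    e2 <- reopair:::fit_engine(m, X, y, seed = 7L)
    expect_identical(e1$score(X), e2$score(X))
    expect_gte(compute_auc(e1$score(X), y), 0.8)   # informative feature is learnable
    if (m %in% reopair:::SELECTION_CAPABLE) {
      sel <- reopair:::select_features(m, X, y, seed = 7L)
      expect_true(length(sel) >= 1 && all(sel %in% colnames(X)))
    }
  }
})
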