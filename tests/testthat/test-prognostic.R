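sim_surv <- function(n, beta, seed, censor_rate = 0.04) {
  expr <- withr::with_seed(seed, matrix(rnorm(n), 1, n,
                                        dimnames = list("gA", sprintf("s%04d", 1:n))))
  cfg <- synthetic_survival_config(n_samples = n, betas = c(gA = beta),
                                   censor_rate = censor_rate, seed = seed + 1L)
  list(expr = expr, surv = gen_survival(cfg, expr))
}

test_that("multivariate Cox recovers a planted log-hazard and reports internals", {
  d <- sim_surv(500L, 0.7, seed = 3L)
  fit <- fit_cox(d$expr, d$surv)
  expect_s3_class(fit, "cox_fit")
  expect_lt(abs(fit$table$coef - 0.7), 0.15)
  expect_equal(fit$table$hazard_ratio, exp(fit$table$coef))
  expect_true(fit$table$ci_lower < fit$table$hazard_ratio &
              fit$table$hazard_ratio < fit$table$ci_upper)
  # internal consistency: reported C-index equals the concordance of the risk scores
  expect_equal(fit$c_index, concordance_index(fit$risk_scores, d$surv))
  # cross-check against the survival package's concordance (dual route)
  cfit <- survival::concordance(survival::Surv(d$surv$time, d$surv$event) ~ fit$risk_scores,
                                reverse = TRUE)
  expect_equal(fit$c_index, unname(cfit$concordance), tolerance = 1e-8)
})

test_that("null covariates give a near-0.5 C-index and near-zero coefficient", {
  d <- sim_surv(400L, 0, seed = 11L)
  fit <- fit_cox(d$expr, d$surv)
  expect_lt(abs(fit$table$coef), 0.15)
  expect_lt(abs(fit$c_index - 0.5), 0.06)
})

test_that("univariate mode fits genes separately and drops constant genes", {
  d <- sim_surv(200L, 0.6, seed = 21L)
  expr <- rbind(d$expr, gB = withr::with_seed(4L, rnorm(200)), gC = rep(2, 200))
  expect_warning(fit <- fit_cox(expr, d$surv, mode = "univariate"), "constant")
  expect_equal(fit$table$gene, c("gA", "gB"))
  expect_null(fit$risk_scores)
  uni_gA <- fit$table$coef[1]
  joint <- suppressWarnings(fit_cox(expr[c("gA", "gB"), ], d$surv))
  expect_lt(abs(uni_gA - joint$table$coef[joint$table$gene == "gA"]), 0.1)
})

test_that("median stratification sends ties to the low-risk group", {
  expect_equal(unname(risk_stratify(setNames(c(1, 2, 3, 4), paste0("s", 1:4)))),
               c("low", "low", "high", "high"))
  expect_equal(unname(risk_stratify(setNames(c(1, 2, 3), paste0("s", 1:3)))),
               c("low", "low", "high"))
  expect_error(risk_stratify(setNames(rep(1, 5), paste0("s", 1:5))), "degenerate")
})

test_that("log-rank separates a planted effect and is null for exchangeable groups", {
  d <- sim_surv(300L, 0.8, seed = 31L)
  fit <- fit_cox(d$expr, d$surv)
  groups <- risk_stratify(fit)
  lr <- km_logrank(groups, d$surv)
  expect_lt(lr$p_value, 0.05)
  expect_true(all(c("group", "time", "survival") %in% names(lr$curves)))
  # identical time/event multisets in both groups: statistic exactly 0
  surv2 <- survival_table(paste0("s", 1:6), time = rep(c(1, 2, 3), 2),
                          event = rep(c(1, 0, 1), 2))
  lr0 <- km_logrank(rep(c("a", "b"), each = 3), surv2)
  expect_equal(lr0$chisq, 0)
  expect_equal(lr0$p_value, 1)
  # all censored: no events -> error
  surv_cens <- survival_table(paste0("s", 1:4), time = 1:4, event = rep(0, 4))
  expect_error(km_logrank(rep(c("a", "b"), 2), surv_cens), "no events")
})

test_that("KM estimate with no censoring equals the empirical survival function", {
  times <- c(1, 2, 2, 3, 5)
  surv <- survival_table(paste0("s", 1:10), time = rep(times, 2), event = rep(1, 10))
  lr <- km_logrank(rep(c("a", "b"), each = 5), surv)
  curve_a <- lr$curves[lr$curves$group == "a", ]
  emp <- sapply(curve_a$time, function(t) mean(times > t))
  expect_equal(curve_a$survival, emp)
})

test_that("concordance index toy cases are exact and match the oracle", {
  s2 <- survival_table(c("a", "b"), time = c(1, 2), event = c(1, 1))
  expect_equal(concordance_index(c(2, 1), s2), 1.0)
  expect_equal(concordance_index(c(1, 2), s2), 0.0)
  s3 <- survival_table(c("a", "b", "c"), time = c(1, 3, 2), event = c(1, 1, 1))
  expect_equal(concordance_index(c(3, 1, 2), s3), 1.0)
  withr::with_seed(51, {
    for (i in 1:10) {
      n <- sample(5:15, 1)
      scores <- sample(1:5, n, replace = TRUE)
      time <- sample(1:6, n, replace = TRUE)
      event <- rbinom(n, 1, 0.7)
      st <- survival_table(paste0("s", 1:n), pmax(time, 0.5), event)
      got <- tryCatch(concordance_index(scores, st), error = function(e) NA)
      want <- oracle_cindex(scores, st$time, st$event)
      if (!is.na(got)) expect_equal(got, want)
    }
  })
  s_cens <- survival_table(c("a", "b"), time = c(1, 2), event = c(0, 0))
  expect_error(concordance_index(c(1, 2), s_cens), "zero comparable")
})

test_that("co-expression is symmetric with unit diagonal and flags constants", {
  withr::with_seed(61, x <- rnorm(50))
  expr <- rbind(g1 = x, g2 = -x, g3 = rnorm(50), g4 = rep(1, 50))
  expect_warning(cc <- coexpression(expr), "constant")
  expect_equal(unname(diag(cc)), rep(1, 4))
  expect_equal(cc, t(cc))
  expect_equal(unname(cc["g1", "g2"]), -1)
  expect_true(all(is.na(cc["g4", c("g1", "g2", "g3")])))
  # independent genes have small average |r|
  withr::with_seed(62, big <- matrix(rnorm(15 * 200), 15))
  rownames(big) <- paste0("g", 1:15)
  cb <- coexpression(big)
  expect_lt(mean(abs(cb[upper.tri(cb)])), 0.15)
})
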