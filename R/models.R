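# Diagnostic model grid over binarized pair profiles.  Each combo is either
# a single classifier or an ordered (selector -> classifier) pair: the
# selector is fit on training data only and the features it retains are
# passed to the classifier.  Combos are ranked by mean AUC over the
# cross-validated training cohort and all validation cohorts.

MODEL_UNIVERSE <- c("Enet", "GBM", "SVM", "RF", "glm", "plsRglm", "Ridge", "Lasso", "rpart")
SELECTION_CAPABLE <- c("Lasso", "Enet", "Ridge", "glm", "rpart", "RF", "GBM", "plsRglm")

#' Enumerate diagnostic model combinations
#'
#' Default grid: every single-classifier model plus every ordered
#' (selector, classifier) pair with `selector != classifier` where the
#' selector is selection-capable.  With the full nine-method universe this
#' yields 9 + 8 x 8 = 73 combos; the grid is configuration-driven, not a
#' fixed catalog.  `mode = "classifiers"` restricts to the single
#' classifiers.
#'
#' @param universe character method names (duplicates dropped); supported:
#'   Enet, GBM, SVM, RF, glm, plsRglm, Ridge, Lasso, rpart.
#' @param mode `"default"` or `"classifiers"`.
#' @return data.frame with columns `selector` (`NA` for single models),
#'   `classifier`, `name`.
#' @export
enumerate_combos <- function(universe = MODEL_UNIVERSE, mode = c("default", "classifiers")) {
  mode <- match.arg(mode)
  universe <- unique(universe)
  check_flag(length(universe) > 0, "input error: empty method universe")
  unknown <- setdiff(universe, MODEL_UNIVERSE)
  check_flag(length(unknown) == 0, "input error: unknown method(s): %s",
             paste(unknown, collapse = ", "))
  combos <- data.frame(selector = NA_character_, classifier = universe,
                       stringsAsFactors = FALSE)
  if (mode == "default") {
    selectors <- intersect(universe, SELECTION_CAPABLE)
    for (s in selectors) {
      cls <- setdiff(universe, s)
      if (length(cls) > 0)
        combos <- rbind(combos, data.frame(selector = s, classifier = cls,
                                           stringsAsFactors = FALSE))
    }
  }
  combos$name <- ifelse(is.na(combos$selector), combos$classifier,
                        paste(combos$selector, combos$classifier, sep = "+"))
  combos
}

#' Area under the ROC curve from scores and labels
#'
#' Rank-statistic (normalized Mann-Whitney) definition: the probability that
#' a random positive scores above a random negative, with ties credited 0.5.
#'
#' @param scores numeric prediction scores (higher = more positive-like).
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive class.
#' @return AUC in \[0, 1\]; `NA` with a warning if a class is absent.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  check_flag(length(scores) == length(labels), "input error: scores/labels length mismatch")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined: cohort has a single class", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ---- method engines ---------------------------------------------------------
# Each engine fits on X (samples x features, numeric 0/1) and y (logical,
# TRUE = tumor) and returns a closure scoring new X on a monotone
# tumor-likeness scale, plus a per-feature importance vector for selector
# duty.  All stochastic engines consume the caller-provided seed.

fit_engine <- function(method, X, y, seed) {
  yf <- factor(ifelse(y, "tumor", "normal"), levels = c("normal", "tumor"))
  # degenerate design (e.g. a fold where features are constant): fall back
  # to the class prevalence so scoring stays defined
  if (ncol(X) == 0 || all(apply(X, 2L, function(c) length(unique(c)) == 1L))) {
    prev <- mean(y)
    return(list(score = function(newX) rep(prev, nrow(newX)),
                importance = setNames(rep(0, ncol(X)), colnames(X))))
  }
  switch(method,
    glm = {
      df <- data.frame(X, check.names = FALSE)
      fit <- suppressWarnings(glm(yf ~ ., data = cbind(df, yf = yf), family = binomial()))
      co <- coef(fit)[-1L]; co[is.na(co)] <- 0
      names(co) <- gsub("^`|`$", "", names(co))
      list(score = function(newX)
             suppressWarnings(predict(fit, data.frame(newX, check.names = FALSE))),
           importance = abs(co))
    },
    Ridge = fit_glmnet(X, y, alpha = 0, seed),
    Lasso = fit_glmnet(X, y, alpha = 1, seed),
    Enet = fit_glmnet(X, y, alpha = 0.5, seed),
    RF = {
      fit <- ranger::ranger(x = X, y = yf, probability = TRUE, num.trees = 300L,
                            importance = "impurity", seed = seed,
                            num.threads = 1L)
      list(score = function(newX)
             predict(fit, data.frame(newX, check.names = FALSE),
                     num.threads = 1L)$predictions[, "tumor"],
           importance = fit$variable.importance)
    },
    GBM = {
      fit <- withr::with_seed(seed, xgboost::xgboost(
        x = as.matrix(X), y = yf, nrounds = 60L, max_depth = 3L,
        learning_rate = 0.3, nthreads = 1L, verbosity = 0))
      imp <- tryCatch({
        tab <- xgboost::xgb.importance(model = fit)
        setNames(tab$Gain, tab$Feature)
      }, error = function(e) NULL)
      full <- setNames(rep(0, ncol(X)), colnames(X))
      if (!is.null(imp)) full[names(imp)] <- imp
      list(score = function(newX) predict(fit, as.matrix(newX)),
           importance = full)
    },
    SVM = {
      fit <- withr::with_seed(seed, e1071::svm(x = X, y = yf, kernel = "radial",
                                               scale = FALSE))
      # orient decision values toward the tumor class
      sgn <- if (fit$labels[1L] == which(levels(yf) == "tumor")) 1 else -1
      list(score = function(newX) {
             dv <- attr(predict(fit, newX, decision.values = TRUE), "decision.values")
             sgn * drop(dv)
           },
           importance = setNames(rep(1, ncol(X)), colnames(X)))  # SVM is not a selector
    },
    rpart = {
      df <- data.frame(X, check.names = FALSE); df$.y <- yf
      fit <- withr::with_seed(seed, rpart::rpart(.y ~ ., data = df, method = "class",
                                                 control = rpart::rpart.control(cp = 0.01)))
      imp <- setNames(rep(0, ncol(X)), colnames(X))
      vi <- fit$variable.importance
      if (!is.null(vi)) imp[names(vi)] <- vi
      list(score = function(newX)
             predict(fit, data.frame(newX, check.names = FALSE))[, "tumor"],
           importance = imp)
    },
    plsRglm = fit_pls_glm(X, y),
    stop_input("input error: unknown method '%s'", method))
}

fit_glmnet <- function(X, y, alpha, seed) {
  if (ncol(X) < 2L) return(fit_engine("glm", X, y, seed))  # glmnet needs >= 2 columns
  # cross-validated lambda with seeded fold assignment for determinism
  foldid <- withr::with_seed(seed, sample(rep_len(1:5, length(y))))
  fit <- glmnet::cv.glmnet(as.matrix(X), factor(y), family = "binomial",
                           alpha = alpha, foldid = foldid, nfolds = 5L)
  co <- as.matrix(coef(fit, s = "lambda.min"))[-1L, 1L]
  list(score = function(newX)
         drop(predict(fit, as.matrix(newX), s = "lambda.min", type = "link")),
       importance = abs(co))
}

# Partial-least-squares logistic model: 2-component NIPALS scores on the
# centered design, then a binomial GLM on the components.
fit_pls_glm <- function(X, y, ncomp = 2L) {
  X <- as.matrix(X)
  ncomp <- min(ncomp, ncol(X))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  yc <- as.numeric(y) - mean(y)
  W <- matrix(0, ncol(X), ncomp); P <- matrix(0, ncol(X), ncomp)
  Tt <- matrix(0, nrow(X), ncomp)
  Xd <- Xc
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yc))
    if (sqrt(sum(w^2)) < 1e-12) { ncomp <- h - 1L; break }
    w <- w / sqrt(sum(w^2))
    t_h <- drop(Xd %*% w)
    p_h <- drop(crossprod(Xd, t_h)) / sum(t_h^2)
    W[, h] <- w; P[, h] <- p_h; Tt[, h] <- t_h
    Xd <- Xd - tcrossprod(t_h, p_h)
  }
  if (ncomp == 0L) {
    prev <- mean(y)
    return(list(score = function(newX) rep(prev, nrow(newX)),
                importance = setNames(rep(0, ncol(X)), colnames(X))))
  }
  W <- W[, seq_len(ncomp), drop = FALSE]; P <- P[, seq_len(ncomp), drop = FALSE]
  Tt <- Tt[, seq_len(ncomp), drop = FALSE]
  Wstar <- W %*% solve(crossprod(P, W))   # X-space projection weights
  df <- data.frame(Tt); names(df) <- paste0("comp", seq_len(ncomp))
  df$.y <- factor(y)
  gfit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  list(score = function(newX) {
         S <- sweep(as.matrix(newX), 2L, mu) %*% Wstar
         nd <- data.frame(S); names(nd) <- paste0("comp", seq_len(ncomp))
         suppressWarnings(predict(gfit, nd))
       },
       importance = setNames(abs(Wstar[, 1L]), colnames(X)))
}

# Selector duty: which features does a fitted method retain?  Sparse
# penalized fits keep nonzero coefficients; tree ensembles keep features
# with positive importance; dense methods keep the above-median half.
select_features <- function(method, X, y, seed) {
  eng <- fit_engine(method, X, y, seed)
  imp <- eng$importance
  keep <- switch(method,
    Lasso = , Enet = names(imp)[imp > 0],
    rpart = , RF = , GBM = names(imp)[imp > 0],
    names(imp)[imp >= median(imp)])
  if (length(keep) == 0) keep <- colnames(X)  # selector vetoed everything: keep all
  keep
}

#' Fit one model combination and evaluate AUC on every cohort
#'
#' The selector (if any) and the classifier are fit on the training profile
#' only.  The training-cohort AUC is computed from out-of-fold predictions
#' under stratified `cv_folds`-fold cross-validation (the whole
#' selector+classifier pipeline is refit inside each fold), avoiding
#' resubstitution optimism; validation cohorts are scored by the model fit
#' on the full training set.
#'
#' @param combo one row of [enumerate_combos()] (or a list with `selector`,
#'   `classifier`, `name`).
#' @param train_profile a [binarize()]d `pair_profile` (pairs x samples).
#' @param train_labels logical or tumor/normal labels for the training
#'   samples.
#' @param cohorts named list; each element a list with `profile`
#'   (pair_profile over the same pairs) and `labels`.
#' @param cv_folds folds for the training AUC (default 5).
#' @param seed integer seed (fold assignment and stochastic fitters).
#' @return object of class `combo_result`: list with `combo`, `auc`
#'   (named vector: `train` then one per cohort; `NA` for single-class
#'   cohorts), `mean_auc`, `n_features` (selector-retained count).
#' @export
fit_eval_combo <- function(combo, train_profile, train_labels, cohorts = list(),
                           cv_folds = 5L, seed = 1L) {
  X <- t(unclass(train_profile))
  y <- as_tumor_logical(train_labels, ncol(train_profile))
  check_flag(any(y) && any(!y), "input error: training set needs both classes")
  sel <- if (is.na(combo$selector)) NULL else combo$selector

  run_pipe <- function(Xtr, ytr, fit_seed) {
    feats <- if (is.null(sel)) colnames(Xtr)
             else select_features(sel, Xtr, ytr, fit_seed)
    eng <- fit_engine(combo$classifier, Xtr[, feats, drop = FALSE], ytr, fit_seed)
    list(feats = feats,
         score = function(newX) eng$score(newX[, feats, drop = FALSE]))
  }

  # out-of-fold training scores (stratified folds)
  folds <- integer(length(y))
  folds[y] <- withr::with_seed(seed, sample(rep_len(seq_len(cv_folds), sum(y))))
  folds[!y] <- withr::with_seed(seed + 1L, sample(rep_len(seq_len(cv_folds), sum(!y))))
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(cv_folds)) {
    hold <- folds == f
    if (all(hold) || !any(hold)) next
    if (length(unique(y[!hold])) < 2L) next  # fold left a single class: skip
    pipe_f <- run_pipe(X[!hold, , drop = FALSE], y[!hold], seed + f)
    oof[hold] <- pipe_f$score(X[hold, , drop = FALSE])
  }
  ok <- !is.na(oof)
  auc <- c(train = compute_auc(oof[ok], y[ok]))

  pipe <- run_pipe(X, y, seed)
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    Xv <- t(unclass(co$profile))
    yv <- as_tumor_logical(co$labels, nrow(Xv))
    auc[nm] <- compute_auc(pipe$score(Xv), yv)
  }
  new_tag(list(combo = combo, auc = auc,
               mean_auc = mean(auc, na.rm = TRUE),
               n_features = length(pipe$feats)),
          "combo_result")
}

as_tumor_logical <- function(labels, n) {
  check_flag(length(labels) == n, "input error: one label per sample required")
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  as.character(labels) == "tumor"
}

#' Rank model combinations by mean AUC
#'
#' Sorts descending by mean AUC over all defined cohort AUCs; exact ties
#' break toward the simpler model (single classifier before
#' selector+classifier), then lexicographic combo name.
#'
#' @param results list of [fit_eval_combo()] results.
#' @return data.frame: `name`, `selector`, `classifier`, one AUC column per
#'   cohort, `mean_auc`, `rank`.
#' @export
rank_models <- function(results) {
  check_flag(length(results) >= 1L, "input error: no results to rank")
  means <- vapply(results, function(r) r$mean_auc, numeric(1L))
  check_flag(any(is.finite(means)), "input error: no result with a defined AUC")
  stages <- vapply(results, function(r) if (is.na(r$combo$selector)) 1L else 2L, integer(1L))
  names <- vapply(results, function(r) r$combo$name, character(1L))
  ord <- order(-means, stages, names)
  auc_tab <- do.call(rbind, lapply(results[ord], function(r) r$auc))
  out <- data.frame(
    name = names[ord],
    selector = vapply(results[ord], function(r) r$combo$selector, character(1L)),
    classifier = vapply(results[ord], function(r) r$combo$classifier, character(1L)),
    auc_tab,
    mean_auc = means[ord],
    rank = seq_along(ord),
    stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE)
  out
}

#' Run the full diagnostic grid
#'
#' Convenience wrapper: enumerate combos, fit and evaluate each, rank.
#'
#' @inheritParams fit_eval_combo
#' @inheritParams enumerate_combos
#' @return the [rank_models()] table.
#' @export
run_model_grid <- function(train_profile, train_labels, cohorts = list(),
                           universe = MODEL_UNIVERSE, mode = "default",
                           cv_folds = 5L, seed = 1L) {
  combos <- enumerate_combos(universe, mode)
  results <- lapply(seq_len(nrow(combos)), function(i)
    fit_eval_combo(combos[i, ], train_profile, train_labels, cohorts,
                   cv_folds = cv_folds, seed = seed + i))
  rank_models(results)
}
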